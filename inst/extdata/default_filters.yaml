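# Default drug-likeness filter set: Lipinski-style property bounds and a
# small deny-list of reactive functional groups.  Edit freely; rule order
# determines which rule a rejection is attributed to.
rules:
  molecular_weight:
    property: MW
    min: 0
    max: 500
  logp:
    property: logP
    max: 5
  hbond_donors:
    property: HBD
    max: 5
  hbond_acceptors:
    property: HBA
    max: 10
  no_nitro:
    pattern: "[N+](=O)[O-]"
    action: deny
  no_acyl_halide:
    pattern: "[CX3](=O)[Cl,Br,I]"
    action: deny
  no_peroxide:
    pattern: "[OX2][OX2]"
    action: deny
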