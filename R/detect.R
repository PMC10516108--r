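# Reference geometric detector of attractive protein-ligand contacts.  The
# criteria are deliberately simple distance/angle rules held in one config
# object; the scoring contract (weighted sum over counted contacts) is the
# methodological content, the cutoffs are tunable conventions.

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
               S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Zn = 1.39,
               Fe = 1.40, Mg = 1.73, Mn = 1.40, Cu = 1.40, Ni = 1.63,
               Co = 1.40, Ca = 2.31, Na = 2.27, K = 2.75)

METAL_ELEMENTS <- c("Zn", "Fe", "Mg", "Mn", "Cu", "Ni", "Co", "Ca", "Na", "K")

#' Geometric criteria of the contact detector
#'
#' All distance cutoffs are in Angstrom, angles in degrees.
#'
#' @param hydrophobic_max Apolar aliphatic C/S pair distance (default 4.5).
#' @param hbond_max Donor-acceptor heavy-atom distance (default 3.5).
#' @param hbond_angle_min D-H...A angle when hydrogens are present
#'   (default 130).
#' @param ionic_max Opposite-formal-charge distance (default 4.5).
#' @param cation_pi_max Cation to aromatic-ring centroid distance
#'   (default 4.5).
#' @param vdw_slack Added to the sum of van der Waals radii (default 0.5).
#' @param halogen_max X...acceptor distance, X bonded to carbon
#'   (default 3.5).
#' @param pi_centroid_max Ring-centroid distance for pi-stacking
#'   (default 5.5).
#' @param pi_face_angle_max Interplanar angle upper bound for face-to-face
#'   stacking (default 30).
#' @param pi_edge_angle_min Interplanar angle lower bound for edge-to-face
#'   stacking (default 60).
#' @param metallic_max Metal to N/O/S distance (default 2.8).
#' @return An `interaction_criteria` list.
#' @export
interaction_criteria <- function(hydrophobic_max = 4.5, hbond_max = 3.5,
                                 hbond_angle_min = 130, ionic_max = 4.5,
                                 cation_pi_max = 4.5, vdw_slack = 0.5,
                                 halogen_max = 3.5, pi_centroid_max = 5.5,
                                 pi_face_angle_max = 30,
                                 pi_edge_angle_min = 60,
                                 metallic_max = 2.8) {
  structure(as.list(environment()), class = "interaction_criteria")
}

#' Read a protein-ligand complex from a PDB file
#'
#' Builds the atom table [detect_interactions()] consumes from a standard
#' PDB file: HETATM records (minus water) form the ligand, ATOM records the
#' protein.  PDB files carry neither formal charges nor aromaticity, so
#' `charge` is zero and `ring_id`/`aromatic` are empty unless supplied via
#' `ring_atoms`/`charges`; contacts requiring those annotations are then
#' not detected.
#'
#' @param path Path to a PDB file.
#' @param ligand_resid Optional residue name(s) to treat as the ligand
#'   (default: all non-water HETATM records).
#' @param charges Optional named numeric vector of formal charges, names =
#'   atom serial numbers.
#' @param ring_atoms Optional list of integer vectors of atom serials, one
#'   aromatic ring each.
#' @return A list with an `atoms` tibble and an empty `bonds` tibble.
#' @export
read_complex_pdb <- function(path, ligand_resid = NULL, charges = NULL,
                             ring_atoms = NULL) {
  assert_that(requireNamespace("bio3d", quietly = TRUE),
              "read_complex_pdb() needs the bio3d package")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  is_lig <- if (is.null(ligand_resid)) {
    a$type == "HETATM" & !(a$resid %in% c("HOH", "WAT"))
  } else {
    a$resid %in% ligand_resid
  }
  el <- trimws(a$elesy)
  el[!nzchar(el)] <- toupper(substr(trimws(a$elety[!nzchar(el)]), 1, 1))
  atoms <- tibble(
    id = a$eleno,
    role = ifelse(is_lig, "ligand", "protein"),
    element = paste0(substr(el, 1, 1),
                     tolower(substr(el, 2, nchar(el)))),
    x = a$x, y = a$y, z = a$z,
    charge = 0,
    ring_id = NA_integer_,
    aromatic = FALSE
  )
  if (!is.null(charges)) {
    idx <- match(as.integer(names(charges)), atoms$id)
    atoms$charge[idx[!is.na(idx)]] <- charges[!is.na(idx)]
  }
  if (!is.null(ring_atoms)) {
    for (r in seq_along(ring_atoms)) {
      idx <- match(ring_atoms[[r]], atoms$id)
      atoms$ring_id[idx] <- r
      atoms$aromatic[idx] <- TRUE
    }
  }
  list(atoms = atoms, bonds = tibble(i = integer(0), j = integer(0),
                                     order = numeric(0)))
}

#' Detect attractive protein-ligand contacts
#'
#' Counts qualifying protein-atom/ligand-atom (or ring) pairs once per
#' interaction type under the configured geometric criteria.  An atom pair
#' may contribute to several types, except van der Waals, which only counts
#' pairs (and ring-member pairs) not already counted elsewhere.
#'
#' @param complex A `toy_complex` from [make_complex()], or any list with
#'   tibbles `atoms` (`role` in protein/ligand, `element`, `x`, `y`, `z`,
#'   `charge`, `ring_id`, `aromatic`) and optionally `bonds` (`i`, `j`).
#' @param criteria An [interaction_criteria()].
#' @return Named integer vector over [INTERACTION_TYPES].
#' @export
#' @examples
#' detect_interactions(make_complex(c(hydrophobic = 1)))
detect_interactions <- function(complex, criteria = interaction_criteria()) {
  atoms <- complex$atoms
  bonds <- complex$bonds %||% tibble(i = integer(0), j = integer(0))
  required <- c("role", "element", "x", "y", "z", "charge", "ring_id", "aromatic")
  miss <- setdiff(required, names(atoms))
  assert_that(length(miss) == 0,
              paste0("atoms table lacks annotation(s): ",
                     paste(miss, collapse = " ")))
  if (!"id" %in% names(atoms)) atoms$id <- seq_len(nrow(atoms))
  prof <- interaction_profile()
  pi_ <- which(atoms$role == "protein")
  li_ <- which(atoms$role == "ligand")
  if (length(pi_) == 0 || length(li_) == 0) return(prof)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  D <- sqrt(outer(rowSums(xyz[pi_, , drop = FALSE]^2), rep(1, length(li_))) +
            outer(rep(1, length(pi_)), rowSums(xyz[li_, , drop = FALSE]^2)) -
            2 * xyz[pi_, , drop = FALSE] %*% t(xyz[li_, , drop = FALSE]))
  el_p <- atoms$element[pi_]; el_l <- atoms$element[li_]
  ch_p <- atoms$charge[pi_]; ch_l <- atoms$charge[li_]
  ar_p <- atoms$aromatic[pi_]; ar_l <- atoms$aromatic[li_]
  has_h <- any(atoms$element == "H")
  counted <- matrix(FALSE, length(pi_), length(li_))  # pairs counted outside vdW

  # hydrophobic: apolar aliphatic C/S on both sides
  apolar_p <- el_p %in% c("C", "S") & !ar_p
  apolar_l <- el_l %in% c("C", "S") & !ar_l
  m <- outer(apolar_p, apolar_l, "&") & D <= criteria$hydrophobic_max
  prof["hydrophobic"] <- sum(m); counted <- counted | m

  # hydrogen bond: N/O donor on one side, N/O acceptor on the other
  polar_p <- el_p %in% c("N", "O"); polar_l <- el_l %in% c("N", "O")
  m <- outer(polar_p, polar_l, "&") & D <= criteria$hbond_max
  if (has_h && any(m)) {
    # angle mode: the donor must carry a bonded H with D-H...A >= cutoff
    ok_angle <- function(di, ai) {
      hs <- c(bonds$j[bonds$i == di], bonds$i[bonds$j == di])
      hs <- hs[atoms$element[match(hs, atoms$id)] == "H"]
      if (length(hs) == 0) return(FALSE)
      any(vapply(hs, function(h) {
        v1 <- xyz[match(h, atoms$id), ] - xyz[di, ]
        v2 <- xyz[ai, ] - xyz[match(h, atoms$id), ]
        ang <- acos(pmin(1, pmax(-1, sum(-v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        (180 - ang) >= criteria$hbond_angle_min
      }, logical(1)))
    }
    for (ii in which(m, arr.ind = TRUE) |> apply(1, identity, simplify = FALSE)) {
      di <- pi_[ii[1]]; ai <- li_[ii[2]]
      if (!(ok_angle(di, ai) || ok_angle(ai, di))) m[ii[1], ii[2]] <- FALSE
    }
  }
  prof["hydrogen_bond"] <- sum(m); counted <- counted | m

  # ionic: opposite formal charges
  m <- outer(ch_p, ch_l) < 0 & D <= criteria$ionic_max
  prof["ionic"] <- sum(m); counted <- counted | m

  # rings: centroids and normals per side
  ring_info <- function(idx) {
    rt <- atoms[idx, ]
    rt <- rt[!is.na(rt$ring_id) & rt$aromatic, ]
    if (nrow(rt) == 0) return(NULL)
    lapply(split(seq_len(nrow(rt)), rt$ring_id), function(rows) {
      P <- as.matrix(rt[rows, c("x", "y", "z")])
      ctr <- colMeans(P)
      sv <- svd(sweep(P, 2, ctr))
      list(centroid = ctr, normal = sv$v[, 3], members = rt$id[rows])
    })
  }
  rings_p <- ring_info(pi_); rings_l <- ring_info(li_)

  # cation-pi: cation on one side to aromatic ring centroid on the other
  n_catpi <- 0L
  catpi_members <- integer(0)
  cat_ring <- function(cations, rings) {
    hits <- 0L
    for (ci in cations) for (rg in rings) {
      if (sqrt(sum((xyz[ci, ] - rg$centroid)^2)) <= criteria$cation_pi_max) {
        hits <- hits + 1L
        catpi_members <<- c(catpi_members, ci, rg$members)
      }
    }
    hits
  }
  n_catpi <- cat_ring(pi_[ch_p > 0], rings_l) + cat_ring(li_[ch_l > 0], rings_p)
  prof["cation_pi"] <- n_catpi

  # halogen bond: C-X (X = Cl/Br/I) with X...acceptor N/O
  halo <- c("Cl", "Br", "I")
  bonded_to_c <- function(ai) {
    nb <- c(bonds$j[bonds$i == ai], bonds$i[bonds$j == ai])
    any(atoms$element[match(nb, atoms$id)] == "C")
  }
  n_hal <- 0L
  for (side in 1:2) {
    xs <- if (side == 1) li_ else pi_
    acc <- if (side == 1) pi_ else li_
    xs <- xs[atoms$element[xs] %in% halo]
    acc <- acc[atoms$element[acc] %in% c("N", "O")]
    for (xi in xs) {
      if (!bonded_to_c(xi)) next
      for (ai in acc) {
        dd <- sqrt(sum((xyz[xi, ] - xyz[ai, ])^2))
        if (dd <= criteria$halogen_max) {
          n_hal <- n_hal + 1L
          if (side == 1) counted[match(ai, pi_), match(xi, li_)] <- TRUE
          else counted[match(xi, pi_), match(ai, li_)] <- TRUE
        }
      }
    }
  }
  prof["halogen_bond"] <- n_hal

  # pi-stacking: ring-pair centroid distance + interplanar angle
  stack_members <- integer(0)
  if (!is.null(rings_p) && !is.null(rings_l)) {
    for (rp in rings_p) for (rl in rings_l) {
      dd <- sqrt(sum((rp$centroid - rl$centroid)^2))
      if (dd > criteria$pi_centroid_max) next
      cosang <- abs(sum(rp$normal * rl$normal))
      ang <- acos(pmin(1, cosang)) * 180 / pi
      if (ang <= criteria$pi_face_angle_max) {
        prof["pi_stack_face"] <- prof["pi_stack_face"] + 1L
        stack_members <- c(stack_members, rp$members, rl$members)
      } else if (ang >= criteria$pi_edge_angle_min) {
        prof["pi_stack_edge"] <- prof["pi_stack_edge"] + 1L
        stack_members <- c(stack_members, rp$members, rl$members)
      }
    }
  }

  # metallic: metal to N/O/S
  m <- (outer(el_p %in% METAL_ELEMENTS, el_l %in% c("N", "O", "S"), "&") |
        outer(el_p %in% c("N", "O", "S"), el_l %in% METAL_ELEMENTS, "&")) &
    D <= criteria$metallic_max
  prof["metallic"] <- sum(m); counted <- counted | m

  # van der Waals: within vdW-sum + slack, excluding pairs already counted
  # and pairs internal to rings engaged in stacking or cation-pi contacts
  rad_p <- unname(VDW_RADII[el_p]); rad_p[is.na(rad_p)] <- 1.7
  rad_l <- unname(VDW_RADII[el_l]); rad_l[is.na(rad_l)] <- 1.7
  ring_excl <- unique(c(stack_members, catpi_members))
  excl <- counted |
    outer(pi_ %in% ring_excl, li_ %in% ring_excl, "&")
  m <- D <= outer(rad_p, rad_l, "+") + criteria$vdw_slack & !excl &
    outer(el_p != "H", el_l != "H", "&")
  prof["van_der_waals"] <- sum(m)

  prof
}
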