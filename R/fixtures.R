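# Synthetic fixtures: combinatorial toy SMILES corpora, a surrogate scorer
# whose value varies smoothly with position in the chemical-space proxy, and
# toy 3D protein-ligand complexes with planted interactions.  Everything is
# generated in code; nothing is downloaded.

# Enumerate the combinatorial SMILES space: prefixes/suffixes on chains of
# several lengths, mono-substituted rings, and branched chains.  The pool is
# canonicalized and deduplicated once, so its size and content are fixed.
toy_smiles_pool <- function() {
  pre <- c("", "O", "N", "Cl", "Br", "F", "OC", "NC")
  suf <- c("", "O", "N", "Cl", "Br", "F", "C#N", "C(=O)O", "C(C)C")
  mid <- c("C", "O", "Cl")
  chains <- vapply(1:6, function(k) strrep("C", k), character(1))
  pool <- c(
    as.vector(outer(as.vector(outer(pre, chains, paste0)), suf, paste0)),
    as.vector(outer(pre, paste0("c1ccc(", suf, ")cc1"), paste0)),
    as.vector(outer(pre, paste0("C1CCC(", suf, ")CC1"), paste0)),
    as.vector(outer(pre, paste0("c1ccc(", suf, ")nc1"), paste0)),
    as.vector(outer(
      as.vector(outer(pre, paste0("CC(", mid, ")CC"), paste0)), suf, paste0))
  )
  pool <- pool[nzchar(pool)]
  can <- canonical_smiles(pool)
  sort(unique(can[!is.na(can)]))
}

# cache: the pool never changes within a session
.toy_pool_env <- new.env(parent = emptyenv())

#' Generate a toy SMILES corpus
#'
#' Draws `n` unique, valid, canonical SMILES from a fixed combinatorial
#' space of small scaffolds (chains, carbocycles, aromatics, a pyridine)
#' decorated with halogens and O/N-containing substituents.  Token lengths
#' span a wide range so the length-cutoff stage is exercised.
#'
#' @param n Number of molecules (must not exceed the enumerable space).
#' @param seed Integer seed; the same seed yields the same corpus.
#' @return Character vector of `n` unique canonical SMILES.
#' @export
#' @examples
#' make_corpus(5, seed = 1)
make_corpus <- function(n, seed = 1L) {
  assert_that(n >= 1, "n must be >= 1")
  if (is.null(.toy_pool_env$pool)) .toy_pool_env$pool <- toy_smiles_pool()
  pool <- .toy_pool_env$pool
  assert_that(n <= length(pool),
              sprintf("n = %d exceeds the enumerable space of %d molecules",
                      n, length(pool)))
  with_seed(seed, sample(pool, n))
}

# ---- surrogate scorer ------------------------------------------------------

#' Surrogate scorer in the chemical-space proxy
#'
#' A stand-in for docking + interaction scoring used to exercise the loop:
#' the score is a Gaussian bump centred on a target point in the projected
#' space, `max_score * exp(-||x - target||^2 / (2 scale^2)) + noise`, so
#' position in the proxy correlates with the score and nearby molecules
#' score similarly.
#'
#' @param target Numeric vector: the target point (leading projected
#'   coordinates).
#' @param length_scale Gaussian length scale (same units as the projected
#'   coordinates).
#' @param max_score Score at the target point.
#' @param noise_sd Standard deviation of optional additive noise (default 0).
#' @param noise_seed Seed from which per-molecule noise is derived
#'   deterministically.
#' @return A `surrogate_scorer` object.
#' @export
surrogate_scorer <- function(target, length_scale, max_score,
                             noise_sd = 0, noise_seed = 1L) {
  assert_that(length_scale > 0, "length_scale must be positive")
  structure(list(target = as.numeric(target), length_scale = length_scale,
                 max_score = max_score, noise_sd = noise_sd,
                 noise_seed = as.integer(noise_seed)),
            class = "surrogate_scorer")
}

#' Calibrate a surrogate scorer against a reference ensemble
#'
#' Picks the target point as the projected coordinates of one seed-chosen
#' reference molecule, sets the length scale to the median distance of the
#' ensemble from the target, and scales `max_score` so that `top_fraction`
#' of the reference ensemble scores at or above `threshold` — emulating the
#' score-threshold attainment a pretrained model starts from.
#'
#' @param coords Matrix or tibble of projected coordinates (rows =
#'   molecules; a `smiles` column, if present, is ignored).
#' @param threshold Score threshold the calibration refers to.
#' @param top_fraction Fraction of the reference ensemble at or above
#'   `threshold` (default 0.25).
#' @param n_dims Number of leading components defining the target (default
#'   all columns).
#' @param noise_sd,noise_seed Passed to [surrogate_scorer()].
#' @param seed Seed choosing the target molecule.
#' @return A calibrated `surrogate_scorer`.
#' @export
calibrate_surrogate <- function(coords, threshold, top_fraction = 0.25,
                                n_dims = NULL, noise_sd = 0, noise_seed = 1L,
                                seed = 1L) {
  X <- coord_matrix(coords)
  if (!is.null(n_dims)) X <- X[, seq_len(n_dims), drop = FALSE]
  i <- with_seed(seed, sample.int(nrow(X), 1))
  target <- X[i, ]
  d <- sqrt(rowSums(sweep(X, 2, target)^2))
  scale <- max(stats::median(d), 1e-6)
  g <- exp(-d^2 / (2 * scale^2))
  qg <- stats::quantile(g, 1 - top_fraction, names = FALSE)
  max_score <- threshold / max(qg, 1e-12)
  surrogate_scorer(target, scale, max_score, noise_sd, noise_seed)
}

coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    coords <- coords[, setdiff(names(coords), c("smiles", "name")), drop = FALSE]
  }
  as.matrix(coords)
}

#' Score molecules with the surrogate scorer
#'
#' Computes descriptors, projects into the proxy, and evaluates the
#' Gaussian surrogate.  A pseudo interaction profile is back-filled using
#' van-der-Waals contacts (weight 1.0) as the unit filler, so
#' [score_profile()] of the profile reproduces the score to within
#' integer-count granularity.
#'
#' @param molecules Character vector of SMILES or tibble with `smiles`.
#' @param scorer A [surrogate_scorer()].
#' @param projection A fitted [fit_projection()] model.
#' @param provider Descriptor provider used when fitting `projection`.
#' @return Tibble with `smiles`, `score` (continuous surrogate value) and
#'   the nine interaction-count columns of the pseudo-profile.
#' @export
surrogate_score <- function(molecules, scorer, projection,
                            provider = descriptor_provider_fast()) {
  if (is.data.frame(molecules)) molecules <- molecules$smiles
  desc <- compute_descriptors(molecules, provider)
  prj <- project(projection, desc)
  X <- coord_matrix(prj)[, seq_along(scorer$target), drop = FALSE]
  d <- sqrt(rowSums(sweep(X, 2, scorer$target)^2))
  score <- scorer$max_score * exp(-d^2 / (2 * scorer$length_scale^2))
  if (scorer$noise_sd > 0) {
    noise <- vapply(prj$smiles, function(s) {
      with_seed(derive_seed(scorer$noise_seed, s), rnorm(1, 0, scorer$noise_sd))
    }, numeric(1), USE.NAMES = FALSE)
    score <- score + noise
  }
  prof <- empty_profile_tbl(length(score))
  prof$van_der_waals <- pmax(round(score), 0)
  bind_cols(tibble(smiles = prj$smiles, score = score), prof)
}

#' Surrogate pose provider
#'
#' Wraps [surrogate_score()] as a [pose_provider()] so the surrogate can
#' stand behind the scoring stage of the loop.
#'
#' @inheritParams surrogate_score
#' @return A `pose_provider`.
#' @export
surrogate_pose_provider <- function(scorer, projection,
                                    provider = descriptor_provider_fast()) {
  pose_provider(
    function(smiles) {
      sc <- surrogate_score(smiles, scorer, projection, provider)
      sc[, c("smiles", INTERACTION_TYPES)]
    },
    label = "surrogate-gaussian"
  )
}

# ---- toy complexes with planted interactions -------------------------------

# Each planted contact is built in its own pocket on a 30 Angstrom grid, far
# outside every geometric cutoff of any other pocket.  Pocket geometries are
# chosen so that exactly one interaction of the requested type (and nothing
# else) satisfies the default detector criteria.
pocket_builders <- function() {
  atom <- function(role, element, x, y, z, charge = 0, ring_id = NA_integer_,
                   aromatic = FALSE) {
    tibble(role = role, element = element, x = x, y = y, z = z,
           charge = charge, ring_id = ring_id, aromatic = aromatic)
  }
  ring <- function(role, ring_id, center, normal_axis = "z", radius = 1.39) {
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    flat <- cbind(radius * cos(th), radius * sin(th), 0)
    xyz <- switch(normal_axis,
      z = flat,
      x = flat[, c(3, 1, 2)],
      y = flat[, c(1, 3, 2)])
    xyz <- sweep(xyz, 2, center, "+")
    atom(role, rep("C", 6), xyz[, 1], xyz[, 2], xyz[, 3],
         ring_id = ring_id, aromatic = TRUE)
  }
  list(
    hydrophobic = function(rid) list(
      atoms = bind_rows(atom("protein", "C", 0, 0, 0),
                        atom("ligand", "C", 4.0, 0, 0)),
      bonds = NULL),
    hydrogen_bond = function(rid) list(
      atoms = bind_rows(atom("protein", "N", 0, 0, 0),
                        atom("ligand", "O", 3.4, 0, 0)),
      bonds = NULL),
    ionic = function(rid) list(
      atoms = bind_rows(atom("protein", "N", 0, 0, 0, charge = 1),
                        atom("ligand", "O", 4.0, 0, 0, charge = -1)),
      bonds = NULL),
    cation_pi = function(rid) list(
      atoms = bind_rows(atom("protein", "N", 0, 0, 4.0, charge = 1),
                        ring("ligand", rid, c(0, 0, 0))),
      bonds = NULL),
    van_der_waals = function(rid) list(
      atoms = bind_rows(atom("protein", "O", 0, 0, 0),
                        atom("ligand", "C", 3.5, 0, 0)),
      bonds = NULL),
    halogen_bond = function(rid) list(
      atoms = bind_rows(atom("protein", "O", 3.2, 0, 0),
                        atom("ligand", "Cl", 0, 0, 0),
                        atom("ligand", "C", -1.8, 0, 0)),
      bonds = tibble(i = 2L, j = 3L, order = 1)),
    pi_stack_face = function(rid) list(
      atoms = bind_rows(ring("protein", rid, c(0, 0, 4.2)),
                        ring("ligand", rid + 1L, c(0, 0, 0))),
      bonds = NULL),
    pi_stack_edge = function(rid) list(
      atoms = bind_rows(ring("protein", rid, c(5.2, 0, 0), normal_axis = "x"),
                        ring("ligand", rid + 1L, c(0, 0, 0))),
      bonds = NULL),
    metallic = function(rid) list(
      atoms = bind_rows(atom("protein", "Zn", 0, 0, 0, charge = 2),
                        atom("ligand", "O", 2.5, 0, 0)),
      bonds = NULL)
  )
}

#' Build a toy protein-ligand complex with planted interactions
#'
#' Emits coordinates, elements, formal charges and aromatic-ring
#' annotations such that the reference geometric detector finds exactly the
#' requested number of contacts of each type and nothing else.  Each
#' contact lives in its own pocket on a 30-Angstrom grid, far outside every
#' cutoff of every other pocket.
#'
#' @param planted Named integer vector/list of per-type counts; names from
#'   [INTERACTION_TYPES] (missing types are 0).
#' @param seed Seed controlling the (irrelevant to detection) pocket
#'   shuffling.
#' @return A `toy_complex`: list with tibbles `atoms`
#'   (`role, element, x, y, z, charge, ring_id, aromatic`) and `bonds`.
#' @export
#' @examples
#' cx <- make_complex(c(hydrogen_bond = 2, ionic = 1))
#' detect_interactions(cx)
make_complex <- function(planted = integer(0), seed = 1L) {
  planted <- unlist(planted)
  bad <- setdiff(names(planted), INTERACTION_TYPES)
  assert_that(length(bad) == 0,
              paste0("unknown interaction type(s): ", paste(bad, collapse = " ")))
  assert_that(all(planted >= 0), "planted counts must be >= 0")
  counts <- setNames(rep(0L, length(INTERACTION_TYPES)), INTERACTION_TYPES)
  counts[names(planted)] <- as.integer(planted)
  builders <- pocket_builders()
  units <- rep(names(counts), counts)
  atoms <- list(); bonds <- list()
  rid <- 1L
  grid <- 30
  order <- if (length(units) > 1) with_seed(seed, sample(seq_along(units))) else seq_along(units)
  for (k in seq_along(units)) {
    type <- units[order[k]]
    pk <- builders[[type]](rid)
    rid <- rid + 2L
    px <- grid * ((k - 1) %% 7)
    py <- grid * ((k - 1) %/% 7)
    a <- pk$atoms
    a$x <- a$x + px; a$y <- a$y + py
    offset <- sum(vapply(atoms, nrow, integer(1)))
    if (!is.null(pk$bonds)) {
      b <- pk$bonds
      b$i <- b$i + offset; b$j <- b$j + offset
      bonds[[length(bonds) + 1]] <- b
    }
    atoms[[length(atoms) + 1]] <- a
  }
  atoms <- if (length(atoms)) bind_rows(atoms) else
    tibble(role = character(0), element = character(0), x = numeric(0),
           y = numeric(0), z = numeric(0), charge = numeric(0),
           ring_id = integer(0), aromatic = logical(0))
  atoms$id <- seq_len(nrow(atoms))
  bonds <- if (length(bonds)) bind_rows(bonds) else
    tibble(i = integer(0), j = integer(0), order = numeric(0))
  structure(list(atoms = atoms, bonds = bonds, planted = counts),
            class = "toy_complex")
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("<toy_complex: %d atoms, %d planted contacts>\n",
              nrow(x$atoms), sum(x$planted)))
  invisible(x)
}
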