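# Attractive-interaction scoring: per-type contact counts, handpicked
# weights, a weighted-sum score, threshold derivation, and the pluggable
# pose-provider contract.

#' The nine attractive interaction types
#'
#' Order matters: it is the column order of profile tibbles and CSV files.
#' @export
INTERACTION_TYPES <- c("hydrophobic", "hydrogen_bond", "ionic", "cation_pi",
                       "van_der_waals", "halogen_bond", "pi_stack_face",
                       "pi_stack_edge", "metallic")

#' Interaction weights
#'
#' Handpicked weights of the scoring function, one per contact type.
#' Defaults: hydrophobic 2.5, hydrogen bond 3.5, ionic 7.5, cation-pi 2.5,
#' van der Waals 1.0, halogen bond 3.0, face-to-face pi-stacking 3.0,
#' edge-to-face pi-stacking 1.0, metallic complexation 3.0.
#'
#' @param ... Named overrides, e.g. `ionic = 10`.
#' @return Named numeric vector over [INTERACTION_TYPES].
#' @export
#' @examples
#' interaction_weights()
#' interaction_weights(hydrogen_bond = 5)
interaction_weights <- function(...) {
  w <- c(hydrophobic = 2.5, hydrogen_bond = 3.5, ionic = 7.5,
         cation_pi = 2.5, van_der_waals = 1.0, halogen_bond = 3.0,
         pi_stack_face = 3.0, pi_stack_edge = 1.0, metallic = 3.0)
  over <- list(...)
  bad <- setdiff(names(over), INTERACTION_TYPES)
  assert_that(length(bad) == 0,
              paste0("unknown interaction type(s): ", paste(bad, collapse = " ")))
  w[names(over)] <- as.numeric(over)
  assert_that(all(is.finite(w)), "weights must be finite")
  w
}

#' Construct an interaction profile
#'
#' @param ... Named nonnegative counts over [INTERACTION_TYPES]; omitted
#'   types are 0.
#' @return Named integer vector over all nine types.
#' @export
#' @examples
#' interaction_profile(hydrogen_bond = 1)
interaction_profile <- function(...) {
  p <- setNames(rep(0L, length(INTERACTION_TYPES)), INTERACTION_TYPES)
  over <- unlist(list(...))
  if (length(over)) {
    bad <- setdiff(names(over), INTERACTION_TYPES)
    assert_that(length(bad) == 0,
                paste0("unknown interaction type(s): ", paste(bad, collapse = " ")))
    assert_that(all(over >= 0), "counts must be >= 0")
    p[names(over)] <- as.integer(over)
  }
  p
}

empty_profile_tbl <- function(n) {
  as_tibble(setNames(
    as.data.frame(matrix(0L, n, length(INTERACTION_TYPES))),
    INTERACTION_TYPES))
}

#' Score an interaction profile
#'
#' The score is the weighted sum of contact counts,
#' `sum(count_type * weight_type)` — linear, additive, and homogeneous in
#' the weights.
#'
#' @param profile Named counts (from [interaction_profile()] or
#'   [detect_interactions()]), or a data frame with the nine count columns
#'   (scored row-wise).
#' @param weights Named weights; default [interaction_weights()].
#' @return Numeric score (vector if `profile` is a data frame).
#' @export
#' @examples
#' score_profile(interaction_profile(hydrophobic = 2, ionic = 1))
score_profile <- function(profile, weights = interaction_weights()) {
  w <- weights[INTERACTION_TYPES]
  assert_that(!any(is.na(w)), "weights must cover all nine types")
  if (is.data.frame(profile)) {
    m <- as.matrix(profile[, INTERACTION_TYPES, drop = FALSE])
    assert_that(all(m >= 0), "counts must be >= 0")
    return(as.numeric(m %*% w))
  }
  p <- setNames(rep(0, length(INTERACTION_TYPES)), INTERACTION_TYPES)
  keep <- names(profile) %in% INTERACTION_TYPES
  p[names(profile)[keep]] <- as.numeric(profile[keep])
  assert_that(all(p >= 0), "counts must be >= 0")
  sum(p * w)
}

#' Derive a score threshold from reference scores
#'
#' The threshold is the minimum score among a set of docked-and-scored
#' reference ligands (e.g. known inhibitors of the target).
#'
#' @param reference_scores Numeric vector of reference scores (length >= 1).
#' @return The minimum.
#' @export
derive_threshold <- function(reference_scores) {
  assert_that(length(reference_scores) >= 1,
              "derive_threshold: need at least one reference score")
  min(reference_scores)
}

# ---- pose providers --------------------------------------------------------

#' Pose-provider contract
#'
#' A pose provider turns molecules into interaction profiles — by docking,
#' by reading precomputed profiles, or synthetically.  It is a function
#' `smiles -> tibble(smiles, <nine count columns>)`; molecules it fails on
#' are simply absent from its output.
#'
#' @param fun Function from a character vector of SMILES to a tibble with
#'   `smiles` plus the nine [INTERACTION_TYPES] columns.
#' @param label Provenance label recorded with scores.
#' @return A `pose_provider`.
#' @export
pose_provider <- function(fun, label = "custom") {
  assert_that(is.function(fun), "fun must be a function")
  structure(list(fun = fun, label = label), class = "pose_provider")
}

#' @export
print.pose_provider <- function(x, ...) {
  cat(sprintf("<pose_provider: %s>\n", x$label))
  invisible(x)
}

#' Pose provider reading precomputed interaction profiles
#'
#' @param profiles CSV path or data frame with a `smiles` column and the
#'   nine [INTERACTION_TYPES] count columns.
#' @return A `pose_provider` that looks molecules up by canonical SMILES.
#' @export
profile_pose_provider <- function(profiles) {
  if (is.character(profiles)) {
    profiles <- readr::read_csv(profiles, show_col_types = FALSE)
  }
  missing <- setdiff(c("smiles", INTERACTION_TYPES), names(profiles))
  assert_that(length(missing) == 0,
              paste0("profile table lacks column(s): ",
                     paste(missing, collapse = " ")))
  tbl <- as_tibble(profiles)[, c("smiles", INTERACTION_TYPES)]
  pose_provider(
    function(smiles) tbl[tbl$smiles %in% smiles, , drop = FALSE],
    label = "profile-from-file"
  )
}

#' Score molecules through a pose provider
#'
#' One scored row per molecule the provider poses successfully; failures
#' are reported separately.  Output order follows input order.
#'
#' @param molecules Character vector of unique (canonical) SMILES, or a
#'   tibble with `smiles` (extra columns such as `cluster` are carried
#'   through).
#' @param provider A [pose_provider()].
#' @param weights Named weights; default [interaction_weights()].
#' @return Tibble with `smiles`, `score`, the nine count columns and any
#'   carried columns; attribute `failures` lists unposed molecules.
#' @export
score_molecules <- function(molecules, provider,
                            weights = interaction_weights()) {
  carried <- NULL
  if (is.data.frame(molecules)) {
    carried <- molecules
    molecules <- molecules$smiles
  }
  assert_that(!anyDuplicated(molecules), "molecule ids must be unique")
  prof <- provider$fun(molecules)
  prof <- as_tibble(prof)[, c("smiles", INTERACTION_TYPES)]
  # one row per molecule, input order
  prof <- prof[!duplicated(prof$smiles), , drop = FALSE]
  idx <- match(molecules, prof$smiles)
  ok <- !is.na(idx)
  out <- prof[idx[ok], , drop = FALSE]
  out$score <- score_profile(out, weights)
  out <- out[, c("smiles", "score", INTERACTION_TYPES)]
  if (!is.null(carried)) {
    extra <- carried[ok, setdiff(names(carried), names(out)), drop = FALSE]
    out <- bind_cols(out, extra)
  }
  failures <- molecules[!ok]
  if (length(failures) > 0) {
    rlang::warn(sprintf("score_molecules: provider failed on %d of %d molecules",
                        length(failures), length(molecules)))
  }
  attr(out, "failures") <- failures
  attr(out, "provider") <- provider$label
  out
}
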