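# Iteration-level evaluation: threshold attainment, score summaries,
# similarity profiles against reference ligands, exact recovery.

#' Percentage of scores at or above a threshold
#'
#' The comparison is inclusive (`>=`).  When the scored molecules are a
#' cluster-stratified sample of a larger ensemble, pass inverse-inclusion
#' `weights` (cluster size / number scored in the cluster) so the subset
#' statistic estimates the ensemble fraction; with equal weights (the
#' default) this is the plain subset percentage.
#'
#' @param scores Numeric vector (length >= 1).
#' @param threshold Score threshold.
#' @param weights Optional nonnegative weights, one per score.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' threshold_fraction(c(10, 11, 12), 11)
threshold_fraction <- function(scores, threshold, weights = NULL) {
  assert_that(length(scores) >= 1, "threshold_fraction: empty scores")
  if (is.null(weights)) return(100 * mean(scores >= threshold))
  assert_that(length(weights) == length(scores) && all(weights >= 0),
              "weights must be nonnegative, one per score")
  100 * sum(weights * (scores >= threshold)) / sum(weights)
}

#' Mean and maximum score
#'
#' @param scores Numeric vector (length >= 1).
#' @param weights Optional weights as in [threshold_fraction()]; the
#'   maximum is always unweighted.
#' @return Tibble with columns `mean` and `max`.
#' @export
score_summary <- function(scores, weights = NULL) {
  assert_that(length(scores) >= 1, "score_summary: empty scores")
  m <- if (is.null(weights)) mean(scores) else {
    sum(weights * scores) / sum(weights)
  }
  tibble(mean = m, max = max(scores))
}

#' Similarity profile against reference ligands
#'
#' For every reference molecule, the mean Tanimoto similarity between its
#' fingerprint and those of all generated molecules, plus the most similar
#' generated molecule.
#'
#' @param generated Character vector (or tibble with `smiles`) of generated
#'   molecules.
#' @param references Named or unnamed character vector of reference SMILES.
#' @param fingerprint_kind `"circular"` (ECFP4-equivalent) or `"path"`;
#'   see [fingerprint_bits()].
#' @return Tibble with one row per reference: `reference`, `mean_tanimoto`,
#'   `best_match` (generated SMILES), `best_tanimoto`.
#' @export
similarity_profile <- function(generated, references,
                               fingerprint_kind = c("circular", "path")) {
  fingerprint_kind <- match.arg(fingerprint_kind)
  if (is.data.frame(generated)) generated <- generated$smiles
  ref_names <- names(references) %||% references
  fps_g <- fingerprint_bits(generated, fingerprint_kind)
  fps_r <- fingerprint_bits(references, fingerprint_kind)
  ok_g <- !vapply(fps_g, is.null, logical(1))
  if (any(!ok_g)) {
    rlang::warn(sprintf("similarity_profile: skipped %d unfingerprintable generated molecule(s)",
                        sum(!ok_g)))
  }
  fps_g <- fps_g[ok_g]
  gen_ok <- generated[ok_g]
  rows <- lapply(seq_along(references), function(i) {
    fr <- fps_r[[i]]
    if (is.null(fr) || length(fps_g) == 0) {
      return(tibble(reference = ref_names[i], mean_tanimoto = NA_real_,
                    best_match = NA_character_, best_tanimoto = NA_real_))
    }
    sims <- unname(vapply(fps_g, tanimoto, numeric(1), b = fr))
    j <- which.max(sims)
    tibble(reference = unname(ref_names[i]), mean_tanimoto = mean(sims),
           best_match = unname(gen_ok[j]), best_tanimoto = sims[j])
  })
  bind_rows(rows)
}

#' Exactly recovered reference molecules
#'
#' Canonical-form set intersection between the generated ensemble and the
#' reference list.
#'
#' @param generated Character vector (or tibble with `smiles`).
#' @param references Character vector of reference SMILES.
#' @return Character vector of recovered references (their canonical
#'   forms).
#' @export
exact_recovery <- function(generated, references) {
  if (is.data.frame(generated)) generated <- generated$smiles
  cg <- canonical_smiles(generated)
  cr <- canonical_smiles(references)
  intersect(cr[!is.na(cr)], cg[!is.na(cg)])
}

# One metrics row for an iteration, computed on the scored subset.  For
# cluster-stratified subsets, `weights` carries the inverse inclusion
# probabilities so the reported fraction/mean estimate the full generated
# ensemble (comparable to a random-subset estimate).
iteration_metrics_row <- function(iteration, scored_scores, threshold,
                                  n_generated, weights = NULL,
                                  references = NULL, generated = NULL) {
  sm <- score_summary(scored_scores, weights)
  row <- tibble(
    iteration = iteration,
    n_generated = n_generated,
    n_scored = length(scored_scores),
    fraction_above_threshold = threshold_fraction(scored_scores, threshold,
                                                  weights),
    mean_score = sm$mean,
    max_score = sm$max
  )
  if (!is.null(references) && !is.null(generated) && length(generated) > 0) {
    prof <- similarity_profile(generated, references)
    row$mean_tanimoto <- mean(prof$mean_tanimoto, na.rm = TRUE)
    rec <- exact_recovery(generated, references)
    row$n_recovered <- length(rec)
  }
  row
}
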