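# Construction of the active-learning training set: replica multiplication
# of above-threshold molecules to a size floor, softmax conversion of mean
# cluster scores to sampling fractions, capacity-aware integer allocation,
# and the final combined set.

#' Active-learning set configuration
#'
#' @param score_threshold Score at or above which a scored molecule enters
#'   the replica part (reference configurations used 37 for a kinase target
#'   with known inhibitors and 11 for a threshold taken from a
#'   protein-ligand database).
#' @param replica_floor Minimum total size of the replica part (full-scale
#'   default 5000).
#' @param sampling_budget Number of unscored molecules sampled from
#'   clusters (full-scale default 5000).
#' @param fraction_method `"softmax"` (mean cluster scores through a
#'   softmax) or `"uniform"` (equal fraction per cluster; the
#'   uniform-sampling control).
#' @return An `al_config` list.
#' @export
al_config <- function(score_threshold, replica_floor = 5000L,
                      sampling_budget = 5000L,
                      fraction_method = c("softmax", "uniform")) {
  assert_that(replica_floor > 0, "replica_floor must be > 0")
  assert_that(sampling_budget > 0, "sampling_budget must be > 0")
  structure(list(score_threshold = score_threshold,
                 replica_floor = as.integer(replica_floor),
                 sampling_budget = as.integer(sampling_budget),
                 fraction_method = match.arg(fraction_method)),
            class = "al_config")
}

#' Replica multiplicity
#'
#' The smallest integer `N` such that `N * n_passing >= floor`, i.e.
#' `ceiling(floor / n_passing)`.
#'
#' @param n_passing Number of molecules at or above the score threshold
#'   (must be >= 1; a zero count is signalled as a condition for the caller
#'   to handle).
#' @param floor Required minimum size of the replica part.
#' @return Integer multiplicity `N`.
#' @export
#' @examples
#' replica_multiplicity(400, 5000)  # 13
replica_multiplicity <- function(n_passing, floor = 5000L) {
  if (n_passing == 0) {
    rlang::abort("no molecules pass the score threshold",
                 class = "chemalign_no_passing")
  }
  assert_that(n_passing >= 1, "n_passing must be >= 1")
  as.integer(ceiling(floor / n_passing))
}

#' Softmax sampling fractions from mean cluster scores
#'
#' `f_i = exp(m_i) / sum_j exp(m_j)`, computed with max-subtraction so the
#' exponentials cannot overflow.  Clusters without a mean score (no scored
#' member) must be excluded before calling.
#'
#' @param mean_cluster_scores Named numeric vector of per-cluster mean
#'   scores.
#' @return Named numeric vector of fractions summing to 1.
#' @export
#' @examples
#' cluster_fractions(c(a = 0, b = log(2)))  # 1/3, 2/3
cluster_fractions <- function(mean_cluster_scores) {
  assert_that(length(mean_cluster_scores) >= 1,
              "need at least one cluster mean score")
  m <- mean_cluster_scores - max(mean_cluster_scores)
  e <- exp(m)
  e / sum(e)
}

#' Integer allocation of the sampling budget across clusters
#'
#' Initial counts come from largest-remainder rounding of
#' `fraction * budget` (so they sum exactly to the budget), then counts are
#' capped at cluster sizes and the surplus is redistributed iteratively
#' among the uncapped clusters in proportion to their fractions, until the
#' budget is met or the population is exhausted.
#'
#' @param fractions Named fractions summing to 1 (see
#'   [cluster_fractions()]).
#' @param cluster_sizes Named sizes of the same clusters.
#' @param budget Total number of molecules to allocate.
#' @return Named integer counts with `sum = min(budget, sum(sizes))` and
#'   `count_i <= size_i`.
#' @export
allocate <- function(fractions, cluster_sizes, budget) {
  assert_that(abs(sum(fractions) - 1) < 1e-8, "fractions must sum to 1")
  assert_that(all(cluster_sizes >= 0), "sizes must be >= 0")
  sizes <- cluster_sizes[names(fractions)]
  assert_that(!any(is.na(sizes)), "every fraction needs a cluster size")
  counts <- largest_remainder(fractions * budget, budget)
  counts <- pmin(counts, sizes)
  repeat {
    deficit <- min(budget, sum(sizes)) - sum(counts)
    if (deficit <= 0) break
    open <- counts < sizes
    if (!any(open)) break
    fr <- fractions[open] / sum(fractions[open])
    add <- largest_remainder(fr * deficit, deficit)
    counts[open] <- pmin(counts[open] + add, sizes[open])
  }
  storage.mode(counts) <- "integer"
  counts
}

# integer counts summing exactly to `total`, rounding down and giving the
# remainder to the largest fractional parts (ties: first index)
largest_remainder <- function(x, total) {
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Build the active-learning training set
#'
#' The replica part holds every scored molecule at or above the threshold,
#' replicated [replica_multiplicity()] times.  The sampled part draws
#' `sampling_budget` molecules without replacement from the clusters of the
#' generated ensemble, with per-cluster counts given by [allocate()] over
#' the [cluster_fractions()] of mean scored-cluster scores (or equal
#' fractions under the uniform control).  If nothing passes the threshold
#' the replica part is empty and a warning is raised.
#'
#' @param scored Tibble from [score_molecules()] with `smiles`, `score`
#'   and `cluster`.
#' @param ensemble Tibble of the full generated ensemble with `smiles` and
#'   `cluster` (see [cluster_members()]).
#' @param config An [al_config()].
#' @param seed Integer seed for the without-replacement draws.
#' @return An `al_training_set` with the replica part, sampled part, and
#'   full provenance (fractions, allocations, multiplicity, seed).
#' @export
build_al_set <- function(scored, ensemble, config, seed = 1L) {
  assert_that(all(c("smiles", "score", "cluster") %in% names(scored)),
              "scored needs smiles, score and cluster columns")
  assert_that(all(c("smiles", "cluster") %in% names(ensemble)),
              "ensemble needs smiles and cluster columns")
  passing <- scored %>% filter(.data$score >= config$score_threshold)
  if (nrow(passing) == 0) {
    rlang::warn("build_al_set: no molecules pass the threshold; replica part is empty")
    N <- 0L
  } else {
    N <- replica_multiplicity(nrow(passing), config$replica_floor)
  }
  sizes_tbl <- ensemble %>% dplyr::count(.data$cluster)
  sizes <- setNames(sizes_tbl$n, sizes_tbl$cluster)
  if (config$fraction_method == "uniform") {
    fr <- setNames(rep(1 / length(sizes), length(sizes)), names(sizes))
  } else {
    means <- scored %>%
      group_by(.data$cluster) %>%
      summarise(mean_score = mean(.data$score), .groups = "drop")
    means <- means[as.character(means$cluster) %in% names(sizes), , drop = FALSE]
    assert_that(nrow(means) >= 1, "no scored cluster overlaps the ensemble")
    fr <- cluster_fractions(setNames(means$mean_score,
                                     as.character(means$cluster)))
  }
  counts <- allocate(fr, sizes[names(fr)], config$sampling_budget)
  sampled <- with_seed(seed, {
    parts <- lapply(names(counts)[counts > 0], function(cl) {
      sub <- ensemble[as.character(ensemble$cluster) == cl, c("smiles", "cluster")]
      sub[sample.int(nrow(sub), counts[[cl]]), , drop = FALSE]
    })
    bind_rows(parts)
  })
  if (nrow(sampled) == 0) sampled <- tibble(smiles = character(0), cluster = integer(0))
  structure(
    list(replica = tibble(smiles = passing$smiles, score = passing$score,
                          multiplicity = N),
         sampled = sampled,
         fractions = fr,
         allocations = counts,
         multiplicity = N,
         config = config,
         seed = seed),
    class = "al_training_set"
  )
}

#' SMILES of an AL training set, replicas expanded
#'
#' @param x An `al_training_set`.
#' @return Character vector: each replica-part molecule repeated
#'   `multiplicity` times, followed by the sampled part.
#' @export
al_set_smiles <- function(x) {
  assert_that(inherits(x, "al_training_set"), "x must be an al_training_set")
  c(rep(x$replica$smiles, each = max(x$multiplicity, 0L)), x$sampled$smiles)
}

#' @export
print.al_training_set <- function(x, ...) {
  cat(sprintf("<al_training_set: %d passing x %d replicas + %d sampled = %d molecules>\n",
              nrow(x$replica), x$multiplicity, nrow(x$sampled),
              length(al_set_smiles(x))))
  invisible(x)
}

#' @rdname build_al_set
#' @param x An `al_training_set`.
#' @param ... Unused.
#' @method tidy al_training_set
#' @export
tidy.al_training_set <- function(x, ...) {
  tibble(cluster = names(x$fractions),
         fraction = unname(x$fractions),
         allocation = unname(x$allocations[names(x$fractions)]))
}

#' @rdname build_al_set
#' @method glance al_training_set
#' @export
glance.al_training_set <- function(x, ...) {
  tibble(n_passing = nrow(x$replica),
         multiplicity = x$multiplicity,
         n_replica = nrow(x$replica) * max(x$multiplicity, 0L),
         n_sampled = nrow(x$sampled),
         n_total = length(al_set_smiles(x)),
         score_threshold = x$config$score_threshold,
         fraction_method = x$config$fraction_method)
}
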