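# Chemical-space proxy: molecular descriptors, a one-time PCA projection,
# k-means clustering with the restart-selection rule, and stratified
# selection of molecules for scoring.

#' Descriptor providers
#'
#' A provider is a function mapping a character vector of SMILES to a data
#' frame of named numeric descriptor columns (one row per molecule, `NA`
#' rows for failures).  Two providers ship with the package:
#'
#' * `descriptor_provider_chemistry()` — toolkit properties (molecular
#'   weight, logP, TPSA, H-bond donors/acceptors, molar refractivity)
#'   plus graph-derived counts from the connectivity table (per-element
#'   heavy-atom counts, bond-order counts, ring and aromaticity measures,
#'   branching).  Slower, chemically grounded.
#' * `descriptor_provider_fast()` — token-statistics descriptors computed
#'   directly from the SMILES string (per-token-class counts, length,
#'   branching, ring closures, aromatic fraction).  Orders of magnitude
#'   faster; the default for desk-scale loop runs.
#'
#' @return A function usable as the `provider` argument of
#'   [compute_descriptors()].
#' @export
descriptor_provider_fast <- function() {
  classes <- list(
    n_C = "C", n_c = "c", n_N = c("N", "n"), n_O = c("O", "o"),
    n_S = c("S", "s"), n_F = "F", n_Cl = "Cl", n_Br = "Br", n_I = "I",
    n_branch = "(", n_double = "=", n_triple = "#", n_ring = as.character(0:9)
  )
  function(smiles) {
    rows <- lapply(smiles, function(s) {
      tk <- tryCatch(tokenize_smiles(s), error = function(e) NULL)
      if (is.null(tk)) return(rep(NA_real_, length(classes) + 4))
      counts <- vapply(classes, function(cl) sum(tk %in% cl), numeric(1))
      bracket <- sum(grepl("^\\[", tk))
      n_atoms <- sum(tk %in% unlist(classes[1:9])) + bracket
      arom <- sum(tk %in% c("c", "n", "o", "s"))
      c(counts, n_tokens = length(tk), n_bracket = bracket,
        n_heavy = n_atoms, frac_aromatic = if (n_atoms > 0) arom / n_atoms else 0)
    })
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- c(names(classes), "n_tokens", "n_bracket", "n_heavy",
                   "frac_aromatic")
    df
  }
}

#' @rdname descriptor_provider_fast
#' @export
descriptor_provider_chemistry <- function() {
  function(smiles) {
    nm <- paste0("q", seq_along(smiles))
    sdf <- tryCatch(smiles_to_sdf(smiles, nm), error = function(e) NULL)
    out <- matrix(NA_real_, length(smiles), 0)
    prop_cols <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
    graph_cols <- c("n_atoms", "n_bonds", "n_single", "n_double", "n_triple",
                    "n_aromatic_bonds", "n_rings", "mean_degree",
                    "max_degree", "n_C", "n_N", "n_O", "n_S", "n_halogen")
    res <- as.data.frame(matrix(NA_real_, length(smiles),
                                length(prop_cols) + length(graph_cols)))
    names(res) <- c(prop_cols, graph_cols)
    if (is.null(sdf) || length(sdf) == 0) return(res)
    idx <- match(ChemmineR::sdfid(sdf), nm)
    props <- ChemmineR::propOB(sdf)
    res[idx, prop_cols] <- props[, prop_cols]
    gs <- lapply(seq_along(ChemmineR::cid(sdf)), function(i) {
      ab <- ChemmineR::atomblock(sdf[[i]])
      bb <- ChemmineR::bondblock(sdf[[i]])
      el <- gsub("_.*$", "", rownames(ab))
      ord <- bb[, 3]
      deg <- tabulate(c(bb[, 1], bb[, 2]), nbins = nrow(ab))
      c(n_atoms = nrow(ab), n_bonds = nrow(bb),
        n_single = sum(ord == 1), n_double = sum(ord == 2),
        n_triple = sum(ord == 3), n_aromatic_bonds = sum(ord == 4),
        n_rings = nrow(bb) - nrow(ab) + 1,
        mean_degree = mean(deg), max_degree = max(deg),
        n_C = sum(el == "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
        n_S = sum(el == "S"),
        n_halogen = sum(el %in% c("F", "Cl", "Br", "I")))
    })
    res[idx, graph_cols] <- do.call(rbind, gs)
    res
  }
}

#' Compute a descriptor matrix
#'
#' Runs the provider and cleans the result: any descriptor column that is
#' non-finite for at least one molecule is dropped (names recorded in the
#' `dropped_descriptors` attribute), and molecules for which the provider
#' fails entirely are removed with a warning.
#'
#' @param molecules Character vector of SMILES or tibble with `smiles`.
#' @param provider A descriptor provider (see
#'   [descriptor_provider_fast()]), or any function
#'   `smiles -> data.frame`.
#' @return Tibble with `smiles` plus one column per retained descriptor;
#'   all values finite.
#' @export
compute_descriptors <- function(molecules, provider = descriptor_provider_fast()) {
  if (is.data.frame(molecules)) molecules <- molecules$smiles
  raw <- as.data.frame(provider(molecules))
  assert_that(nrow(raw) == length(molecules),
              "provider must return one row per molecule")
  all_na <- apply(raw, 1, function(r) all(!is.finite(as.numeric(r))))
  if (any(all_na)) {
    rlang::warn(sprintf("compute_descriptors: dropping %d molecule(s) the provider failed on",
                        sum(all_na)))
  }
  raw <- raw[!all_na, , drop = FALSE]
  molecules <- molecules[!all_na]
  finite_col <- vapply(raw, function(x) all(is.finite(as.numeric(x))), logical(1))
  dropped <- names(raw)[!finite_col]
  out <- bind_cols(tibble(smiles = molecules),
                   as_tibble(raw[, finite_col, drop = FALSE]))
  attr(out, "dropped_descriptors") <- dropped
  out
}

# ---- PCA projection --------------------------------------------------------

#' Fit the chemical-space projection
#'
#' A one-time PCA of the descriptor matrix of a reference set (normally the
#' pretraining corpus).  The fitted model is immutable: all later ensembles
#' are projected with the same centering/scaling constants and loadings, so
#' coordinates are comparable across iterations.
#'
#' @param descriptors A [compute_descriptors()] tibble (or plain numeric
#'   matrix/data frame).
#' @param n_components Number of principal components retained (full-scale
#'   default 120; capped at the matrix rank).
#' @param scale Standardize each descriptor to unit variance before PCA
#'   (default `TRUE`; descriptors have wildly different units).
#' @return A `chem_projection` with loadings, centering/scaling constants,
#'   explained-variance ratios and the retained descriptor names.
#' @export
fit_projection <- function(descriptors, n_components = 120L, scale = TRUE) {
  X <- coord_matrix(descriptors)
  assert_that(all(is.finite(X)), "descriptor matrix must be finite")
  assert_that(nrow(X) >= 2,
              "fit_projection: need at least 2 rows for any n_components")
  n_components <- min(n_components, ncol(X))
  assert_that(nrow(X) >= n_components,
              "need at least n_components rows to fit the projection")
  # constant columns carry no information and break unit scaling
  sds <- apply(X, 2, stats::sd)
  keep <- !is.na(sds) & sds > 0
  X <- X[, keep, drop = FALSE]
  n_components <- min(n_components, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  k <- min(n_components, ncol(pc$rotation))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(descriptors = colnames(X),
         center = pc$center,
         scale = if (scale) pc$scale else NULL,
         loadings = pc$rotation[, seq_len(k), drop = FALSE],
         sdev = pc$sdev[seq_len(k)],
         explained_variance_ratio = evr[seq_len(k)],
         n_components = k),
    class = "chem_projection"
  )
}

#' @export
print.chem_projection <- function(x, ...) {
  cat(sprintf("<chem_projection: %d descriptors -> %d components (%.1f%% variance)>\n",
              length(x$descriptors), x$n_components,
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' @rdname fit_projection
#' @param x A `chem_projection`.
#' @param ... Unused.
#' @method tidy chem_projection
#' @export
tidy.chem_projection <- function(x, ...) {
  tibble(component = seq_len(x$n_components),
         sdev = x$sdev,
         explained_variance_ratio = x$explained_variance_ratio)
}

#' Project descriptors into the chemical-space proxy
#'
#' @param model A fitted [fit_projection()].
#' @param descriptors Descriptor tibble whose columns include all of the
#'   model's retained descriptors (extra columns are ignored).
#' @return Tibble with `smiles` (if present in the input) and `PC1..PCk`.
#' @export
project <- function(model, descriptors) {
  assert_that(inherits(model, "chem_projection"), "model must be a chem_projection")
  sm <- if (is.data.frame(descriptors) && "smiles" %in% names(descriptors)) {
    descriptors$smiles
  } else NULL
  X <- coord_matrix(descriptors)
  missing <- setdiff(model$descriptors, colnames(X))
  assert_that(length(missing) == 0,
              paste0("missing descriptor column(s): ",
                     paste(missing, collapse = " ")))
  X <- X[, model$descriptors, drop = FALSE]
  X <- sweep(X, 2, model$center)
  if (!is.null(model$scale)) X <- sweep(X, 2, model$scale, "/")
  Y <- X %*% model$loadings
  out <- as_tibble(as.data.frame(Y))
  names(out) <- paste0("PC", seq_len(ncol(Y)))
  if (!is.null(sm)) out <- bind_cols(tibble(smiles = sm), out)
  out
}

# ---- clustering ------------------------------------------------------------

# seeded k-means++ initial centers
kmeanspp_centers <- function(X, k, seed) {
  with_seed(seed, {
    n <- nrow(X)
    centers <- matrix(NA_real_, k, ncol(X))
    i <- sample.int(n, 1)
    centers[1, ] <- X[i, ]
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in seq_len(k - 1) + 1) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(p) <= 0) p <- rep(1 / n, n)
      i <- sample.int(n, 1, prob = p)
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
    centers
  })
}

#' Cluster molecules in the chemical-space proxy
#'
#' Runs k-means `n_restarts` times with seeded k-means++ initialisations
#' (restart `r` uses `seed + r`).  Among the five lowest-inertia runs, the
#' one with the smallest variance in cluster size is returned; ties break
#' toward lower inertia, then lower run index.
#'
#' @param coordinates Projected coordinates ([project()] tibble or matrix).
#' @param k Number of clusters (full-scale default 100).
#' @param n_restarts Number of seeded restarts (default 100).
#' @param seed Base seed.
#' @param top_runs How many lowest-inertia runs enter the size-variance
#'   stage (default 5).
#' @return A `chem_clustering` with per-molecule labels, centroids,
#'   inertia, cluster-size variance and restart provenance.
#' @export
cluster_molecules <- function(coordinates, k = 100L, n_restarts = 100L,
                              seed = 1L, top_runs = 5L) {
  sm <- if (is.data.frame(coordinates) && "smiles" %in% names(coordinates)) {
    coordinates$smiles
  } else NULL
  X <- coord_matrix(coordinates)
  assert_that(nrow(X) >= k,
              sprintf("need at least k = %d rows, got %d", k, nrow(X)))
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(X, k, seed + r)
    km <- suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 50))
    sizes <- tabulate(km$cluster, nbins = k)
    runs[[r]] <- list(km = km, inertia = km$tot.withinss,
                      size_var = pop_var(sizes))
  }
  inertia <- vapply(runs, `[[`, numeric(1), "inertia")
  size_var <- vapply(runs, `[[`, numeric(1), "size_var")
  top <- order(inertia)[seq_len(min(top_runs, n_restarts))]
  chosen <- top[order(size_var[top], inertia[top], top)][1]
  km <- runs[[chosen]]$km
  structure(
    list(k = as.integer(k),
         labels = km$cluster,
         smiles = sm,
         centroids = km$centers,
         inertia = km$tot.withinss,
         size_variance = runs[[chosen]]$size_var,
         restarts = tibble(run = seq_len(n_restarts), inertia = inertia,
                           size_variance = size_var),
         chosen_run = chosen,
         chosen_rank = match(chosen, order(inertia)),
         seed = seed),
    class = "chem_clustering"
  )
}

pop_var <- function(x) mean((x - mean(x))^2)

#' @export
print.chem_clustering <- function(x, ...) {
  cat(sprintf("<chem_clustering: k=%d, n=%d, inertia=%.3g, size-variance=%.3g (run %d of %d)>\n",
              x$k, length(x$labels), x$inertia, x$size_variance,
              x$chosen_run, nrow(x$restarts)))
  invisible(x)
}

#' @rdname cluster_molecules
#' @param x A `chem_clustering`.
#' @param ... Unused.
#' @method tidy chem_clustering
#' @export
tidy.chem_clustering <- function(x, ...) {
  sizes <- tabulate(x$labels, nbins = x$k)
  tibble(cluster = seq_len(x$k), size = sizes)
}

#' @rdname cluster_molecules
#' @method glance chem_clustering
#' @export
glance.chem_clustering <- function(x, ...) {
  tibble(k = x$k, n = length(x$labels), inertia = x$inertia,
         size_variance = x$size_variance, chosen_run = x$chosen_run,
         chosen_rank = x$chosen_rank, n_restarts = nrow(x$restarts))
}

#' Cluster membership as a tibble
#'
#' @param clustering A `chem_clustering`.
#' @param smiles Optional molecule identifiers (defaults to those stored
#'   with the clustering).
#' @return Tibble with `smiles` and `cluster`.
#' @export
cluster_members <- function(clustering, smiles = NULL) {
  smiles <- smiles %||% clustering$smiles
  assert_that(!is.null(smiles), "no molecule identifiers available")
  tibble(smiles = smiles, cluster = clustering$labels)
}

#' Select a cluster-stratified subset for scoring
#'
#' First pass: up to `per_cluster_cap` molecules drawn at random from every
#' cluster (all members when a cluster is smaller than the cap).  Top-up
#' pass: if the running total is below `total`, additional molecules are
#' drawn uniformly from the not-yet-selected members of clusters larger
#' than the cap until `total` is reached or the population is exhausted.
#'
#' @param clustering A `chem_clustering`.
#' @param molecules Molecule identifiers aligned with the clustering (or
#'   `NULL` to use those stored in it).
#' @param per_cluster_cap First-pass per-cluster cap (full-scale default
#'   10).
#' @param total Target subset size (full-scale default 1000).
#' @param seed Integer seed.
#' @return Tibble with `smiles` and `cluster` of the selected subset.
#' @export
select_for_scoring <- function(clustering, molecules = NULL,
                               per_cluster_cap = 10L, total = 1000L,
                               seed = 1L) {
  assert_that(per_cluster_cap >= 1, "per_cluster_cap must be >= 1")
  assert_that(total >= 1, "total must be >= 1")
  mem <- cluster_members(clustering, molecules)
  with_seed(seed, {
    first <- mem %>%
      group_by(.data$cluster) %>%
      mutate(.r = sample.int(n())) %>%
      ungroup() %>%
      filter(.data$.r <= per_cluster_cap) %>%
      select(-".r")
    if (nrow(first) < total) {
      sizes <- table(mem$cluster)
      eligible <- names(sizes)[sizes > per_cluster_cap]
      pool <- mem %>%
        filter(.data$cluster %in% as.integer(eligible),
               !(.data$smiles %in% first$smiles))
      need <- min(total - nrow(first), nrow(pool))
      extra <- pool[sample.int(nrow(pool), need), , drop = FALSE]
      first <- bind_rows(first, extra)
    }
  })
  if (nrow(first) < total) {
    rlang::warn(sprintf("select_for_scoring: only %d of %d molecules available",
                        nrow(first), total))
  }
  arrange(first, .data$cluster, .data$smiles)
}
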