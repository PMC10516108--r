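test_that("descriptor computation drops non-finite columns and failed molecules", {
  prov_bad <- function(smiles) {
    data.frame(a = seq_along(smiles), b = NA_real_, c = rep(1, length(smiles)))
  }
  d <- compute_descriptors(c("CCO", "CCN"), prov_bad)
  expect_setequal(setdiff(names(d), "smiles"), c("a", "c"))
  expect_equal(attr(d, "dropped_descriptors"), "b")
  # all-finite provider keeps all columns
  d2 <- compute_descriptors(c("CCO", "CCN"), function(s)
    data.frame(a = nchar(s), b = seq_along(s)))
  expect_setequal(setdiff(names(d2), "smiles"), c("a", "b"))
  # provider values pass through unchanged
  oracle <- function(s) data.frame(len = nchar(s), ox = as.numeric(grepl("O", s)))
  d3 <- compute_descriptors(c("CCO", "CC", "CCCO"), oracle)
  expect_equal(d3$len, c(3, 2, 4))
  expect_equal(d3$ox, c(1, 0, 1))
  # molecules the provider fails on entirely are removed with a warning
  prov_fail <- function(s) {
    out <- data.frame(a = nchar(s), b = seq_along(s))
    out[2, ] <- NA_real_
    out
  }
  expect_warning(d4 <- compute_descriptors(c("CCO", "CC", "CCC"), prov_fail),
                 "dropping 1")
  expect_equal(nrow(d4), 2L)
  # shipped providers return finite values on the toy corpus
  df <- compute_descriptors(micro_corpus[1:10], descriptor_provider_fast())
  expect_true(all(vapply(df[-1], function(x) all(is.finite(x)), logical(1))))
  dc <- compute_descriptors(micro_corpus[1:5], descriptor_provider_chemistry())
  expect_true(all(vapply(dc[-1], function(x) all(is.finite(x)), logical(1))))
  expect_true(all(c("MW", "logP", "TPSA") %in% names(dc)))
})

test_that("projection matches an eigendecomposition oracle", {
  set.seed(31)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(rnorm(36), 6, 6)
  d <- bind_cols(tibble::tibble(smiles = paste0("m", 1:200)),
                 tibble::as_tibble(as.data.frame(X)))
  pj <- fit_projection(d, n_components = 6, scale = FALSE)
  # oracle: eigendecomposition of the covariance matrix
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(pj$sdev^2, ev$values[1:6], tolerance = 1e-8)
  expect_equal(abs(diag(t(pj$loadings) %*% ev$vectors)), rep(1, 6),
               tolerance = 1e-6)
  # explained variance ratios are non-increasing and sum to <= 1
  expect_true(all(diff(pj$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pj$explained_variance_ratio), 1 + 1e-9)
  # per-component variance of the projected fit data equals the eigenvalue
  co <- project(pj, d)
  vars <- apply(chemalign:::coord_matrix(co), 2, var)
  expect_equal(unname(vars), ev$values[1:6], tolerance = 1e-8)
  # projecting the mean row lands on the origin
  mrow <- d[1, ]
  mrow[1, -1] <- as.list(colMeans(X))
  expect_equal(unname(as.matrix(project(pj, mrow)[, -1])),
               matrix(0, 1, 6), tolerance = 1e-8)
  # loadings are orthonormal
  expect_equal(t(pj$loadings) %*% pj$loadings, diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("projection handles degenerate geometry, errors, and row order", {
  line <- tibble::tibble(smiles = paste0("m", 1:50),
                         x = 1:50, y = 2 * (1:50))
  pj <- fit_projection(line, n_components = 2)
  expect_equal(pj$explained_variance_ratio[1], 1, tolerance = 1e-10)
  # the requested component count caps at the column count, but can never
  # exceed the number of rows
  expect_error(fit_projection(line[1, ], n_components = 2), "n_components")
  expect_equal(fit_projection(line[1:3, ], n_components = 5)$n_components, 2L)
  d <- compute_descriptors(micro_corpus, descriptor_provider_fast())
  pj2 <- fit_projection(d, n_components = 5)
  expect_error(project(pj2, d[, 1:3]), "missing descriptor")
  # row-order invariance and determinism
  a <- project(pj2, d)
  b <- project(pj2, d[rev(seq_len(nrow(d))), ])
  expect_equal(a[order(a$smiles), ], b[order(b$smiles), ], ignore_attr = TRUE)
  expect_identical(project(pj2, d), project(pj2, d))
})

test_that("two well-separated blobs are recovered exactly by clustering", {
  set.seed(8)
  X <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
             matrix(rnorm(12, 10, 0.1), 6, 2))
  cl <- cluster_molecules(X, k = 2, n_restarts = 10, seed = 3)
  expect_equal(length(unique(cl$labels[1:6])), 1L)
  expect_equal(length(unique(cl$labels[7:12])), 1L)
  expect_false(cl$labels[1] == cl$labels[7])
  # k = 1: one cluster, zero size variance, inertia = total scatter
  cl1 <- cluster_molecules(X, k = 1, n_restarts = 3, seed = 3)
  expect_equal(cl1$size_variance, 0)
  expect_equal(cl1$inertia, sum(scale(X, scale = FALSE)^2), tolerance = 1e-8)
  expect_error(cluster_molecules(X[1:3, ], k = 5), "at least k")
})

test_that("restart selection keeps a low-inertia, low-size-variance clustering", {
  d <- compute_descriptors(micro_corpus, descriptor_provider_fast())
  co <- project(fit_projection(d, 5), d)
  cl <- cluster_molecules(co, k = 8, n_restarts = 20, seed = 17)
  expect_equal(sort(unique(cl$labels)), 1:8)
  expect_length(cl$labels, nrow(co))
  rk <- cl$restarts
  top5 <- order(rk$inertia)[1:5]
  expect_lte(cl$inertia, sort(rk$inertia)[5])
  expect_equal(cl$size_variance, min(rk$size_variance[top5]))
  expect_true(cl$chosen_run %in% top5)
  # same seed reproduces the same clustering
  cl2 <- cluster_molecules(co, k = 8, n_restarts = 20, seed = 17)
  expect_identical(cl$labels, cl2$labels)
})

test_that("scored-subset selection respects caps, totals and top-up rules", {
  # synthetic clustering: 12 clusters of 30 + 3 small clusters
  labels <- c(rep(1:12, each = 30), rep(13:15, each = 4))
  ids <- paste0("m", seq_along(labels))
  cl <- structure(list(k = 15L, labels = labels, smiles = ids),
                  class = "chem_clustering")
  # first pass alone gives 12 x 10 + 3 x 4 = 132 > total, so the
  # first-pass selection is returned unreduced
  sel <- select_for_scoring(cl, per_cluster_cap = 10, total = 100, seed = 2)
  expect_equal(nrow(sel), 132L)
  expect_false(anyDuplicated(sel$smiles) > 0)
  sizes <- table(sel$cluster)
  # small clusters fully taken, big clusters capped
  expect_true(all(sizes[as.character(13:15)] == 4))
  expect_true(all(sizes[as.character(1:12)] == 10))
  # with a larger total the top-up draws only from clusters above the cap
  sel_up <- select_for_scoring(cl, per_cluster_cap = 10, total = 200,
                               seed = 2)
  expect_equal(nrow(sel_up), 200L)
  up_sizes <- table(sel_up$cluster)
  expect_true(all(up_sizes[as.character(13:15)] == 4))
  expect_true(all(up_sizes[as.character(1:12)] >= 10))
  # population smaller than the target: everything returned with a warning
  small <- structure(list(k = 2L, labels = rep(1:2, each = 10),
                          smiles = paste0("s", 1:20)),
                     class = "chem_clustering")
  expect_warning(sel2 <- select_for_scoring(small, per_cluster_cap = 5,
                                            total = 50, seed = 1),
                 "only")
  expect_equal(nrow(sel2), 20L)
  # deterministic under a fixed seed
  expect_identical(select_for_scoring(cl, per_cluster_cap = 10, total = 100,
                                      seed = 5),
                   select_for_scoring(cl, per_cluster_cap = 10, total = 100,
                                      seed = 5))
})
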