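test_that("toy corpora are unique, valid and reproducible", {
  c10 <- make_corpus(10, seed = 4)
  expect_length(c10, 10L)
  expect_false(anyDuplicated(c10) > 0)
  expect_true(all(is_valid_smiles(c10)))
  expect_identical(c10, make_corpus(10, seed = 4))
  expect_false(identical(c10, make_corpus(10, seed = 5)))
  expect_length(make_corpus(1, seed = 1), 1L)
  expect_error(make_corpus(1e6, seed = 1), "exceeds the enumerable space")
  # token lengths span a range (so the length cutoff is exercised)
  lens <- vapply(make_corpus(200, seed = 2),
                 function(s) length(tokenize_smiles(s)), integer(1))
  expect_gt(max(lens) - min(lens), 5L)
})

test_that("the surrogate score is a calibrated Gaussian in the proxy", {
  d <- compute_descriptors(micro_corpus, descriptor_provider_fast())
  pj <- fit_projection(d, 5)
  co <- project(pj, d)
  sc <- calibrate_surrogate(co, threshold = 11, top_fraction = 0.25, seed = 2)
  ss <- surrogate_score(micro_corpus, sc, pj)
  # calibration: about a quarter of the reference ensemble reaches the
  # threshold (quantile granularity on 120 molecules)
  expect_equal(threshold_fraction(ss$score, 11), 25, tolerance = 0.1)
  # the molecule defining the target scores the maximum
  expect_equal(max(ss$score), sc$max_score, tolerance = 1e-9)
  # pseudo-profile reproduces the score to integer granularity
  expect_true(all(abs(ss$van_der_waals - ss$score) <= 0.5 + 1e-9))
  expect_equal(score_profile(ss[, INTERACTION_TYPES]), ss$van_der_waals)
  # monotone decay with distance from the target (ties allowed)
  X <- chemalign:::coord_matrix(project(pj, d))[, seq_along(sc$target), drop = FALSE]
  dist <- sqrt(rowSums(sweep(X, 2, sc$target)^2))
  expect_true(all(diff(ss$score[order(dist)]) <= 1e-9))
  expect_equal(cor(ss$score, dist, method = "spearman"), -1,
               tolerance = 1e-6)
})

test_that("nearby molecules in the proxy have similar surrogate scores", {
  # Lipschitz-style finite-difference check on the score surface
  sc <- surrogate_scorer(target = c(0, 0), length_scale = 2, max_score = 50)
  f <- function(x) 50 * exp(-sum(x^2) / (2 * 4))
  # the scorer's own functional form, probed on a grid of displacements
  set.seed(6)
  for (i in 1:50) {
    x <- rnorm(2, sd = 3)
    h <- rnorm(2, sd = 0.01)
    # bound |f(x+h)-f(x)| by L * ||h|| with L = max|grad| = max_score/(scale*exp(.5))
    L <- 50 / (2 * exp(0.5))
    expect_lte(abs(f(x + h) - f(x)), L * sqrt(sum(h^2)) * (1 + 1e-6))
  }
  expect_error(surrogate_scorer(c(0, 0), length_scale = -1, max_score = 1),
               "positive")
})

test_that("surrogate noise is deterministic per molecule", {
  d <- compute_descriptors(micro_corpus[1:10], descriptor_provider_fast())
  pj <- fit_projection(d, 3)
  sc <- surrogate_scorer(target = rep(0, 3), length_scale = 2, max_score = 30,
                         noise_sd = 1, noise_seed = 9)
  a <- surrogate_score(micro_corpus[1:10], sc, pj)
  b <- surrogate_score(micro_corpus[10:1], sc, pj)
  m <- match(a$smiles, b$smiles)
  expect_equal(a$score, b$score[m])
})

test_that("the surrogate pose provider drives score_molecules", {
  d <- compute_descriptors(micro_corpus, descriptor_provider_fast())
  pj <- fit_projection(d, 5)
  sc <- calibrate_surrogate(project(pj, d), threshold = 11, seed = 3)
  pp <- surrogate_pose_provider(sc, pj)
  scored <- score_molecules(micro_corpus[1:20], pp)
  oracle <- surrogate_score(micro_corpus[1:20], sc, pj)
  expect_equal(scored$score, oracle$van_der_waals * 1.0)
  expect_equal(scored$smiles, micro_corpus[1:20])
})
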