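test_that("threshold attainment is inclusive and monotone in the threshold", {
  expect_equal(threshold_fraction(c(10, 11, 12), 11), 100 * 2 / 3)
  expect_equal(threshold_fraction(c(1, 2, 3), 10), 0)
  expect_equal(threshold_fraction(c(5, 7, 9), 5), 100)
  expect_error(threshold_fraction(numeric(0), 1), "empty")
  set.seed(2)
  s <- rnorm(200, 10, 5)
  ths <- sort(runif(20, 0, 20))
  fr <- vapply(ths, threshold_fraction, numeric(1), scores = s)
  expect_true(all(diff(fr) <= 0))
})

test_that("score summaries match a brute-force recomputation", {
  expect_equal(score_summary(c(1, 2, 3)), tibble::tibble(mean = 2, max = 3))
  expect_equal(score_summary(7.5), tibble::tibble(mean = 7.5, max = 7.5))
  set.seed(4)
  for (i in 1:20) {
    s <- runif(sample(1:50, 1), 0, 100)
    sm <- score_summary(s)
    expect_equal(sm$mean, sum(s) / length(s))
    expect_equal(sm$max, sort(s, decreasing = TRUE)[1])
  }
})

test_that("similarity profiles behave for identical and disjoint molecules", {
  refs <- micro_corpus[c(3, 17)]
  # a reference included in the generated set has max similarity 1
  prof <- similarity_profile(c(refs[1], micro_corpus[5:8]), refs)
  expect_equal(prof$best_tanimoto[1], 1)
  expect_equal(prof$best_match[1], refs[1])
  expect_true(all(prof$mean_tanimoto >= 0 & prof$mean_tanimoto <= 1))
  # generated set = the single reference: mean similarity exactly 1
  p1 <- similarity_profile(refs[1], refs[1])
  expect_equal(p1$mean_tanimoto, 1)
  # both fingerprint dialects work and lie in [0, 1]
  pp <- similarity_profile(micro_corpus[1:10], refs, "path")
  expect_true(all(pp$mean_tanimoto >= 0 & pp$mean_tanimoto <= 1))
  # permutation invariance over the generated set
  a <- similarity_profile(micro_corpus[1:10], refs)
  b <- similarity_profile(micro_corpus[10:1], refs)
  expect_equal(a$mean_tanimoto, b$mean_tanimoto)
})

test_that("tanimoto agrees with the toolkit similarity on path fingerprints", {
  sm <- micro_corpus[1:8]
  bits <- fingerprint_bits(sm, "path")
  sdf <- ChemmineR::smiles2sdf(setNames(sm, paste0("f", 1:8)))
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  for (i in 1:4) {
    for (j in 5:8) {
      ours <- tanimoto(bits[[i]], bits[[j]])
      ref <- ChemmineR::fpSim(fp[i], fp[j], method = "Tanimoto",
                              sorted = FALSE, addone = 0)
      expect_equal(ours, unname(ref), tolerance = 1e-12)
    }
  }
})

test_that("circular fingerprints separate structure sensibly", {
  b <- fingerprint_bits(c("CCO", "CCO", "CCCCCCCC", "c1ccccc1"), "circular")
  expect_identical(b[[1]], b[[2]])
  expect_equal(tanimoto(b[[1]], b[[1]]), 1)
  expect_lt(tanimoto(b[[1]], b[[4]]), 0.5)
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  expect_equal(tanimoto(c(1L, 5L), c(7L, 9L)), 0)
})

test_that("exact recovery intersects by canonical form", {
  gen <- c("OCC", "CCN")
  refs <- c("CCO", "CCC")
  expect_equal(exact_recovery(gen, refs), canonical_smiles("CCO"))
  expect_length(exact_recovery("CCC", "CCO"), 0L)
  expect_setequal(exact_recovery(micro_corpus, micro_corpus[4:6]),
                  micro_corpus[4:6])
})
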