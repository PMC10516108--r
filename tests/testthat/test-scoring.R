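test_that("single-contact profiles score at the handpicked weights", {
  w <- interaction_weights()
  expect_equal(score_profile(interaction_profile(hydrophobic = 1)), 2.5)
  expect_equal(score_profile(interaction_profile(hydrogen_bond = 1)), 3.5)
  expect_equal(score_profile(interaction_profile(ionic = 1)), 7.5)
  expect_equal(score_profile(interaction_profile(cation_pi = 1)), 2.5)
  expect_equal(score_profile(interaction_profile(van_der_waals = 1)), 1.0)
  expect_equal(score_profile(interaction_profile(halogen_bond = 1)), 3.0)
  expect_equal(score_profile(interaction_profile(pi_stack_face = 1)), 3.0)
  expect_equal(score_profile(interaction_profile(pi_stack_edge = 1)), 1.0)
  expect_equal(score_profile(interaction_profile(metallic = 1)), 3.0)
  expect_equal(score_profile(interaction_profile()), 0)
  expect_equal(score_profile(interaction_profile(hydrophobic = 2, ionic = 1)),
               12.5)
  expect_error(interaction_profile(banana = 1), "unknown")
  expect_error(interaction_weights(banana = 1), "unknown")
})

test_that("the score is additive, homogeneous and nonnegative", {
  set.seed(77)
  w <- interaction_weights()
  for (i in 1:200) {
    p1 <- random_profile()
    p2 <- random_profile()
    # brute-force oracle: explicit loop over types
    oracle <- 0
    for (ty in INTERACTION_TYPES) oracle <- oracle + p1[[ty]] * w[[ty]]
    expect_equal(score_profile(p1), oracle)
    expect_equal(score_profile(p1 + p2), score_profile(p1) + score_profile(p2))
    expect_equal(score_profile(p1, 2 * w), 2 * score_profile(p1))
    expect_gte(score_profile(p1), 0)
  }
  # data-frame route agrees with the scalar route
  df <- dplyr::bind_rows(lapply(1:20, function(i)
    tibble::as_tibble(as.list(random_profile()))))
  expect_equal(score_profile(df),
               vapply(seq_len(20), function(i)
                 score_profile(unlist(df[i, ])), numeric(1)))
})

test_that("threshold derivation returns the minimum reference score", {
  expect_equal(derive_threshold(c(40, 37, 55.5)), 37)
  expect_equal(derive_threshold(11), 11)
  expect_equal(derive_threshold(sample(c(40, 37, 55.5))), 37)
  expect_error(derive_threshold(numeric(0)), "at least one")
})

test_that("score_molecules preserves order, carries columns, reports failures", {
  prof <- dplyr::bind_cols(
    tibble::tibble(smiles = c("A", "B", "C")),
    chemalign:::empty_profile_tbl(3))
  prof$hydrogen_bond <- c(1L, 0L, 2L)
  pp <- profile_pose_provider(prof)
  mols <- tibble::tibble(smiles = c("C", "A", "D"), cluster = c(5L, 2L, 9L))
  expect_warning(sc <- score_molecules(mols, pp), "failed on 1")
  expect_equal(sc$smiles, c("C", "A"))
  expect_equal(sc$score, c(7, 3.5))
  expect_equal(sc$cluster, c(5L, 2L))
  expect_equal(attr(sc, "failures"), "D")
  # provider returning empty profiles scores everything 0
  zero <- pose_provider(function(s)
    dplyr::bind_cols(tibble::tibble(smiles = s),
                     chemalign:::empty_profile_tbl(length(s))))
  sc0 <- score_molecules(c("X", "Y"), zero)
  expect_equal(sc0$score, c(0, 0))
  expect_error(score_molecules(c("A", "A"), zero), "unique")
})

test_that("profiles round-trip through CSV", {
  prof <- dplyr::bind_cols(tibble::tibble(smiles = c("CCO", "CCN")),
                           chemalign:::empty_profile_tbl(2))
  prof$ionic <- c(1L, 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(prof, path)
  pp <- profile_pose_provider(path)
  sc <- score_molecules("CCO", pp)
  expect_equal(sc$score, 7.5)
})
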