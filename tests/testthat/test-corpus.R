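test_that("tokenization follows the SMILES grammar and round-trips", {
  expect_equal(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_equal(tokenize_smiles("CCl"), c("C", "Cl"))
  expect_equal(tokenize_smiles("C(=O)O"), c("C", "(", "=", "O", ")", "O"))
  expect_equal(tokenize_smiles("C[nH]1ccc1"),
               c("C", "[nH]", "1", "c", "c", "c", "1"))
  expect_equal(tokenize_smiles("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_error(tokenize_smiles("CXO"), "offset")
  # round-trip over the whole synthetic corpus
  for (s in micro_corpus) {
    expect_identical(paste(tokenize_smiles(s), collapse = ""), s)
  }
})

test_that("canonicalization drops invalid strings and is order-independent", {
  out <- canonicalize_filter(c("CCO", "OCC", "C("))
  expect_equal(out$smiles, "CCO")
  rep <- attr(out, "report")
  expect_equal(rep$n_invalid, 1L)
  expect_equal(rep$n_duplicate, 1L)
  expect_equal(nrow(canonicalize_filter(character(0))), 0L)
  expect_equal(nrow(canonicalize_filter(c("c1ccccc1", "c1ccccc1"))), 1L)
  # order independence
  a <- canonicalize_filter(micro_corpus)
  b <- canonicalize_filter(rev(micro_corpus))
  expect_identical(a$smiles, b$smiles)
  # strictness: unbalanced ring bond and branch are invalid
  expect_false(is_valid_smiles("C1CC"))
  expect_false(is_valid_smiles("C(C"))
  expect_true(is_valid_smiles("C1CC1"))
  # the independent parser route agrees on validity of the corpus
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(micro_corpus[1:10],
                                                         paste0("x", 1:10))))
  expect_equal(sum(ChemmineR::validSDF(sdf)), 10L)
})

test_that("idempotence: re-canonicalizing canonical output is the identity", {
  once <- canonicalize_filter(micro_corpus)
  twice <- canonicalize_filter(once)
  expect_identical(once$smiles, twice$smiles)
})

test_that("rare-token pruning uses pre-pruning counts and reports totals", {
  # corpus-wide counts: C 9, O 2, N 1, [Se] 1 -> strings containing N or
  # [Se] are removed at min_count = 2
  pr <- prune_rare_tokens(c("CCO", "CCN", "CCOC", "C[Se]C"), min_count = 2)
  expect_setequal(pr$corpus$smiles, c("CCO", "CCOC"))
  expect_setequal(pr$report$removed_tokens, c("N", "[Se]"))
  expect_equal(pr$report$n_removed + pr$report$n_retained, pr$report$n_input)
  # min_count = 1 keeps everything
  pr1 <- prune_rare_tokens(micro_corpus, min_count = 1)
  expect_equal(nrow(pr1$corpus), length(micro_corpus))
  # everything removed is reported, not fatal
  expect_warning(pr0 <- prune_rare_tokens("C[Se]C", min_count = 2),
                 "all strings removed")
  expect_equal(nrow(pr0$corpus), 0L)
  # vocabulary has contiguous 0-based indices with the three specials first
  v <- pr$vocabulary
  expect_identical(unname(v$index[v$tokens]), seq_along(v$tokens) - 1L)
  expect_identical(v$tokens[1:3], c("<", "!", "~"))
})

test_that("length cutoff is the smallest length covering the requested fraction", {
  corp <- c("CC", "CCC", "CCCC", strrep("C", 50))
  lc <- length_cutoff(corp, coverage = 0.75)
  expect_equal(lc$cutoff, 4L)
  expect_equal(nrow(lc$corpus), 3L)
  # coverage 1 keeps everything
  lc1 <- length_cutoff(corp, coverage = 1)
  expect_equal(lc1$cutoff, 50L)
  expect_equal(nrow(lc1$corpus), 4L)
  # all equal lengths
  lc2 <- length_cutoff(c("CC", "CO", "CN"), coverage = 0.5)
  expect_equal(lc2$cutoff, 2L)
  expect_error(length_cutoff(character(0), 0.9), "empty")
  # exhaustive check against the definition on the synthetic corpus
  lens <- vapply(micro_corpus, function(s) length(tokenize_smiles(s)),
                 integer(1))
  for (cov in c(0.5, 0.9, 0.99)) {
    L <- length_cutoff(micro_corpus, cov)$cutoff
    expect_gte(mean(lens <= L), cov)
    if (L > min(lens)) {
      below <- max(lens[lens < L])
      expect_lt(mean(lens <= below), cov)
    }
  }
})

test_that("encoding adds specials, pads to fixed length, and inverts exactly", {
  v <- token_vocabulary(c("CCO", "CCN"))
  e <- encode_smiles("CCO", v, max_len = 5)
  expect_length(e, 7L)
  expect_equal(e[1], unname(v$index["!"]))
  expect_equal(sum(e == v$index["~"]), 1L)
  end_at <- which(e == v$index["~"])
  expect_true(all(e[seq_len(7) > end_at] == v$index["<"]))
  expect_error(encode_smiles("CCCCCC", v, max_len = 5), "exceeds")
  expect_error(encode_smiles("CCS", v, max_len = 5), "not in vocabulary")
  # round-trip over the corpus, uniform sequence length
  enc <- encode_corpus(micro_prep$corpus, micro_prep$vocabulary,
                       micro_prep$max_len)
  expect_true(all(dim(enc) == c(nrow(micro_prep$corpus),
                                micro_prep$max_len + 2L)))
  dec <- apply(unclass(enc), 1, decode_sequence,
               vocabulary = micro_prep$vocabulary)
  expect_identical(unname(dec), micro_prep$corpus$smiles)
  # vectorised decoder agrees with the scalar one
  expect_identical(unname(chemalign:::decode_sequences(unclass(enc),
                                                       micro_prep$vocabulary)),
                   micro_prep$corpus$smiles)
})

test_that("train/validation split is exact, disjoint and seed-reproducible", {
  corp <- paste0(strrep("C", 1 + (1:100) %% 7), "O")
  corp <- unique(corp)
  corp <- micro_corpus  # 120 unique strings
  sp <- split_corpus(corp, 0.95, seed = 1)
  expect_equal(nrow(sp$train), floor(0.95 * length(corp)))
  expect_equal(nrow(sp$train) + nrow(sp$validation), length(corp))
  expect_length(intersect(sp$train$smiles, sp$validation$smiles), 0L)
  sp2 <- split_corpus(corp, 0.95, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_corpus(corp, 0.95, seed = 2)
  expect_false(identical(sp$train$smiles, sp3$train$smiles))
  expect_error(split_corpus("CCO", 0.5), "at least 2")
})
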