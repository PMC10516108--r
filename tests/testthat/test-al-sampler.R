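test_that("replica multiplicity is the smallest integer reaching the floor", {
  expect_equal(replica_multiplicity(400, 5000), 13L)
  expect_equal(replica_multiplicity(5000, 5000), 1L)
  expect_equal(replica_multiplicity(1, 5000), 5000L)
  expect_error(replica_multiplicity(0, 5000), class = "chemalign_no_passing")
  # exhaustive bound check
  for (n in 1:10000) {
    N <- replica_multiplicity(n, 5000)
    if (!(N * n >= 5000 && (N - 1) * n < 5000)) {
      fail(sprintf("replica bound violated at n = %d", n))
    }
  }
  succeed()
})

test_that("softmax fractions: normalisation, closed form, shift invariance", {
  f <- cluster_fractions(c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(unname(f), rep(0.25, 4))
  f2 <- cluster_fractions(c(a = 0, b = log(2)))
  expect_equal(unname(f2), c(1 / 3, 2 / 3))
  set.seed(5)
  for (i in 1:50) {
    m <- setNames(rnorm(sample(2:12, 1), sd = 5), NULL)
    names(m) <- paste0("c", seq_along(m))
    f <- cluster_fractions(m)
    expect_lt(abs(sum(f) - 1), 1e-12)
    expect_equal(cluster_fractions(m + 123.4), f, tolerance = 1e-12)
  }
  # overflow safety
  expect_equal(unname(cluster_fractions(c(a = 1e4, b = 1e4))), c(0.5, 0.5))
})

# independent waterfall oracle: re-derives the allocation from its
# definition (largest-remainder integerisation, iterative proportional
# redistribution of the surplus among unsaturated clusters)
waterfall_oracle <- function(fractions, sizes, budget) {
  lr <- function(x, total) {
    base <- floor(x)
    extra <- order(x - base, decreasing = TRUE)
    take <- total - sum(base)
    if (take > 0) base[extra[seq_len(take)]] <- base[extra[seq_len(take)]] + 1
    base
  }
  counts <- pmin(lr(fractions * budget, budget), sizes)
  target <- min(budget, sum(sizes))
  repeat {
    need <- target - sum(counts)
    if (need <= 0) break
    open <- counts < sizes
    fr <- fractions[open] / sum(fractions[open])
    counts[open] <- pmin(counts[open] + lr(fr * need, need), sizes[open])
  }
  counts
}

test_that("allocation matches the waterfall oracle and conserves the budget", {
  f <- c(a = 0.5, b = 0.5)
  expect_equal(allocate(f, c(a = 1e5, b = 1e5), 5000),
               c(a = 2500L, b = 2500L))
  # capacity-limited cluster spills into the other
  f2 <- c(a = 0.8, b = 0.2)
  expect_equal(allocate(f2, c(a = 1000, b = 10000), 5000),
               c(a = 1000L, b = 4000L))
  # population exhaustion
  expect_equal(sum(allocate(f2, c(a = 1000, b = 2000), 5000)), 3000L)
  set.seed(91)
  for (i in 1:150) {
    k <- sample(2:8, 1)
    fr <- cluster_fractions(setNames(rnorm(k, sd = 2), paste0("c", 1:k)))
    sizes <- setNames(sample(0:400, k, replace = TRUE), names(fr))
    budget <- sample(50:600, 1)
    got <- allocate(fr, sizes, budget)
    expect_equal(got, waterfall_oracle(fr, sizes, budget),
                 ignore_attr = "class")
    expect_true(all(got <= sizes))
    expect_equal(sum(got), min(budget, sum(sizes)))
  }
})

test_that("the AL training set combines replicas and cluster samples", {
  set.seed(3)
  k <- 10
  scored <- tibble::tibble(
    smiles = paste0("s", 1:100),
    score = c(rep(20, 50), rep(5, 50)),
    cluster = rep(1:k, 10))
  ensemble <- tibble::tibble(
    smiles = paste0("e", 1:2000),
    cluster = rep(1:k, each = 200))
  cfg <- al_config(score_threshold = 11, replica_floor = 250,
                   sampling_budget = 250)
  aset <- build_al_set(scored, ensemble, cfg, seed = 7)
  expect_equal(aset$multiplicity, 5L)           # ceiling(250 / 50)
  expect_true(all(aset$replica$score >= 11))
  expect_equal(nrow(aset$sampled), 250L)
  expect_false(anyDuplicated(aset$sampled$smiles) > 0)
  sm <- al_set_smiles(aset)
  expect_length(sm, 50 * 5 + 250)
  # each replica molecule appears exactly at its multiplicity in the
  # replica part
  tab <- table(head(sm, 250))
  expect_true(all(tab == 5))
  # zero passing molecules: sampled part only, with a warning
  none <- dplyr::mutate(scored, score = 0)
  expect_warning(a0 <- build_al_set(none, ensemble, cfg, seed = 7),
                 "no molecules pass")
  expect_equal(nrow(a0$replica), 0L)
  expect_length(al_set_smiles(a0), 250L)
  # deterministic under seed
  expect_identical(al_set_smiles(build_al_set(scored, ensemble, cfg, 9)),
                   al_set_smiles(build_al_set(scored, ensemble, cfg, 9)))
})

test_that("uniform fractions equal softmax fractions when mean scores are equal", {
  set.seed(13)
  k <- 6
  scored <- tibble::tibble(smiles = paste0("s", 1:60),
                           score = 15, cluster = rep(1:k, 10))
  ensemble <- tibble::tibble(smiles = paste0("e", 1:1200),
                             cluster = rep(1:k, each = 200))
  soft <- build_al_set(scored, ensemble,
                       al_config(11, 100, 120, "softmax"), seed = 2)
  unif <- build_al_set(scored, ensemble,
                       al_config(11, 100, 120, "uniform"), seed = 2)
  expect_equal(soft$fractions[names(unif$fractions)], unif$fractions)
  expect_equal(soft$allocations[names(unif$allocations)], unif$allocations)
})
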