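test_that("model initialisation follows the documented scheme and seed", {
  cfg <- tiny_generator_config(context_length = 12)
  v <- micro_prep$vocabulary
  m1 <- build_model(cfg, v, seed = 9)
  m2 <- build_model(cfg, v, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, v, seed = 10)
  expect_false(identical(m1$params, m3$params))
  # biases 0, layer-norm scales 1
  expect_true(all(m1$params$b1.bqkv == 0))
  expect_true(all(m1$params$b2.b2 == 0))
  expect_true(all(m1$params$b1.ln1_g == 1))
  expect_true(all(m1$params$lnf_b == 0))
  # empirical sd of a large weight matrix within 3 standard errors of 0.02
  w <- m1$params$b1.W1
  se <- 0.02 / sqrt(2 * length(w))
  expect_lt(abs(sd(w) - 0.02), 3 * se)
  expect_error(generator_config(embed_dim = 10, n_heads = 3), "divisible")
})

test_that("learning-rate schedule: linear warmup then cosine decay", {
  sch <- pretrain_schedule()
  total <- 1e6
  expect_equal(lr_at_step(sch, 0, total), 0)
  expect_equal(lr_at_step(sch, 0.05 * total, total), 3e-4 / 2)
  expect_equal(lr_at_step(sch, 0.10 * total, total), 3e-4)
  expect_equal(lr_at_step(sch, total, total), 3e-5, tolerance = 1e-12)
  mid <- 0.10 * total + 0.45 * total  # cosine phase pi/2
  expect_equal(lr_at_step(sch, mid, total), (3e-4 + 3e-5) / 2)
  # fine-tuning: no warmup, starts at peak
  fsch <- finetune_schedule()
  expect_equal(lr_at_step(fsch, 0, total), 3e-5)
  expect_equal(lr_at_step(fsch, total, total), 3e-6, tolerance = 1e-12)
  expect_error(train_schedule(peak_lr = 1e-4, final_lr = 1e-3), "final_lr")
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- generator_config(embed_dim = 8, n_blocks = 2, n_heads = 2,
                          dropout = 0, context_length = 6)
  p <- chemalign:::t_init_params(cfg, 7, seed = 2)
  X <- matrix(sample(1:7, 10, TRUE), 2, 5)
  Y <- matrix(sample(1:7, 10, TRUE), 2, 5)
  mask <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE), 2, 5, byrow = TRUE)
  lossfn <- function(p) {
    fw <- chemalign:::t_forward(p, cfg, X)
    chemalign:::t_loss(fw$logits, Y, mask)$loss
  }
  fw <- chemalign:::t_forward(p, cfg, X)
  ls <- chemalign:::t_loss(fw$logits, Y, mask)
  gr <- chemalign:::t_backward(p, cfg, fw, ls$dlogits)
  eps <- 1e-5
  for (nm in names(p)) {
    n <- length(p[[nm]])
    for (i in unique(round(seq(1, n, length.out = min(3, n))))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("compiled kernels agree with the R reference implementation", {
  set.seed(7)
  cfg <- generator_config(embed_dim = 16, n_blocks = 2, n_heads = 2,
                          dropout = 0, context_length = 8)
  p <- chemalign:::t_init_params(cfg, 9, seed = 5)
  X <- matrix(sample(1:9, 21, TRUE), 3, 7)
  Y <- matrix(sample(1:9, 21, TRUE), 3, 7)
  mask <- matrix(sample(c(TRUE, TRUE, FALSE), 21, TRUE), 3, 7)
  fw <- chemalign:::t_forward(p, cfg, X)
  ls <- chemalign:::t_loss(fw$logits, Y, mask)
  gr <- chemalign:::t_backward(p, cfg, fw, ls$dlogits)
  res <- chemalign:::.ta_forward_backward(p, 2L, 2L, X, Y, mask, 0, list(), TRUE)
  expect_equal(res$loss, ls$loss, tolerance = 1e-7)
  for (nm in names(p)) {
    expect_equal(as.numeric(res$grads[[nm]]), as.numeric(gr[[nm]]),
                 tolerance = 1e-6)
  }
  # KV-cached incremental logits equal the full forward pass
  ids <- matrix(c(2, 3, 4, 5, 6), 1, 5)
  full <- chemalign:::t_forward(p, cfg, ids)$logits[5, ]
  kv <- chemalign:::t_kv_env(cfg, 1)
  sums <- chemalign:::t_make_summers(cfg$context_length, 8L)
  for (t in 1:5) lg <- chemalign:::t_step(p, cfg, ids[1, t], t, kv, sums)
  expect_equal(as.numeric(lg[1, ]), as.numeric(full), tolerance = 1e-10)
  # one full training epoch: both engines land on the same parameters
  v <- token_vocabulary(c("CCO", "CCN", "CCC", "COC"))
  enc <- encode_corpus(c("CCO", "CCN", "CCC", "COC"), v, 6)
  m0 <- build_model(generator_config(embed_dim = 16, n_blocks = 2,
                                     n_heads = 2, dropout = 0,
                                     context_length = 8), v, seed = 3)
  sch <- train_schedule(batch_size = 10, epochs = 1, peak_lr = 1e-3,
                        final_lr = 1e-4, warmup_token_fraction = 0)
  m_cpp <- withr::with_options(list(chemalign.engine = "cpp"),
                               pretrain(m0, enc, sch, seed = 11))
  m_r <- withr::with_options(list(chemalign.engine = "r"),
                             pretrain(m0, enc, sch, seed = 11))
  for (nm in names(m0$params)) {
    expect_equal(as.numeric(m_cpp$params[[nm]]), as.numeric(m_r$params[[nm]]),
                 tolerance = 1e-6)
  }
  # greedy sampling agrees across engines
  g_r <- withr::with_options(list(chemalign.engine = "r"),
    chemalign:::t_sample(m_cpp$params, m_cpp$config, 4, 2, 3, 0))
  g_c <- withr::with_options(list(chemalign.engine = "cpp"),
    chemalign:::t_sample(m_cpp$params, m_cpp$config, 4, 2, 3, 0))
  expect_equal(unname(g_r[, 1:2]), unname(g_c[, 1:2]),
               ignore_attr = TRUE)
})

test_that("pretraining reduces validation loss and is seed-deterministic", {
  tr <- micro_model$trace
  expect_lt(tail(tr$val_loss, 1), tr$val_loss[1])
  expect_true(all(is.finite(tr$train_loss)))
  # zero epochs: parameters unchanged
  cfg <- tiny_generator_config(context_length = micro_prep$max_len + 2L)
  m0 <- build_model(cfg, micro_prep$vocabulary, seed = 11)
  m_same <- pretrain(m0, micro_prep$train,
                     train_schedule(batch_size = 16, epochs = 0), seed = 1)
  expect_identical(m0$params, m_same$params)
  # determinism of the loss trace
  sch <- train_schedule(batch_size = 16, epochs = 2, peak_lr = 2e-3,
                        final_lr = 2e-4)
  a <- pretrain(m0, micro_prep$train, sch, seed = 4)
  b <- pretrain(m0, micro_prep$train, sch, seed = 4)
  expect_identical(a$trace, b$trace)
  expect_identical(a$params, b$params)
})

test_that("generation yields unique valid canonical molecules", {
  g <- suppressWarnings(generate_unique(micro_model, 60, seed = 21))
  expect_lte(nrow(g), 60)
  expect_gt(nrow(g), 10)
  expect_false(anyDuplicated(g$smiles) > 0)
  expect_true(all(is_valid_smiles(g$smiles)))
  expect_identical(g$smiles, canonical_smiles(g$smiles))
  # n = 0
  expect_equal(nrow(generate_unique(micro_model, 0, seed = 1)), 0L)
  # determinism
  g2 <- suppressWarnings(generate_unique(micro_model, 60, seed = 21))
  expect_identical(g$smiles, g2$smiles)
})

test_that("an overfit model memorises: greedy decoding returns the molecule", {
  g <- suppressWarnings(generate_unique(overfit_model, 1, temperature = 1e-9,
                                        max_attempts = 8, seed = 2))
  expect_equal(g$smiles, canonical_smiles("CCOCC"))
  # asking for 2 unique molecules from a one-molecule model falls short
  expect_warning(
    g2 <- generate_unique(overfit_model, 2, temperature = 1e-9,
                          max_attempts = 16, seed = 2),
    "unique")
  expect_equal(nrow(g2), 1L)
})

test_that("fine-tuning on one molecule raises its sequence likelihood", {
  target <- micro_prep$corpus$smiles[5]
  ll0 <- sequence_log_likelihood(micro_model, target)
  sch <- train_schedule(batch_size = 16, epochs = 5, peak_lr = 3e-4,
                        final_lr = 3e-5, warmup_token_fraction = 0)
  m2 <- fine_tune(micro_model, rep(target, 32), sch, seed = 6)
  ll1 <- sequence_log_likelihood(m2, target)
  expect_gt(ll1, ll0)
  # out-of-vocabulary molecules are dropped with a warning
  expect_warning(
    fine_tune(micro_model, c(rep(target, 16), "C[Se]C"), sch, seed = 6),
    "dropped")
  # zero epochs is the identity
  m_id <- fine_tune(micro_model, rep(target, 8),
                    train_schedule(batch_size = 16, epochs = 0), seed = 1)
  expect_identical(m_id$params, micro_model$params)
})

test_that("next-token distributions are valid probability vectors", {
  p <- micro_model$params
  cfg <- micro_model$config
  X <- unclass(micro_prep$train)[1:4, , drop = FALSE] + 1L
  fw <- chemalign:::t_forward(p, cfg, X[, -ncol(X)])
  probs <- chemalign:::t_softmax_rows(fw$logits)
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
})
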