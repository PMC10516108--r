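# Generative SMILES language model: configuration, training schedules,
# pretraining/fine-tuning, and unique-molecule generation.

#' Generator configuration
#'
#' Architecture hyperparameters of the transformer-decoder SMILES model.
#' The full-scale defaults are a 256-dimensional embedding with eight
#' decoder blocks of eight attention heads; [tiny_generator_config()] gives
#' a desk-scale profile exercising the same code paths.
#'
#' @param embed_dim Embedding dimension (default 256).
#' @param n_blocks Number of decoder blocks (default 8).
#' @param n_heads Attention heads per block (default 8); must divide
#'   `embed_dim`.
#' @param dropout Dropout probability applied after the attention and
#'   feed-forward projections during training (default 0.10).
#' @param init_std Standard deviation of the Gaussian weight initialisation
#'   (default 0.02).
#' @param layernorm_init Initial value of layer-norm scales (default 1).
#' @param bias_init Initial value of biases (default 0).
#' @param context_length Sequence length the model operates on
#'   (`max_len + 2`, accounting for the start and end tokens).
#' @param mlp_mult Width multiplier of the feed-forward layer (default 4).
#' @return A `generator_config` list.
#' @export
generator_config <- function(embed_dim = 256L, n_blocks = 8L, n_heads = 8L,
                             dropout = 0.10, init_std = 0.02,
                             layernorm_init = 1.0, bias_init = 0.0,
                             context_length = 135L, mlp_mult = 4L) {
  assert_that(embed_dim %% n_heads == 0,
              "embed_dim must be divisible by n_heads")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(embed_dim = as.integer(embed_dim),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 dropout = dropout, init_std = init_std,
                 layernorm_init = layernorm_init, bias_init = bias_init,
                 context_length = as.integer(context_length),
                 mlp_mult = as.integer(mlp_mult)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
tiny_generator_config <- function(context_length = 40L, dropout = 0.10) {
  generator_config(embed_dim = 64L, n_blocks = 2L, n_heads = 2L,
                   dropout = dropout, context_length = context_length)
}

#' Training schedule
#'
#' Learning-rate and regularisation schedule: linear warmup from zero to
#' `peak_lr` over `warmup_token_fraction` of all training tokens, then
#' cosine decay to `final_lr`; token-level cross-entropy with decoupled L2
#' on linear-layer weights; global gradient-norm clipping.
#'
#' @param batch_size Sequences per optimisation step (full-scale default 512).
#' @param epochs Training epochs (30 pretraining / 10 fine-tuning).
#' @param peak_lr Peak learning rate (3e-4 pretraining / 3e-5 fine-tuning).
#' @param final_lr Final learning rate of the cosine decay.
#' @param warmup_token_fraction Fraction of total tokens used for linear
#'   warmup (0.10 pretraining, 0 fine-tuning).
#' @param l2_lambda Decoupled weight decay applied to linear-layer weights
#'   only (default 0.1).
#' @param betas Adaptive-optimizer moment coefficients (default 0.965, 0.99).
#' @param rho Clipping parameter of the reference optimizer configuration;
#'   recorded for provenance (the shipped optimizer is Adam-style and does
#'   not use it).
#' @param grad_clip_norm Global gradient-norm clip (default 1.0).
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(batch_size = 512L, epochs = 30L, peak_lr = 3e-4,
                           final_lr = 3e-5, warmup_token_fraction = 0.10,
                           l2_lambda = 0.1, betas = c(0.965, 0.99),
                           rho = 0.04, grad_clip_norm = 1.0) {
  assert_that(final_lr <= peak_lr, "final_lr must be <= peak_lr")
  assert_that(warmup_token_fraction >= 0 && warmup_token_fraction < 1,
              "warmup_token_fraction must be in [0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 peak_lr = peak_lr, final_lr = final_lr,
                 warmup_token_fraction = warmup_token_fraction,
                 l2_lambda = l2_lambda, betas = betas, rho = rho,
                 grad_clip_norm = grad_clip_norm),
            class = "train_schedule")
}

#' @rdname train_schedule
#' @export
pretrain_schedule <- function(batch_size = 512L, epochs = 30L) {
  train_schedule(batch_size = batch_size, epochs = epochs)
}

#' @rdname train_schedule
#' @export
finetune_schedule <- function(batch_size = 512L, epochs = 10L) {
  train_schedule(batch_size = batch_size, epochs = epochs,
                 peak_lr = 3e-5, final_lr = 3e-6,
                 warmup_token_fraction = 0)
}

#' Learning rate at a training position
#'
#' Linear warmup from 0 to `peak_lr` over the first
#' `warmup_token_fraction * tokens_total` tokens, then cosine decay from
#' `peak_lr` to `final_lr` at `tokens_total`.
#'
#' @param schedule A [train_schedule()].
#' @param tokens_seen Tokens consumed so far.
#' @param tokens_total Total tokens over the whole run.
#' @return The learning rate (scalar).
#' @export
lr_at_step <- function(schedule, tokens_seen, tokens_total) {
  assert_that(tokens_seen >= 0 && tokens_seen <= tokens_total,
              "tokens_seen must be in [0, tokens_total]")
  warm <- schedule$warmup_token_fraction * tokens_total
  if (warm > 0 && tokens_seen < warm) {
    return(schedule$peak_lr * tokens_seen / warm)
  }
  span <- tokens_total - warm
  phase <- if (span <= 0) 1 else (tokens_seen - warm) / span
  schedule$final_lr +
    (schedule$peak_lr - schedule$final_lr) * 0.5 * (1 + cos(pi * phase))
}

#' Build a language model
#'
#' Weights are drawn from N(0, `init_std`^2); layer-norm scales start at 1
#' and biases at 0.  Deterministic under `seed`.
#'
#' @param config A [generator_config()].
#' @param vocabulary A [token_vocabulary()].
#' @param seed Integer seed for initialisation.
#' @return A `language_model` object.
#' @export
build_model <- function(config, vocabulary, seed = 1L) {
  V <- length(vocabulary$tokens)
  params <- t_init_params(config, V, seed)
  structure(
    list(params = params, config = config, vocabulary = vocabulary,
         optimizer = "adamw-decoupled",
         n_params = sum(vapply(params, length, integer(1))),
         trace = tibble(phase = character(0), epoch = integer(0),
                        train_loss = numeric(0), val_loss = numeric(0))),
    class = "language_model"
  )
}

#' @export
print.language_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<language_model: %d params | d=%d, blocks=%d, heads=%d, context=%d | vocab=%d>\n",
    x$n_params, cfg$embed_dim, cfg$n_blocks, cfg$n_heads,
    cfg$context_length, length(x$vocabulary$tokens)))
  invisible(x)
}

#' @rdname build_model
#' @param x A `language_model`.
#' @param ... Unused.
#' @method glance language_model
#' @export
glance.language_model <- function(x, ...) {
  tibble(n_params = x$n_params,
         embed_dim = x$config$embed_dim,
         n_blocks = x$config$n_blocks,
         n_heads = x$config$n_heads,
         context_length = x$config$context_length,
         vocab_size = length(x$vocabulary$tokens),
         final_train_loss = if (nrow(x$trace)) tail(x$trace$train_loss, 1) else NA_real_)
}

# shared training loop; phase is "pretrain" or "finetune"
lm_train <- function(model, sequences, schedule, seed, validation = NULL,
                     phase = "pretrain") {
  assert_that(nrow(sequences) > 0, "training corpus is empty")
  cfg <- model$config
  Tm <- cfg$context_length
  assert_that(ncol(sequences) <= Tm,
              sprintf("sequences of length %d exceed context_length %d",
                      ncol(sequences), Tm))
  seqs <- sequences + 1L  # 0-based ids -> 1-based
  pad_id <- unname(model$vocabulary$index[model$vocabulary$specials[["pad"]]]) + 1L
  n <- nrow(seqs)
  L <- ncol(seqs)
  tokens_total <- as.double(n) * L * schedule$epochs
  params <- model$params
  # the compiled trainer uses block-dense attention, quadratic in
  # batch_size * sequence length; beyond this the R path is the safe route
  cpp_ok <- as.double(min(schedule$batch_size, n)) * (L - 1) <= 8192 &&
    (L - 1) <= 256
  if (schedule$epochs > 0 && t_engine() == "cpp" && cpp_ok) {
    val <- if (!is.null(validation) && nrow(validation) > 0) {
      unclass(validation) + 1L
    } else matrix(integer(0), 0, L)
    res <- .ta_train(params, cfg$n_blocks, cfg$n_heads, seqs, pad_id, val,
                     schedule$batch_size, schedule$epochs, schedule$peak_lr,
                     schedule$final_lr, schedule$warmup_token_fraction,
                     schedule$l2_lambda, schedule$betas[1], schedule$betas[2],
                     schedule$grad_clip_norm, cfg$dropout, as.integer(seed))
    if (res$diverged) {
      rlang::abort("training diverged (non-finite loss)")
    }
    model$params <- res$params
    model$trace <- bind_rows(model$trace,
                             tibble(phase = phase,
                                    epoch = seq_along(res$train_loss),
                                    train_loss = res$train_loss,
                                    val_loss = res$val_loss))
    return(model)
  }
  adam <- t_adam_init(params)
  decay <- t_decay_names(params)
  tokens_seen <- 0
  trace <- list()
  if (schedule$epochs > 0) {
    with_seed(seed, {
      for (epoch in seq_len(schedule$epochs)) {
        ord <- sample.int(n)
        losses <- numeric(0)
        for (i0 in seq(1, n, by = schedule$batch_size)) {
          take <- ord[i0:min(i0 + schedule$batch_size - 1, n)]
          batch <- seqs[take, , drop = FALSE]
          X <- batch[, -L, drop = FALSE]
          Y <- batch[, -1, drop = FALSE]
          mask <- Y != pad_id
          step <- t_train_step(params, cfg, X, Y, mask, cfg$dropout)
          if (!is.finite(step$loss)) {
            rlang::abort(sprintf(
              "training diverged (non-finite loss) at epoch %d", epoch))
          }
          grads <- step$grads
          gn <- t_grad_global_norm(grads)
          if (gn > schedule$grad_clip_norm) {
            sc <- schedule$grad_clip_norm / gn
            grads <- lapply(grads, function(g) g * sc)
          }
          lr <- lr_at_step(schedule, tokens_seen, tokens_total)
          st <- t_adam_step(params, grads, adam, lr, schedule$betas,
                            weight_decay = schedule$l2_lambda,
                            decay_names = decay)
          params <- st$params
          adam <- st$state
          tokens_seen <- tokens_seen + length(batch)
          losses <- c(losses, step$loss)
        }
        val_loss <- NA_real_
        if (!is.null(validation) && nrow(validation) > 0) {
          val_loss <- lm_eval_loss(params, cfg, validation + 1L, pad_id)
        }
        trace[[epoch]] <- tibble(phase = phase, epoch = epoch,
                                 train_loss = mean(losses),
                                 val_loss = val_loss)
      }
    })
  }
  model$params <- params
  model$trace <- bind_rows(model$trace, bind_rows(trace))
  model
}

lm_eval_loss <- function(params, cfg, seqs1, pad_id, batch = 256L) {
  L <- ncol(seqs1)
  tot <- 0; cnt <- 0
  for (i0 in seq(1, nrow(seqs1), by = batch)) {
    b <- seqs1[i0:min(i0 + batch - 1, nrow(seqs1)), , drop = FALSE]
    X <- b[, -L, drop = FALSE]
    Y <- b[, -1, drop = FALSE]
    mask <- Y != pad_id
    tot <- tot + t_batch_loss(params, cfg, X, Y, mask) * sum(mask)
    cnt <- cnt + sum(mask)
  }
  tot / cnt
}

#' Pretrain the language model
#'
#' Token-level cross-entropy on next-token prediction, with the warmup +
#' cosine learning-rate schedule, decoupled L2 on linear weights, and
#' gradient-norm clipping.  Returns the model with a per-epoch loss trace
#' appended (`model$trace`).
#'
#' @param model A [build_model()] result.
#' @param corpus An [encode_corpus()] matrix of training sequences.
#' @param schedule A [train_schedule()]; default [pretrain_schedule()].
#' @param seed Integer seed (shuffling, dropout).
#' @param validation Optional encoded validation corpus; adds per-epoch
#'   validation loss to the trace.
#' @return The trained `language_model`.
#' @export
pretrain <- function(model, corpus, schedule = pretrain_schedule(),
                     seed = 1L, validation = NULL) {
  lm_train(model, corpus, schedule, seed, validation, phase = "pretrain")
}

#' Fine-tune the language model on an AL training set
#'
#' Replicated molecules in the training set are distinct training examples.
#' Molecules that cannot be encoded under the model's vocabulary (unknown
#' token or overlength) are dropped with a warning.
#'
#' @param model A trained `language_model`.
#' @param training_set Character vector of SMILES (replicas included), an
#'   [al_training_set()], or an encoded matrix.
#' @param schedule A [train_schedule()]; default [finetune_schedule()].
#' @param seed Integer seed.
#' @return The fine-tuned `language_model`.
#' @export
fine_tune <- function(model, training_set, schedule = finetune_schedule(),
                      seed = 1L) {
  if (inherits(training_set, "al_training_set")) {
    training_set <- al_set_smiles(training_set)
  }
  if (is.character(training_set)) {
    max_len <- model$config$context_length - 2L
    enc <- encode_corpus_safe(training_set, model$vocabulary, max_len)
    training_set <- enc$sequences
    if (enc$n_dropped > 0) {
      rlang::warn(sprintf(
        "fine_tune: dropped %d molecules not encodable under the vocabulary",
        enc$n_dropped))
    }
  }
  lm_train(model, training_set, schedule, seed, phase = "finetune")
}

# encode, dropping out-of-vocabulary / overlength strings
encode_corpus_safe <- function(smiles, vocabulary, max_len) {
  rows <- lapply(smiles, function(s) {
    tryCatch(encode_smiles(s, vocabulary, max_len), error = function(e) NULL)
  })
  ok <- !vapply(rows, is.null, logical(1))
  seqs <- if (any(ok)) do.call(rbind, rows[ok]) else
    matrix(integer(0), 0, max_len + 2L)
  list(sequences = seqs, n_dropped = sum(!ok))
}

#' Generate unique molecules
#'
#' Samples sequences autoregressively (multinomial sampling at the given
#' temperature), decodes them, drops invalid strings, canonicalizes, and
#' deduplicates by canonical form.  Sampling rounds continue until `n`
#' unique molecules are collected or `max_attempts` raw samples have been
#' drawn, in which case a shortfall warning is raised.
#'
#' @param model A trained `language_model`.
#' @param n Number of unique molecules requested.
#' @param temperature Softmax temperature (default 1.0; values near 0 give
#'   greedy decoding).
#' @param max_attempts Cap on raw samples drawn (default `20 * n`).
#' @param seed Integer seed.
#' @return A tibble with columns `smiles` (unique canonical forms, in first
#'   generation order) and attribute `report` (attempt/validity counts).
#' @export
generate_unique <- function(model, n, temperature = 1.0,
                            max_attempts = 20L * n, seed = 1L) {
  assert_that(n >= 0, "n must be >= 0")
  vocab <- model$vocabulary
  sp <- vocab$specials
  start_id <- unname(vocab$index[sp[["start"]]]) + 1L
  end_id <- unname(vocab$index[sp[["end"]]]) + 1L
  found <- character(0)
  attempts <- 0L
  n_invalid <- 0L
  n_dup <- 0L
  if (n > 0) {
    with_seed(seed, {
      while (length(found) < n && attempts < max_attempts) {
        batch <- min(max(ceiling((n - length(found)) * 2), 256L),
                     max_attempts - attempts)
        raw <- t_sample(model$params, model$config, batch,
                        start_id, end_id, temperature)
        attempts <- attempts + batch
        sm <- decode_sequences(raw - 1L, vocab)
        sm <- sm[!is.na(sm) & nzchar(sm)]
        can <- canonical_smiles_memo(sm)
        n_invalid <- n_invalid + (batch - sum(!is.na(can)))
        can <- can[!is.na(can)]
        new <- setdiff(unique(can), found)
        n_dup <- n_dup + length(can) - length(new)
        found <- c(found, head(new, n - length(found)))
      }
    })
    if (length(found) < n) {
      rlang::warn(sprintf(
        "generate_unique: %d of %d unique molecules after %d attempts",
        length(found), n, attempts))
    }
  }
  out <- tibble(smiles = found)
  attr(out, "report") <- report_row(
    n_requested = n, n_returned = length(found), n_attempts = attempts,
    n_invalid = n_invalid, n_duplicate = n_dup)
  out
}

#' Sequence log-likelihood under the model
#'
#' @param model A `language_model`.
#' @param smiles Character vector of SMILES encodable under the model's
#'   vocabulary.
#' @return Numeric vector of total log-likelihoods (natural log), one per
#'   molecule.
#' @export
sequence_log_likelihood <- function(model, smiles) {
  max_len <- model$config$context_length - 2L
  seqs <- encode_corpus(tibble(smiles = smiles), model$vocabulary, max_len)
  pad_id <- unname(model$vocabulary$index[model$vocabulary$specials[["pad"]]]) + 1L
  unname(t_sequence_logprob(model$params, model$config,
                            unclass(seqs) + 1L, pad_id))
}
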