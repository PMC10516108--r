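# Internal transformer-decoder engine: parameter initialisation, forward
# pass, manual backpropagation, Adam-style updates with decoupled weight
# decay, and KV-cached autoregressive sampling.  Activations for a batch are
# held as (B*T) x d matrices with row (b-1)*T + t; attention is computed
# per sequence during training (B is small) and vectorised across the batch
# during generation (B is large, T is small).

t_init_params <- function(cfg, vocab_size, seed) {
  d <- cfg$embed_dim
  V <- vocab_size
  Tm <- cfg$context_length
  sd0 <- cfg$init_std
  gmat <- function(nr, nc) matrix(rnorm(nr * nc, 0, sd0), nr, nc)
  with_seed(seed, {
    p <- list(
      tok_emb = gmat(V, d),
      pos_emb = gmat(Tm, d)
    )
    for (l in seq_len(cfg$n_blocks)) {
      p[[sprintf("b%d.ln1_g", l)]] <- rep(cfg$layernorm_init, d)
      p[[sprintf("b%d.ln1_b", l)]] <- rep(cfg$bias_init, d)
      p[[sprintf("b%d.Wqkv", l)]] <- gmat(d, 3 * d)
      p[[sprintf("b%d.bqkv", l)]] <- rep(cfg$bias_init, 3 * d)
      p[[sprintf("b%d.Wo", l)]] <- gmat(d, d)
      p[[sprintf("b%d.bo", l)]] <- rep(cfg$bias_init, d)
      p[[sprintf("b%d.ln2_g", l)]] <- rep(cfg$layernorm_init, d)
      p[[sprintf("b%d.ln2_b", l)]] <- rep(cfg$bias_init, d)
      p[[sprintf("b%d.W1", l)]] <- gmat(d, cfg$mlp_mult * d)
      p[[sprintf("b%d.b1", l)]] <- rep(cfg$bias_init, cfg$mlp_mult * d)
      p[[sprintf("b%d.W2", l)]] <- gmat(cfg$mlp_mult * d, d)
      p[[sprintf("b%d.b2", l)]] <- rep(cfg$bias_init, d)
    }
    p$lnf_g <- rep(cfg$layernorm_init, d)
    p$lnf_b <- rep(cfg$bias_init, d)
    p$Whead <- gmat(d, V)
    p$bhead <- rep(cfg$bias_init, V)
    p
  })
}

# names of parameters treated as linear-layer weights (decoupled L2 applies
# to these only; embeddings, layer norms and biases are excluded)
t_decay_names <- function(params) {
  grep("\\.(Wqkv|Wo|W1|W2)$|^Whead$", names(params), value = TRUE)
}

t_layernorm <- function(x, g, b, eps = 1e-5) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  rstd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * rstd
  list(y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, rstd = rstd)
}

# y = xhat * g + b computed as above; backward returns dx, dg, db
t_layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$rstd
  list(dx = dx, dg = dg, db = db)
}

# GELU, sigmoid approximation: x * sigmoid(1.702 x).  The exp-based form is
# several times cheaper than the exact Gaussian CDF at indistinguishable
# quality for this use.
t_gelu <- function(x) x / (1 + exp(-1.702 * x))
t_gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

t_addbias <- function(x, b) x + rep(b, each = nrow(x))

t_rowmax <- function(x) {
  m <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) m <- pmax(m, x[, j])
  m
}

t_softmax_rows <- function(x) {
  e <- exp(x - t_rowmax(x))
  e / rowSums(e)
}

# Training-mode forward pass with caches; X, Y are B x T matrices of 1-based
# token ids, mask is B x T logical (loss positions).  Returns loss, caches.
t_forward <- function(params, cfg, X, train = FALSE, dropout_p = 0) {
  B <- nrow(X); Tt <- ncol(X); d <- cfg$embed_dim
  H <- cfg$n_heads; dh <- d %/% H
  ids <- as.vector(t(X))                      # length B*T, row (b-1)*T + t
  pos <- rep(seq_len(Tt), times = B)
  h <- params$tok_emb[ids, , drop = FALSE] + params$pos_emb[pos, , drop = FALSE]
  caches <- vector("list", cfg$n_blocks)
  rows_of <- function(b) ((b - 1) * Tt + 1):(b * Tt)
  neg <- -1e30
  for (l in seq_len(cfg$n_blocks)) {
    pn <- function(nm) params[[sprintf("b%d.%s", l, nm)]]
    cache <- list(h_in = h)
    ln1 <- t_layernorm(h, pn("ln1_g"), pn("ln1_b"))
    qkv <- t_addbias(ln1$y %*% pn("Wqkv"), pn("bqkv"))
    Q <- qkv[, 1:d, drop = FALSE]
    K <- qkv[, d + 1:d, drop = FALSE]
    V <- qkv[, 2 * d + 1:d, drop = FALSE]
    atn <- matrix(0, B * Tt, d)
    Plist <- vector("list", B * H)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      for (hh in seq_len(H)) {
        cs <- (hh - 1) * dh + 1:dh
        S <- (Q[rb, cs, drop = FALSE] %*% t(K[rb, cs, drop = FALSE])) / sqrt(dh)
        S[upper.tri(S)] <- neg
        P <- t_softmax_rows(S)
        Plist[[(b - 1) * H + hh]] <- P
        atn[rb, cs] <- P %*% V[rb, cs, drop = FALSE]
      }
    }
    proj <- t_addbias(atn %*% pn("Wo"), pn("bo"))
    if (train && dropout_p > 0) {
      dm1 <- matrix(runif(length(proj)) >= dropout_p, nrow(proj)) / (1 - dropout_p)
      proj <- proj * dm1
      cache$dm1 <- dm1
    }
    h2 <- h + proj
    ln2 <- t_layernorm(h2, pn("ln2_g"), pn("ln2_b"))
    f1 <- t_addbias(ln2$y %*% pn("W1"), pn("b1"))
    gact <- t_gelu(f1)
    f2 <- t_addbias(gact %*% pn("W2"), pn("b2"))
    if (train && dropout_p > 0) {
      dm2 <- matrix(runif(length(f2)) >= dropout_p, nrow(f2)) / (1 - dropout_p)
      f2 <- f2 * dm2
      cache$dm2 <- dm2
    }
    h <- h2 + f2
    cache$ln1 <- ln1; cache$ln2 <- ln2
    cache$Q <- Q; cache$K <- K; cache$V <- V
    cache$Plist <- Plist; cache$atn <- atn; cache$h2 <- h2
    cache$f1 <- f1; cache$gact <- gact
    caches[[l]] <- cache
  }
  lnf <- t_layernorm(h, params$lnf_g, params$lnf_b)
  logits <- t_addbias(lnf$y %*% params$Whead, params$bhead)
  list(logits = logits, caches = caches, lnf = lnf, ids = ids, pos = pos,
       B = B, Tt = Tt)
}

# Cross-entropy over masked positions; returns loss and dlogits.
t_loss <- function(logits, Y, mask) {
  tgt <- as.vector(t(Y))
  msk <- as.vector(t(mask))
  n <- sum(msk)
  P <- t_softmax_rows(logits)
  sel <- cbind(seq_along(tgt), tgt)
  ll <- log(pmax(P[sel], 1e-12))
  loss <- -sum(ll[msk]) / n
  dlogits <- P
  dlogits[sel] <- dlogits[sel] - 1
  dlogits[!msk, ] <- 0
  dlogits <- dlogits / n
  list(loss = loss, dlogits = dlogits)
}

t_backward <- function(params, cfg, fw, dlogits) {
  d <- cfg$embed_dim; H <- cfg$n_heads; dh <- d %/% H
  B <- fw$B; Tt <- fw$Tt
  rows_of <- function(b) ((b - 1) * Tt + 1):(b * Tt)
  g <- list()
  g$Whead <- t(fw$lnf$y) %*% dlogits
  g$bhead <- colSums(dlogits)
  dy <- dlogits %*% t(params$Whead)
  lb <- t_layernorm_bwd(dy, fw$lnf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dh_out <- lb$dx
  for (l in rev(seq_len(cfg$n_blocks))) {
    pn <- function(nm) params[[sprintf("b%d.%s", l, nm)]]
    gn <- function(nm) sprintf("b%d.%s", l, nm)
    cache <- fw$caches[[l]]
    # MLP branch
    df2 <- dh_out
    if (!is.null(cache$dm2)) df2 <- df2 * cache$dm2
    g[[gn("W2")]] <- t(cache$gact) %*% df2
    g[[gn("b2")]] <- colSums(df2)
    dgact <- df2 %*% t(pn("W2"))
    df1 <- dgact * t_gelu_grad(cache$f1)
    g[[gn("W1")]] <- t(cache$ln2$y) %*% df1
    g[[gn("b1")]] <- colSums(df1)
    dln2y <- df1 %*% t(pn("W1"))
    lb2 <- t_layernorm_bwd(dln2y, cache$ln2, pn("ln2_g"))
    g[[gn("ln2_g")]] <- lb2$dg; g[[gn("ln2_b")]] <- lb2$db
    dh2 <- dh_out + lb2$dx
    # attention branch
    dproj <- dh2
    if (!is.null(cache$dm1)) dproj <- dproj * cache$dm1
    g[[gn("Wo")]] <- t(cache$atn) %*% dproj
    g[[gn("bo")]] <- colSums(dproj)
    datn <- dproj %*% t(pn("Wo"))
    dQ <- matrix(0, B * Tt, d); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      for (hh in seq_len(H)) {
        cs <- (hh - 1) * dh + 1:dh
        P <- cache$Plist[[(b - 1) * H + hh]]
        dO <- datn[rb, cs, drop = FALSE]
        Vb <- cache$V[rb, cs, drop = FALSE]
        dP <- dO %*% t(Vb)
        dV[rb, cs] <- t(P) %*% dO
        dS <- P * (dP - rowSums(dP * P))
        dQ[rb, cs] <- (dS %*% cache$K[rb, cs, drop = FALSE]) / sqrt(dh)
        dK[rb, cs] <- (t(dS) %*% cache$Q[rb, cs, drop = FALSE]) / sqrt(dh)
      }
    }
    dqkv <- cbind(dQ, dK, dV)
    g[[gn("Wqkv")]] <- t(cache$ln1$y) %*% dqkv
    g[[gn("bqkv")]] <- colSums(dqkv)
    dln1y <- dqkv %*% t(pn("Wqkv"))
    lb1 <- t_layernorm_bwd(dln1y, cache$ln1, pn("ln1_g"))
    g[[gn("ln1_g")]] <- lb1$dg; g[[gn("ln1_b")]] <- lb1$db
    dh_out <- dh2 + lb1$dx
  }
  g$tok_emb <- rowsum_into(dh_out, fw$ids, nrow(params$tok_emb))
  g$pos_emb <- rowsum_into(dh_out, fw$pos, nrow(params$pos_emb))
  g
}

rowsum_into <- function(x, groups, n_out) {
  rs <- rowsum(x, group = groups)
  out <- matrix(0, n_out, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

t_grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}

t_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Adam update with decoupled weight decay on linear weights only.
t_adam_step <- function(params, grads, state, lr, betas, eps = 1e-8,
                        weight_decay = 0, decay_names = character(0)) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gnm
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gnm * gnm
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && nm %in% decay_names) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# ---- KV-cached batched sampling -------------------------------------------

# Forward one position for the whole batch; x_ids 1-based token ids (len B).
# kv is an environment holding preallocated per-block, per-head K/V caches
# of shape B x (dh * Tm), filled through column `t_pos * dh`.  `sums` holds
# precomputed column-group summation matrices (see t_make_summers) so
# attention is two elementwise products and two matmuls per head,
# independent of the batch size.
t_step <- function(params, cfg, x_ids, t_pos, kv, sums) {
  d <- cfg$embed_dim; H <- cfg$n_heads; dh <- d %/% H
  B <- length(x_ids)
  tlen <- t_pos
  h <- params$tok_emb[x_ids, , drop = FALSE] +
    rep(params$pos_emb[t_pos, ], each = B)
  for (l in seq_len(cfg$n_blocks)) {
    pn <- function(nm) params[[sprintf("b%d.%s", l, nm)]]
    a1 <- t_layernorm(h, pn("ln1_g"), pn("ln1_b"))$y
    qkv <- t_addbias(a1 %*% pn("Wqkv"), pn("bqkv"))
    atn <- matrix(0, B, d)
    for (hh in seq_len(H)) {
      cs <- (hh - 1) * dh + 1:dh
      key <- (l - 1) * H + hh
      kv$K[[key]][, (tlen - 1) * dh + 1:dh] <- qkv[, d + cs, drop = FALSE]
      kv$V[[key]][, (tlen - 1) * dh + 1:dh] <- qkv[, 2 * d + cs, drop = FALSE]
      Kc <- kv$K[[key]][, seq_len(tlen * dh), drop = FALSE]
      Vc <- kv$V[[key]][, seq_len(tlen * dh), drop = FALSE]
      # S[b, j] = q_b . k_{b,j} / sqrt(dh), vectorised over the batch
      QK <- qkv[, cs[sums$rep_dh[[tlen]]], drop = FALSE] * Kc
      S <- QK %*% sums$group[[tlen]] / sqrt(dh)
      P <- t_softmax_rows(S)
      PV <- P[, sums$rep_t[[tlen]], drop = FALSE] * Vc
      atn[, cs] <- PV %*% sums$spread[[tlen]]
    }
    h <- h + t_addbias(atn %*% pn("Wo"), pn("bo"))
    a2 <- t_layernorm(h, pn("ln2_g"), pn("ln2_b"))$y
    f1 <- t_addbias(a2 %*% pn("W1"), pn("b1"))
    h <- h + t_addbias(t_gelu(f1) %*% pn("W2"), pn("b2"))
  }
  hf <- t_layernorm(h, params$lnf_g, params$lnf_b)$y
  logits <- t_addbias(hf %*% params$Whead, params$bhead)
  logits
}

t_kv_env <- function(cfg, B) {
  H <- cfg$n_heads; dh <- cfg$embed_dim %/% H
  kv <- new.env(parent = emptyenv())
  kv$K <- lapply(seq_len(cfg$n_blocks * H),
                 function(i) matrix(0, B, dh * cfg$context_length))
  kv$V <- lapply(seq_len(cfg$n_blocks * H),
                 function(i) matrix(0, B, dh * cfg$context_length))
  kv
}

# drop finished rows from the KV caches
t_kv_subset <- function(kv, keep) {
  kv$K <- lapply(kv$K, function(m) m[keep, , drop = FALSE])
  kv$V <- lapply(kv$V, function(m) m[keep, , drop = FALSE])
  kv
}

t_make_summers <- function(Tm, dh) {
  list(
    rep_dh = lapply(seq_len(Tm), function(t) rep(1:dh, t)),
    rep_t = lapply(seq_len(Tm), function(t) rep(1:t, each = dh)),
    group = lapply(seq_len(Tm), function(t)
      kronecker(diag(t), matrix(1, dh, 1))),
    spread = lapply(seq_len(Tm), function(t)
      kronecker(matrix(1, t, 1), diag(dh)))
  )
}

# Sample B sequences autoregressively.  Returns a B x context_length matrix
# of 1-based ids beginning with the start token; rows are truncated by the
# caller at the first end token.
t_sample_batch <- function(params, cfg, B, start_id, end_id, temperature = 1) {
  Tm <- cfg$context_length
  kv <- t_kv_env(cfg, B)
  sums <- t_make_summers(Tm, cfg$embed_dim %/% cfg$n_heads)
  out <- matrix(NA_integer_, B, Tm)
  out[, 1] <- start_id
  x <- rep(start_id, B)
  active <- seq_len(B)  # rows of `out` still generating
  V <- nrow(params$tok_emb)
  cum_mat <- upper.tri(matrix(1, V, V), diag = TRUE) * 1
  for (t in seq_len(Tm - 1)) {
    logits <- t_step(params, cfg, x, t, kv, sums)
    if (temperature < 1e-8) {
      nxt <- max.col(logits, ties.method = "first")
    } else {
      P <- t_softmax_rows(logits / temperature)
      cum <- P %*% cum_mat
      u <- runif(length(active))
      nxt <- rowSums(cum < u) + 1L
      nxt[nxt > V] <- V
    }
    out[cbind(active, t + 1)] <- nxt
    alive <- nxt != end_id
    if (!any(alive)) break
    # compact the batch once enough rows have finished
    if (mean(alive) < 0.7) {
      kv <- t_kv_subset(kv, alive)
      active <- active[alive]
      nxt <- nxt[alive]
    }
    x <- nxt
  }
  out
}

# ---- engine dispatch -------------------------------------------------------
# The compiled kernels in src/transformer.cpp mirror the R reference above;
# option "chemalign.engine" ("cpp" default, "r" reference) selects the path.

t_engine <- function() getOption("chemalign.engine", "cpp")

# one training step: loss + gradients
t_train_step <- function(params, cfg, X, Y, mask, dropout_p) {
  if (t_engine() == "cpp") {
    dropu <- list()
    if (dropout_p > 0) {
      BT <- nrow(X) * ncol(X)
      dropu <- lapply(seq_len(2L * cfg$n_blocks),
                      function(i) matrix(runif(BT * cfg$embed_dim), BT))
    }
    res <- .ta_forward_backward(params, cfg$n_blocks, cfg$n_heads,
                                X, Y, mask, dropout_p, dropu, TRUE)
    grads <- res$grads
    for (nm in names(grads)) {
      if (is.null(dim(params[[nm]]))) grads[[nm]] <- as.numeric(grads[[nm]])
    }
    list(loss = res$loss, grads = grads[names(params)])
  } else {
    fw <- t_forward(params, cfg, X, train = TRUE, dropout_p = dropout_p)
    ls <- t_loss(fw$logits, Y, mask)
    list(loss = ls$loss,
         grads = if (is.finite(ls$loss)) t_backward(params, cfg, fw, ls$dlogits))
  }
}

t_batch_loss <- function(params, cfg, X, Y, mask) {
  if (t_engine() == "cpp") {
    .ta_forward_backward(params, cfg$n_blocks, cfg$n_heads,
                         X, Y, mask, 0, list(), FALSE)$loss
  } else {
    fw <- t_forward(params, cfg, X, train = FALSE)
    t_loss(fw$logits, Y, mask)$loss
  }
}

# sample B sequences; randomness always drawn from R's RNG
t_sample <- function(params, cfg, B, start_id, end_id, temperature = 1) {
  if (t_engine() == "cpp") {
    U <- matrix(runif(B * (cfg$context_length - 1)), B)
    out <- .ta_sample_batch(params, cfg$n_blocks, cfg$n_heads,
                            cfg$context_length, B, start_id, end_id,
                            temperature, U)
    out[out == 0L] <- NA_integer_
    out
  } else {
    t_sample_batch(params, cfg, B, start_id, end_id, temperature)
  }
}

# Mean log-likelihood of full sequences (no dropout); seqs is a matrix of
# 1-based ids, loss positions are targets != pad.
t_sequence_logprob <- function(params, cfg, seqs, pad_id) {
  X <- seqs[, -ncol(seqs), drop = FALSE]
  Y <- seqs[, -1, drop = FALSE]
  mask <- Y != pad_id
  fw <- t_forward(params, cfg, X, train = FALSE)
  P <- t_softmax_rows(fw$logits)
  tgt <- as.vector(t(Y))
  msk <- as.vector(t(mask))
  ll <- log(pmax(P[cbind(seq_along(tgt), tgt)], 1e-12))
  llm <- matrix(ll * msk, nrow(X), ncol(X), byrow = TRUE)
  rowSums(llm)
}
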