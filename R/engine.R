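# Batched forward/backward engine for training. Sequences in a batch are
# packed as contiguous row blocks of one tall matrix (a "ragged" batch), so
# all linear sublayers are single BLAS calls and no padding enters the
# computation; attention loops over the per-sequence row blocks. Layouts and
# parameter names are identical to the inference path in transformer.R,
# which the tests exploit to cross-check the two.

# cache of strictly-upper-triangle linear indices for causal masking
.causal_env <- new.env(parent = emptyenv())
.upper_idx <- function(n) {
  key <- as.character(n)
  if (is.null(.causal_env[[key]]))
    .causal_env[[key]] <- which(outer(seq_len(n), seq_len(n), "<"))
  .causal_env[[key]]
}

.row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# multi-head attention forward over a ragged batch.
# Q,K,V: projected matrices (rows x d_model); off_*: 0-based row offsets.
.attn_fwd <- function(Q, K, V, off_q, off_kv, h, causal) {
  d <- ncol(Q); dk <- d %/% h; B <- length(off_q) - 1L
  O <- matrix(0, nrow(Q), d)
  A <- vector("list", B * h)
  inv_sqrt <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rq <- (off_q[b] + 1L):off_q[b + 1L]
    rk <- (off_kv[b] + 1L):off_kv[b + 1L]
    ui <- if (causal) .upper_idx(length(rq)) else NULL
    for (hd in seq_len(h)) {
      cols <- ((hd - 1L) * dk + 1L):(hd * dk)
      S <- tcrossprod(Q[rq, cols, drop = FALSE],
                      K[rk, cols, drop = FALSE]) * inv_sqrt
      if (causal && length(ui)) S[ui] <- -Inf
      W <- .row_softmax(S)
      A[[(b - 1L) * h + hd]] <- W
      O[rq, cols] <- W %*% V[rk, cols, drop = FALSE]
    }
  }
  list(O = O, A = A)
}

.attn_bwd <- function(dO, A, Q, K, V, off_q, off_kv, h) {
  d <- ncol(Q); dk <- d %/% h; B <- length(off_q) - 1L
  dQ <- matrix(0, nrow(Q), d)
  dK <- matrix(0, nrow(K), d)
  dV <- matrix(0, nrow(V), d)
  inv_sqrt <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rq <- (off_q[b] + 1L):off_q[b + 1L]
    rk <- (off_kv[b] + 1L):off_kv[b + 1L]
    for (hd in seq_len(h)) {
      cols <- ((hd - 1L) * dk + 1L):(hd * dk)
      W <- A[[(b - 1L) * h + hd]]
      dOb <- dO[rq, cols, drop = FALSE]
      Vb <- V[rk, cols, drop = FALSE]
      dW <- tcrossprod(dOb, Vb)
      dV[rk, cols] <- dV[rk, cols] + crossprod(W, dOb)
      dS <- W * (dW - rowSums(W * dW))
      dQ[rq, cols] <- (dS %*% K[rk, cols, drop = FALSE]) * inv_sqrt
      dK[rk, cols] <- dK[rk, cols] + crossprod(dS, Q[rq, cols, drop = FALSE]) * inv_sqrt
    }
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

.mha_fwd <- function(xq, xkv, p, pre, off_q, off_kv, h, causal) {
  Wq <- p[[paste0(pre, ".Wq")]]; Wk <- p[[paste0(pre, ".Wk")]]
  Wv <- p[[paste0(pre, ".Wv")]]; Wo <- p[[paste0(pre, ".Wo")]]
  Q <- xq %*% Wq; K <- xkv %*% Wk; V <- xkv %*% Wv
  at <- .attn_fwd(Q, K, V, off_q, off_kv, h, causal)
  list(y = at$O %*% Wo,
       cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V, O = at$O,
                    A = at$A, off_q = off_q, off_kv = off_kv))
}

.mha_bwd <- function(dy, cache, p, pre, h, g) {
  Wq <- p[[paste0(pre, ".Wq")]]; Wk <- p[[paste0(pre, ".Wk")]]
  Wv <- p[[paste0(pre, ".Wv")]]; Wo <- p[[paste0(pre, ".Wo")]]
  g[[paste0(pre, ".Wo")]] <- g[[paste0(pre, ".Wo")]] + crossprod(cache$O, dy)
  dO <- tcrossprod(dy, Wo)
  ab <- .attn_bwd(dO, cache$A, cache$Q, cache$K, cache$V,
                  cache$off_q, cache$off_kv, h)
  g[[paste0(pre, ".Wq")]] <- g[[paste0(pre, ".Wq")]] + crossprod(cache$xq, ab$dQ)
  g[[paste0(pre, ".Wk")]] <- g[[paste0(pre, ".Wk")]] + crossprod(cache$xkv, ab$dK)
  g[[paste0(pre, ".Wv")]] <- g[[paste0(pre, ".Wv")]] + crossprod(cache$xkv, ab$dV)
  dxq <- tcrossprod(ab$dQ, Wq)
  dxkv <- tcrossprod(ab$dK, Wk) + tcrossprod(ab$dV, Wv)
  list(dxq = dxq, dxkv = dxkv, g = g)
}

.ln_fwd <- function(x, g_, b_, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xn <- xc / sd
  y <- xn * matrix(g_, nrow(x), ncol(x), byrow = TRUE) +
    matrix(b_, nrow(x), ncol(x), byrow = TRUE)
  list(y = y, xn = xn, sd = sd)
}

.ln_bwd <- function(dy, cache, g_) {
  xn <- cache$xn
  dg <- matrix(colSums(dy * xn), 1)
  db <- matrix(colSums(dy), 1)
  dxn <- dy * matrix(g_, nrow(dy), ncol(dy), byrow = TRUE)
  dx <- (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn)) / cache$sd
  list(dx = dx, dg = dg, db = db)
}

.ffn_fwd <- function(x, p, pre) {
  W1 <- p[[paste0(pre, ".ff.W1")]]; b1 <- p[[paste0(pre, ".ff.b1")]]
  W2 <- p[[paste0(pre, ".ff.W2")]]; b2 <- p[[paste0(pre, ".ff.b2")]]
  H <- x %*% W1 + matrix(b1, nrow(x), ncol(W1), byrow = TRUE)
  Hr <- H * (H > 0)
  y <- Hr %*% W2 + matrix(b2, nrow(x), ncol(W2), byrow = TRUE)
  list(y = y, cache = list(x = x, H = H, Hr = Hr))
}

.ffn_bwd <- function(dy, cache, p, pre, g) {
  W1 <- p[[paste0(pre, ".ff.W1")]]; W2 <- p[[paste0(pre, ".ff.W2")]]
  g[[paste0(pre, ".ff.W2")]] <- g[[paste0(pre, ".ff.W2")]] + crossprod(cache$Hr, dy)
  g[[paste0(pre, ".ff.b2")]] <- g[[paste0(pre, ".ff.b2")]] + matrix(colSums(dy), 1)
  dHr <- tcrossprod(dy, W2)
  dH <- dHr * (cache$H > 0)
  g[[paste0(pre, ".ff.W1")]] <- g[[paste0(pre, ".ff.W1")]] + crossprod(cache$x, dH)
  g[[paste0(pre, ".ff.b1")]] <- g[[paste0(pre, ".ff.b1")]] + matrix(colSums(dH), 1)
  list(dx = tcrossprod(dH, W1), g = g)
}

# inverted-dropout mask (NULL when p == 0)
.drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}
.apply_drop <- function(x, m) if (is.null(m)) x else x * m

# full forward (+ optional backward) pass over one ragged batch.
# batch: list(src, off_src, tgt_in, tgt_lab, off_tgt) -- 0-based ids/offsets.
# Returns list(loss, n_tokens, grads?) where grads is a named list congruent
# with params.
.fwd_bwd <- function(params, config, batch, dropout = 0, grads = TRUE) {
  d <- config$d_model; h <- config$h; N <- config$N
  V <- nrow(params$embed)
  src <- batch$src; tgt_in <- batch$tgt_in; tgt_lab <- batch$tgt_lab
  off_s <- batch$off_src; off_t <- batch$off_tgt
  pe <- positional_encoding(max(diff(off_s), diff(off_t)), d)
  pos_s <- unlist(lapply(diff(off_s), seq_len), use.names = FALSE)
  pos_t <- unlist(lapply(diff(off_t), seq_len), use.names = FALSE)

  scale <- sqrt(d)
  Xs <- params$embed[src + 1L, , drop = FALSE] * scale + pe[pos_s, , drop = FALSE]
  ms_emb <- .drop_mask(nrow(Xs), d, dropout)
  Xs <- .apply_drop(Xs, ms_emb)

  enc_cache <- vector("list", N)
  x <- Xs
  for (i in seq_len(N)) {
    pre <- sprintf("enc%d", i)
    mh <- .mha_fwd(x, x, params, paste0(pre, ".self"), off_s, off_s, h, FALSE)
    dm1 <- .drop_mask(nrow(x), d, dropout)
    ln1 <- .ln_fwd(x + .apply_drop(mh$y, dm1),
                   params[[paste0(pre, ".ln1.g")]], params[[paste0(pre, ".ln1.b")]])
    ff <- .ffn_fwd(ln1$y, params, pre)
    dm2 <- .drop_mask(nrow(x), d, dropout)
    ln2 <- .ln_fwd(ln1$y + .apply_drop(ff$y, dm2),
                   params[[paste0(pre, ".ln2.g")]], params[[paste0(pre, ".ln2.b")]])
    enc_cache[[i]] <- list(x_in = x, mh = mh, dm1 = dm1, ln1 = ln1,
                           ff = ff, dm2 = dm2, ln2 = ln2)
    x <- ln2$y
  }
  memory <- x

  Xt <- params$embed[tgt_in + 1L, , drop = FALSE] * scale + pe[pos_t, , drop = FALSE]
  mt_emb <- .drop_mask(nrow(Xt), d, dropout)
  Xt <- .apply_drop(Xt, mt_emb)

  dec_cache <- vector("list", N)
  y <- Xt
  for (i in seq_len(N)) {
    pre <- sprintf("dec%d", i)
    mh <- .mha_fwd(y, y, params, paste0(pre, ".self"), off_t, off_t, h, TRUE)
    dm1 <- .drop_mask(nrow(y), d, dropout)
    ln1 <- .ln_fwd(y + .apply_drop(mh$y, dm1),
                   params[[paste0(pre, ".ln1.g")]], params[[paste0(pre, ".ln1.b")]])
    cr <- .mha_fwd(ln1$y, memory, params, paste0(pre, ".cross"), off_t, off_s,
                   h, FALSE)
    dm2 <- .drop_mask(nrow(y), d, dropout)
    ln2 <- .ln_fwd(ln1$y + .apply_drop(cr$y, dm2),
                   params[[paste0(pre, ".ln2.g")]], params[[paste0(pre, ".ln2.b")]])
    ff <- .ffn_fwd(ln2$y, params, pre)
    dm3 <- .drop_mask(nrow(y), d, dropout)
    ln3 <- .ln_fwd(ln2$y + .apply_drop(ff$y, dm3),
                   params[[paste0(pre, ".ln3.g")]], params[[paste0(pre, ".ln3.b")]])
    dec_cache[[i]] <- list(y_in = y, mh = mh, dm1 = dm1, ln1 = ln1, cr = cr,
                           dm2 = dm2, ln2 = ln2, ff = ff, dm3 = dm3, ln3 = ln3)
    y <- ln3$y
  }

  nT <- length(tgt_lab)
  Z <- y %*% params$out.W + matrix(params$out.b, nT, V, byrow = TRUE)
  m <- Z[cbind(seq_len(nT), max.col(Z, ties.method = "first"))]
  E <- exp(Z - m)
  sumE <- rowSums(E)
  logp_lab <- Z[cbind(seq_len(nT), tgt_lab + 1L)] - m - log(sumE)
  loss <- -mean(logp_lab)
  if (!grads) return(list(loss = loss, n_tokens = nT))

  P <- E / sumE
  dZ <- P
  dZ[cbind(seq_len(nT), tgt_lab + 1L)] <- dZ[cbind(seq_len(nT), tgt_lab + 1L)] - 1
  dZ <- dZ / nT

  g <- lapply(params, function(p) array(0, dim = dim(p)))
  g$out.W <- crossprod(y, dZ)
  g$out.b <- matrix(colSums(dZ), 1)
  dy <- tcrossprod(dZ, params$out.W)
  dmem <- matrix(0, nrow(memory), d)

  for (i in rev(seq_len(N))) {
    pre <- sprintf("dec%d", i)
    cc <- dec_cache[[i]]
    l3 <- .ln_bwd(dy, cc$ln3, params[[paste0(pre, ".ln3.g")]])
    g[[paste0(pre, ".ln3.g")]] <- g[[paste0(pre, ".ln3.g")]] + l3$dg
    g[[paste0(pre, ".ln3.b")]] <- g[[paste0(pre, ".ln3.b")]] + l3$db
    fb <- .ffn_bwd(.apply_drop(l3$dx, cc$dm3), cc$ff$cache, params, pre, g)
    g <- fb$g
    dy2 <- l3$dx + fb$dx
    l2 <- .ln_bwd(dy2, cc$ln2, params[[paste0(pre, ".ln2.g")]])
    g[[paste0(pre, ".ln2.g")]] <- g[[paste0(pre, ".ln2.g")]] + l2$dg
    g[[paste0(pre, ".ln2.b")]] <- g[[paste0(pre, ".ln2.b")]] + l2$db
    cb <- .mha_bwd(.apply_drop(l2$dx, cc$dm2), cc$cr$cache, params,
                   paste0(pre, ".cross"), h, g)
    g <- cb$g
    # cross-attention key/value gradients flow into the encoder memory
    dmem <- dmem + cb$dxkv
    dy1 <- l2$dx + cb$dxq
    l1 <- .ln_bwd(dy1, cc$ln1, params[[paste0(pre, ".ln1.g")]])
    g[[paste0(pre, ".ln1.g")]] <- g[[paste0(pre, ".ln1.g")]] + l1$dg
    g[[paste0(pre, ".ln1.b")]] <- g[[paste0(pre, ".ln1.b")]] + l1$db
    sb <- .mha_bwd(.apply_drop(l1$dx, cc$dm1), cc$mh$cache, params,
                   paste0(pre, ".self"), h, g)
    g <- sb$g
    dy <- l1$dx + sb$dxq + sb$dxkv
  }
  dXt <- .apply_drop(dy, mt_emb)
  ge_t <- rowsum(dXt * scale, tgt_in)
  g$embed[as.integer(rownames(ge_t)) + 1L, ] <-
    g$embed[as.integer(rownames(ge_t)) + 1L, ] + ge_t

  dx <- dmem
  for (i in rev(seq_len(N))) {
    pre <- sprintf("enc%d", i)
    cc <- enc_cache[[i]]
    l2 <- .ln_bwd(dx, cc$ln2, params[[paste0(pre, ".ln2.g")]])
    g[[paste0(pre, ".ln2.g")]] <- g[[paste0(pre, ".ln2.g")]] + l2$dg
    g[[paste0(pre, ".ln2.b")]] <- g[[paste0(pre, ".ln2.b")]] + l2$db
    fb <- .ffn_bwd(.apply_drop(l2$dx, cc$dm2), cc$ff$cache, params, pre, g)
    g <- fb$g
    dx1 <- l2$dx + fb$dx
    l1 <- .ln_bwd(dx1, cc$ln1, params[[paste0(pre, ".ln1.g")]])
    g[[paste0(pre, ".ln1.g")]] <- g[[paste0(pre, ".ln1.g")]] + l1$dg
    g[[paste0(pre, ".ln1.b")]] <- g[[paste0(pre, ".ln1.b")]] + l1$db
    sb <- .mha_bwd(.apply_drop(l1$dx, cc$dm1), cc$mh$cache, params,
                   paste0(pre, ".self"), h, g)
    g <- sb$g
    dx <- l1$dx + sb$dxq + sb$dxkv
  }
  dXs <- .apply_drop(dx, ms_emb)
  ge_s <- rowsum(dXs * scale, src)
  g$embed[as.integer(rownames(ge_s)) + 1L, ] <-
    g$embed[as.integer(rownames(ge_s)) + 1L, ] + ge_s

  list(loss = loss, n_tokens = nT, grads = g)
}

# Adam with the inverse-square-root warmup schedule conventional for this
# architecture: lr(t) = factor * d_model^-0.5 * min(t^-0.5, t * warmup^-1.5)
.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p))),
       v = lapply(params, function(p) array(0, dim = dim(p))),
       t = 0L)
}

.adam_step <- function(params, grads, state, config, warmup = 200,
                       lr_factor = 1, beta1 = 0.9, beta2 = 0.98, eps = 1e-9) {
  state$t <- state$t + 1L
  t <- state$t
  lr <- lr_factor * config$d_model^-0.5 * min(t^-0.5, t * warmup^-1.5)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat * gmat
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
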