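# Independent straight-line reference implementation of the attention stack:
# scalar loops, one query at a time, no batching or masking tricks. Used as
# the oracle that the package's vectorized paths must reproduce.

ref_softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

ref_attention <- function(Q, K, V, mask = NULL) {
  out <- matrix(0, nrow(Q), ncol(V))
  W <- matrix(0, nrow(Q), nrow(K))
  for (qi in seq_len(nrow(Q))) {
    logits <- numeric(nrow(K))
    for (ki in seq_len(nrow(K))) {
      logits[ki] <- sum(Q[qi, ] * K[ki, ]) / sqrt(ncol(K))
      if (!is.null(mask) && !mask[qi, ki]) logits[ki] <- -Inf
    }
    w <- ref_softmax(logits)
    W[qi, ] <- w
    for (ki in seq_len(nrow(K))) out[qi, ] <- out[qi, ] + w[ki] * V[ki, ]
  }
  list(output = out, weights = W)
}

ref_mha <- function(x_q, x_kv, Wq, Wk, Wv, Wo, h, mask = NULL) {
  d <- ncol(x_q); dk <- d / h
  Q <- x_q %*% Wq; K <- x_kv %*% Wk; V <- x_kv %*% Wv
  concat <- matrix(0, nrow(x_q), d)
  for (head in seq_len(h)) {
    cols <- ((head - 1) * dk + 1):(head * dk)
    att <- ref_attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                         V[, cols, drop = FALSE], mask)
    concat[, cols] <- att$output
  }
  concat %*% Wo
}

ref_layer_norm <- function(x, g, b, eps = 1e-6) {
  out <- x
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    sd <- sqrt(mean((x[i, ] - mu)^2) + eps)
    out[i, ] <- (x[i, ] - mu) / sd * as.numeric(g) + as.numeric(b)
  }
  out
}

ref_ffn <- function(x, W1, b1, W2, b2) {
  h <- x %*% W1
  for (i in seq_len(nrow(h))) h[i, ] <- pmax(h[i, ] + as.numeric(b1), 0)
  y <- h %*% W2
  for (i in seq_len(nrow(y))) y[i, ] <- y[i, ] + as.numeric(b2)
  y
}

ref_pe <- function(len, d) {
  pe <- matrix(0, len, d)
  for (pos in 0:(len - 1)) {
    for (j in 0:(d - 1)) {
      i2 <- 2 * (j %/% 2)
      arg <- pos / 10000^(i2 / d)
      pe[pos + 1, j + 1] <- if (j %% 2 == 0) sin(arg) else cos(arg)
    }
  }
  pe
}

ref_encode <- function(ids, params, config) {
  n <- length(ids)
  x <- params$embed[ids + 1, , drop = FALSE] * sqrt(config$d_model) +
    ref_pe(n, config$d_model)
  mask <- matrix(rep(ids != 0L, each = n), n, n)
  for (i in seq_len(config$N)) {
    pre <- sprintf("enc%d", i)
    a <- ref_mha(x, x, params[[paste0(pre, ".self.Wq")]],
                 params[[paste0(pre, ".self.Wk")]],
                 params[[paste0(pre, ".self.Wv")]],
                 params[[paste0(pre, ".self.Wo")]], config$h, mask)
    x <- ref_layer_norm(x + a, params[[paste0(pre, ".ln1.g")]],
                        params[[paste0(pre, ".ln1.b")]])
    f <- ref_ffn(x, params[[paste0(pre, ".ff.W1")]],
                 params[[paste0(pre, ".ff.b1")]],
                 params[[paste0(pre, ".ff.W2")]],
                 params[[paste0(pre, ".ff.b2")]])
    x <- ref_layer_norm(x + f, params[[paste0(pre, ".ln2.g")]],
                        params[[paste0(pre, ".ln2.b")]])
  }
  x
}

ref_decode_logprobs <- function(memory, prefix, params, config,
                                memory_keep = NULL) {
  n <- length(prefix)
  x <- params$embed[prefix + 1, , drop = FALSE] * sqrt(config$d_model) +
    ref_pe(n, config$d_model)
  causal <- matrix(FALSE, n, n)
  for (qi in seq_len(n)) for (ki in seq_len(n)) causal[qi, ki] <- ki <= qi
  if (is.null(memory_keep)) memory_keep <- rep(TRUE, nrow(memory))
  cross <- matrix(rep(memory_keep, each = n), n, nrow(memory))
  for (i in seq_len(config$N)) {
    pre <- sprintf("dec%d", i)
    a <- ref_mha(x, x, params[[paste0(pre, ".self.Wq")]],
                 params[[paste0(pre, ".self.Wk")]],
                 params[[paste0(pre, ".self.Wv")]],
                 params[[paste0(pre, ".self.Wo")]], config$h, causal)
    x <- ref_layer_norm(x + a, params[[paste0(pre, ".ln1.g")]],
                        params[[paste0(pre, ".ln1.b")]])
    cr <- ref_mha(x, memory, params[[paste0(pre, ".cross.Wq")]],
                  params[[paste0(pre, ".cross.Wk")]],
                  params[[paste0(pre, ".cross.Wv")]],
                  params[[paste0(pre, ".cross.Wo")]], config$h, cross)
    x <- ref_layer_norm(x + cr, params[[paste0(pre, ".ln2.g")]],
                        params[[paste0(pre, ".ln2.b")]])
    f <- ref_ffn(x, params[[paste0(pre, ".ff.W1")]],
                 params[[paste0(pre, ".ff.b1")]],
                 params[[paste0(pre, ".ff.W2")]],
                 params[[paste0(pre, ".ff.b2")]])
    x <- ref_layer_norm(x + f, params[[paste0(pre, ".ln3.g")]],
                        params[[paste0(pre, ".ln3.b")]])
  }
  z <- as.numeric(x[n, , drop = FALSE] %*% params$out.W) +
    as.numeric(params$out.b)
  log(ref_softmax(z))
}

# exhaustive decoding oracle: scores every token sequence of length <=
# max_len (EOS-terminated or truncated) by summing decode_step
# log-probabilities, and returns them ranked like beam_search ranks
ref_enumerate_sequences <- function(params, config, src_ids, max_len) {
  memory <- retroformer::encode(src_ids, params, config)
  V <- nrow(params$embed)
  results <- list()
  recurse <- function(prefix, score) {
    lp <- retroformer::decode_step(memory, prefix, params, config)
    for (tok in 0:(V - 1)) {
      ids <- c(prefix, tok)
      s <- score + lp[tok + 1]
      if (tok == 2L) {  # EOS
        results[[length(results) + 1L]] <<-
          list(ids = ids, score = s, finished = TRUE)
      } else if (length(ids) - 1L < max_len) {
        recurse(ids, s)
      } else {
        results[[length(results) + 1L]] <<-
          list(ids = ids, score = s, finished = FALSE)
      }
    }
  }
  recurse(1L, 0)  # BOS
  results
}

# small helpers shared across test files
tiny_config <- function(N = 1L, d_model = 8L, h = 2L, d_ff = 16L,
                        dropout = 0) {
  model_config(N = N, d_model = d_model, h = h, d_ff = d_ff, max_len = 64L,
               dropout = dropout)
}

toy_records <- function(n = 20L) {
  lib <- default_fragments()
  tpl <- default_templates()[[1]]
  grid <- expand.grid(ACYL = lib$acyl, ALKYL = lib$alkyl,
                      stringsAsFactors = FALSE)
  lapply(seq_len(min(n, nrow(grid))), function(i)
    apply_template(tpl, c(ACYL = grid$ACYL[i], ALKYL = grid$ALKYL[i]),
                   record_id = sprintf("toy-%02d", i)))
}

read_fixture <- function(name) {
  utils::read.table(testthat::test_path("fixtures", name), sep = "\t",
                    header = TRUE, quote = "", comment.char = "",
                    stringsAsFactors = FALSE)
}
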