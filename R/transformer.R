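# Attention-only encoder-decoder core. These are the reference inference
# paths (one sequence at a time, dropout off); training uses the batched
# engine in engine.R over the same ParameterSet layout.

#' Model architecture configuration
#'
#' @param N Encoder/decoder depth (identical layers per stack).
#' @param d_model Embedding / residual stream width.
#' @param h Number of attention heads; must divide `d_model`.
#' @param d_ff Inner width of the position-wise feed-forward sublayer.
#' @param max_len Maximum supported sequence length.
#' @param dropout Dropout rate applied during training (disabled at
#'   inference).
#' @return A list of class `model_config`; `d_k = d_model / h` is derived so
#'   that `h * d_k == d_model` holds by construction.
#' @export
model_config <- function(N = 2L, d_model = 128L, h = 4L, d_ff = 256L,
                         max_len = 256L, dropout = 0.1) {
  N <- as.integer(N); d_model <- as.integer(d_model); h <- as.integer(h)
  d_ff <- as.integer(d_ff); max_len <- as.integer(max_len)
  if (any(c(N < 0, d_model < 1, h < 1, d_ff < 1, max_len < 1)))
    stop("all architecture counts must be positive (N may be 0)")
  if (d_model %% h != 0L)
    stop("h must divide d_model (h * d_k = d_model)")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(N = N, d_model = d_model, h = h, d_k = d_model %/% h,
                 d_ff = d_ff, max_len = max_len, dropout = dropout),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("transformer config: N=%d d_model=%d h=%d (d_k=%d) d_ff=%d max_len=%d dropout=%g\n",
              x$N, x$d_model, x$h, x$d_k, x$d_ff, x$max_len, x$dropout))
  invisible(x)
}

# expected parameter names for a config + vocabulary size
.param_shapes <- function(config, vocab_size) {
  d <- config$d_model; dff <- config$d_ff
  shapes <- list(embed = c(vocab_size, d),
                 out.W = c(d, vocab_size), out.b = c(1, vocab_size))
  sub <- function(prefix) {
    s <- list()
    for (w in c("Wq", "Wk", "Wv", "Wo")) s[[paste0(prefix, ".", w)]] <- c(d, d)
    s
  }
  ff_ln <- function(prefix, nln) {
    s <- list()
    s[[paste0(prefix, ".ff.W1")]] <- c(d, dff)
    s[[paste0(prefix, ".ff.b1")]] <- c(1, dff)
    s[[paste0(prefix, ".ff.W2")]] <- c(dff, d)
    s[[paste0(prefix, ".ff.b2")]] <- c(1, d)
    for (j in seq_len(nln)) {
      s[[paste0(prefix, ".ln", j, ".g")]] <- c(1, d)
      s[[paste0(prefix, ".ln", j, ".b")]] <- c(1, d)
    }
    s
  }
  for (i in seq_len(config$N)) {
    shapes <- c(shapes, sub(sprintf("enc%d.self", i)),
                ff_ln(sprintf("enc%d", i), 2L))
    shapes <- c(shapes, sub(sprintf("dec%d.self", i)),
                sub(sprintf("dec%d.cross", i)), ff_ln(sprintf("dec%d", i), 3L))
  }
  shapes
}

#' Initialize a parameter set for a model configuration
#'
#' Weights use scaled-uniform (Glorot) initialization from a local RNG
#' stream, so the caller's RNG state is untouched; layer-norm gains start at
#' 1 and all biases at 0.
#'
#' @param config A [model_config()].
#' @param vocab_size Vocabulary size (see [vocab_size()]).
#' @param seed Integer seed.
#' @return Named list of matrices (class `param_set`), addressable by name
#'   for checkpoint averaging.
#' @export
init_params <- function(config, vocab_size, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  shapes <- .param_shapes(config, vocab_size)
  params <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (grepl("\\.b[0-9]?$|\\.ln[0-9]\\.b$", nm)) {
      matrix(0, sh[1], sh[2])
    } else if (grepl("\\.g$", nm)) {
      matrix(1, sh[1], sh[2])
    } else {
      lim <- sqrt(6 / (sh[1] + sh[2]))
      matrix(stats::runif(prod(sh), -lim, lim), sh[1], sh[2])
    }
  })
  names(params) <- names(shapes)
  attr(params, "config") <- config
  attr(params, "vocab_size") <- as.integer(vocab_size)
  class(params) <- "param_set"
  params
}

#' Sinusoidal positional encoding matrix
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d_model))` and entry
#' `(pos, 2i+1)` the cosine of the same argument (positions and `i`
#' 0-based), the trigonometric scheme that injects token order into an
#' otherwise order-blind attention stack. All entries lie in `[-1, 1]`.
#'
#' @param length Number of positions (rows).
#' @param d_model Embedding width (columns).
#' @return A `length x d_model` matrix.
#' @export
positional_encoding <- function(length, d_model) {
  if (length < 1 || d_model < 1) stop("length and d_model must be positive")
  pos <- seq_len(length) - 1
  i2 <- 2 * ((seq_len(d_model) - 1) %/% 2)       # 0,0,2,2,4,4,...
  arg <- outer(pos, 10000^(i2 / d_model), "/")
  pe <- matrix(0, length, d_model)
  odd_cols <- seq(1, d_model, by = 2)            # 0-based even dims -> sin
  even_cols <- seq(2, d_model, by = 2)[seq_len(d_model %/% 2)]
  pe[, odd_cols] <- sin(arg[, odd_cols, drop = FALSE])
  if (d_model > 1) pe[, even_cols] <- cos(arg[, even_cols, drop = FALSE])
  pe
}

.softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`, with disallowed (query, key)
#' pairs receiving `-Inf` before normalization so they carry exactly zero
#' weight. Every query row must keep at least one allowed key.
#'
#' @param Q,K,V Matrices with `d_k` columns; `K` and `V` have equal row
#'   counts.
#' @param mask Optional logical matrix (`nrow(Q) x nrow(K)`) of allowed
#'   pairs; `NULL` allows everything.
#' @return List with `output` (`nrow(Q) x ncol(V)`) and `weights`
#'   (`nrow(Q) x nrow(K)`, rows summing to 1).
#' @export
scaled_dot_product_attention <- function(Q, K, V, mask = NULL) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share d_k")
  if (nrow(K) != nrow(V)) stop("K and V must have equal row counts")
  logits <- (Q %*% t(K)) / sqrt(ncol(K))
  if (!is.null(mask)) {
    if (!all(dim(mask) == c(nrow(Q), nrow(K))))
      stop("mask shape must be nrow(Q) x nrow(K)")
    if (any(rowSums(mask) == 0L))
      stop("a query row is fully masked (no allowed keys)")
    logits[!mask] <- -Inf
  }
  w <- .softmax_rows(logits)
  list(output = w %*% V, weights = w)
}

#' Multi-head attention
#'
#' Queries, keys and values are linearly projected, split into `h` heads of
#' width `d_k` each, attended independently with scaled dot-product
#' attention, concatenated, and projected back to `d_model`.
#'
#' @param x_q Query-side input (`n_q x d_model`).
#' @param x_kv Key/value-side input (`n_kv x d_model`).
#' @param proj Named list with projection matrices `Wq`, `Wk`, `Wv`, `Wo`
#'   (each `d_model x d_model`).
#' @param h Number of heads.
#' @param mask Optional logical `n_q x n_kv` matrix of allowed pairs.
#' @return `n_q x d_model` matrix.
#' @export
multi_head_attention <- function(x_q, x_kv, proj, h, mask = NULL) {
  for (w in c("Wq", "Wk", "Wv", "Wo"))
    if (is.null(proj[[w]])) stop("missing projection parameter: ", w)
  d <- ncol(x_q)
  if (ncol(x_kv) != d) stop("query and key/value widths must both be d_model")
  if (d %% h != 0L) stop("h must divide d_model")
  dk <- d %/% h
  Q <- x_q %*% proj$Wq; K <- x_kv %*% proj$Wk; V <- x_kv %*% proj$Wv
  out <- matrix(0, nrow(x_q), d)
  for (head in seq_len(h)) {
    cols <- ((head - 1L) * dk + 1L):(head * dk)
    att <- scaled_dot_product_attention(Q[, cols, drop = FALSE],
                                        K[, cols, drop = FALSE],
                                        V[, cols, drop = FALSE], mask)
    out[, cols] <- att$output
  }
  out %*% proj$Wo
}

# row-wise layer normalization with gain g and bias b (1 x d matrices)
.layer_norm <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xn <- xc / sd
  xn * matrix(g, nrow(x), ncol(x), byrow = TRUE) +
    matrix(b, nrow(x), ncol(x), byrow = TRUE)
}

.proj_group <- function(params, prefix) {
  list(Wq = params[[paste0(prefix, ".Wq")]],
       Wk = params[[paste0(prefix, ".Wk")]],
       Wv = params[[paste0(prefix, ".Wv")]],
       Wo = params[[paste0(prefix, ".Wo")]])
}

.ffn <- function(x, params, prefix) {
  h <- x %*% params[[paste0(prefix, ".ff.W1")]]
  h <- pmax(h + matrix(params[[paste0(prefix, ".ff.b1")]], nrow(h), ncol(h),
                       byrow = TRUE), 0)
  h %*% params[[paste0(prefix, ".ff.W2")]] +
    matrix(params[[paste0(prefix, ".ff.b2")]], nrow(x),
           ncol(params[[paste0(prefix, ".ff.W2")]]), byrow = TRUE)
}

#' Encode a source token sequence into a memory matrix
#'
#' Embeds the ids (scaled by `sqrt(d_model)`), adds the positional encoding,
#' and applies `N` identical layers of multi-head self-attention and
#' position-wise feed-forward sublayers, each wrapped in a residual
#' connection followed by layer normalization (post-norm). Padding ids are
#' masked out as attention keys, so appending `<PAD>` never changes the
#' memory rows of real tokens.
#'
#' @param ids Integer vector of 0-based token ids.
#' @param params A `param_set` from [init_params()] (or a trained model).
#' @param config The matching [model_config()].
#' @return `length(ids) x d_model` memory matrix.
#' @export
encode <- function(ids, params, config) {
  n <- length(ids)
  if (n == 0L) stop("empty source sequence")
  if (n > config$max_len) stop("source longer than max_len")
  if (any(ids < 0L | ids >= nrow(params$embed))) stop("id out of range")
  x <- params$embed[ids + 1L, , drop = FALSE] * sqrt(config$d_model) +
    positional_encoding(n, config$d_model)
  keep <- ids != .PAD
  if (!any(keep)) stop("source is all padding")
  mask <- matrix(keep, n, n, byrow = TRUE)
  for (i in seq_len(config$N)) {
    pre <- sprintf("enc%d", i)
    a <- multi_head_attention(x, x, .proj_group(params, paste0(pre, ".self")),
                              config$h, mask)
    x <- .layer_norm(x + a, params[[paste0(pre, ".ln1.g")]],
                     params[[paste0(pre, ".ln1.b")]])
    f <- .ffn(x, params, pre)
    x <- .layer_norm(x + f, params[[paste0(pre, ".ln2.g")]],
                     params[[paste0(pre, ".ln2.b")]])
  }
  x
}

# full decoder forward over a prefix; returns d_model rows for all positions
.decode_states <- function(memory, prefix_ids, params, config,
                           memory_keep = NULL) {
  n <- length(prefix_ids)
  x <- params$embed[prefix_ids + 1L, , drop = FALSE] * sqrt(config$d_model) +
    positional_encoding(n, config$d_model)
  causal <- outer(seq_len(n), seq_len(n), ">=")
  if (is.null(memory_keep)) memory_keep <- rep(TRUE, nrow(memory))
  cross_mask <- matrix(memory_keep, n, nrow(memory), byrow = TRUE)
  for (i in seq_len(config$N)) {
    pre <- sprintf("dec%d", i)
    a <- multi_head_attention(x, x, .proj_group(params, paste0(pre, ".self")),
                              config$h, causal)
    x <- .layer_norm(x + a, params[[paste0(pre, ".ln1.g")]],
                     params[[paste0(pre, ".ln1.b")]])
    c_ <- multi_head_attention(x, memory,
                               .proj_group(params, paste0(pre, ".cross")),
                               config$h, cross_mask)
    x <- .layer_norm(x + c_, params[[paste0(pre, ".ln2.g")]],
                     params[[paste0(pre, ".ln2.b")]])
    f <- .ffn(x, params, pre)
    x <- .layer_norm(x + f, params[[paste0(pre, ".ln3.g")]],
                     params[[paste0(pre, ".ln3.b")]])
  }
  x
}

#' One decoder step: next-token log-probabilities
#'
#' Runs the decoder stack over a `<BOS>`-initiated prefix with causally
#' masked self-attention (position `t` sees only positions `<= t`) and
#' cross-attention over all (non-padding) encoder memory rows, and returns
#' the normalized log-distribution over the vocabulary for the next token.
#'
#' @param memory Encoder output from [encode()].
#' @param prefix_ids Integer vector of 0-based ids beginning with `<BOS>`.
#' @param params A `param_set`.
#' @param config The matching [model_config()].
#' @param memory_keep Optional logical vector marking real (non-pad) memory
#'   rows; defaults to all rows.
#' @return Numeric vector of log-probabilities (length = vocabulary size;
#'   `log(sum(exp(.))) == 0` up to rounding).
#' @export
decode_step <- function(memory, prefix_ids, params, config,
                        memory_keep = NULL) {
  if (length(prefix_ids) == 0L) stop("empty decoder prefix")
  if (prefix_ids[1] != .BOS) stop("decoder prefix must begin with <BOS>")
  if (length(prefix_ids) > config$max_len) stop("prefix longer than max_len")
  x <- .decode_states(memory, prefix_ids, params, config, memory_keep)
  z <- drop(x[nrow(x), , drop = FALSE] %*% params$out.W) + drop(params$out.b)
  z - log(sum(exp(z - max(z)))) - max(z)
}
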