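# Training: token-budget batching, the optimization loop, checkpointing and
# checkpoint averaging.

#' Training configuration
#'
#' @param batch_tokens Token budget per batch. "Batch size" is counted in
#'   tokens, not sequences: a batch is closed once adding the next sequence
#'   would push its padded token count (batch-max length times batch size)
#'   over this budget. Source and target tokens are counted together, since
#'   both sides occupy memory during a step.
#' @param max_steps Number of optimization steps (0 trains nothing and emits
#'   the initialization as the only checkpoint).
#' @param checkpoint_interval Steps between saved checkpoints. At full
#'   corpus scale the conventional cadence is 2000 steps with the last 20
#'   checkpoints averaged; desk-scale defaults are 50 and 5.
#' @param avg_window Default number of trailing checkpoints averaged by
#'   [average_checkpoints()].
#' @param seed Integer seed governing initialization, epoch shuffling and
#'   dropout.
#' @param warmup,lr_factor Inverse-square-root Adam schedule:
#'   `lr(t) = lr_factor * d_model^-0.5 * min(t^-0.5, t * warmup^-1.5)`.
#' @param val_cap Maximum validation sequences used for checkpoint
#'   validation loss.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_tokens = 1500L, max_steps = 600L,
                         checkpoint_interval = 50L, avg_window = 5L,
                         seed = 1L, warmup = 200, lr_factor = 2,
                         val_cap = 256L) {
  if (batch_tokens < 1L) stop("batch_tokens must be positive")
  if (max_steps < 0L) stop("max_steps must be non-negative")
  if (checkpoint_interval < 1L) stop("checkpoint_interval must be positive")
  structure(list(batch_tokens = as.integer(batch_tokens),
                 max_steps = as.integer(max_steps),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 avg_window = as.integer(avg_window), seed = as.integer(seed),
                 warmup = warmup, lr_factor = lr_factor,
                 val_cap = as.integer(val_cap)),
            class = "train_config")
}

#' Greedy in-order token-budget batching
#'
#' Walks the sequences in corpus order; a sequence joins the current batch
#' iff the padded cost of the extended batch -- its new maximum length times
#' its new size -- stays within `batch_tokens`, otherwise it starts a new
#' batch. Every index appears in exactly one batch.
#'
#' @param lengths Integer vector of sequence lengths in corpus order.
#' @param batch_tokens Token budget per batch.
#' @return List of integer index vectors.
#' @examples
#' pack_batches_by_tokens(c(5, 7, 8), 16)  # list(c(1, 2), 3)
#' @export
pack_batches_by_tokens <- function(lengths, batch_tokens) {
  over <- which(lengths > batch_tokens)
  if (length(over))
    stop("sequence ", over[1], " (length ", lengths[over[1]],
         ") exceeds the token budget ", batch_tokens)
  batches <- list()
  cur <- integer(0); cur_max <- 0L
  for (i in seq_along(lengths)) {
    new_max <- max(cur_max, lengths[i])
    if (length(cur) > 0L && new_max * (length(cur) + 1L) > batch_tokens) {
      batches[[length(batches) + 1L]] <- cur
      cur <- i; cur_max <- lengths[i]
    } else {
      cur <- c(cur, i); cur_max <- new_max
    }
  }
  if (length(cur)) batches[[length(batches) + 1L]] <- cur
  batches
}

# tokenized id sequences for a list of records
.prep_sequences <- function(records, vocab, use_class_token = TRUE) {
  lapply(records, function(r) {
    src_toks <- tokenize_smiles(r$product)
    if (use_class_token)
      src_toks <- c(sprintf("<RX_%d>", r$class_id), src_toks)
    tgt_toks <- tokenize_smiles(paste(r$reactants, collapse = "."))
    src <- encode_tokens(vocab, src_toks)
    tgt <- encode_tokens(vocab, tgt_toks)
    list(src = src, tgt_in = c(.BOS, tgt), tgt_lab = c(tgt, .EOS))
  })
}

# assemble a ragged batch from prepared sequences
.make_batch <- function(seqs, idx) {
  sel <- seqs[idx]
  src <- lapply(sel, `[[`, "src")
  tin <- lapply(sel, `[[`, "tgt_in")
  tlab <- lapply(sel, `[[`, "tgt_lab")
  list(src = unlist(src, use.names = FALSE),
       off_src = c(0L, cumsum(lengths(src))),
       tgt_in = unlist(tin, use.names = FALSE),
       tgt_lab = unlist(tlab, use.names = FALSE),
       off_tgt = c(0L, cumsum(lengths(tin))))
}

.val_loss <- function(params, config, val_batches) {
  if (length(val_batches) == 0L) return(NA_real_)
  tot <- 0; ntok <- 0
  for (b in val_batches) {
    r <- .fwd_bwd(params, config, b, dropout = 0, grads = FALSE)
    tot <- tot + r$loss * r$n_tokens
    ntok <- ntok + r$n_tokens
  }
  tot / ntok
}

#' Train the translation model
#'
#' Teacher-forced cross-entropy training of the encoder-decoder over a
#' dataset split, with Adam under an inverse-square-root warmup schedule.
#' Checkpoints (parameters, optimizer state, validation loss) are emitted
#' every `checkpoint_interval` steps; with a fixed seed the loss trajectory
#' is reproducible on one machine. If the loss turns non-finite the run
#' aborts, retaining the checkpoints saved so far.
#'
#' @param split A `dataset_split` (see [make_splits()] or
#'   [generate_dataset()]); `train` and `validation` parts are used.
#' @param config A [model_config()].
#' @param tconfig A [train_config()].
#' @param vocab Optional `retro_vocab`; built from the split (with 10 class
#'   tokens) when omitted.
#' @param use_class_token Prefix the source with the record's
#'   reaction-class token (`<RX_k>`).
#' @return A list of class `train_run`: `checkpoints` (list of
#'   `checkpoint`s), `log` (data.frame step/train_loss/val_loss), `vocab`,
#'   `config`, `tconfig`, `use_class_token`.
#' @export
train_model <- function(split, config, tconfig = train_config(),
                        vocab = NULL, use_class_token = TRUE) {
  records <- split$train
  if (length(records) == 0L) stop("empty training split")
  if (is.null(vocab)) {
    corpus <- lapply(c(split$train, split$validation, split$test),
                     function(r) c(tokenize_smiles(r$product),
                                   tokenize_smiles(paste(r$reactants,
                                                         collapse = "."))))
    vocab <- build_vocabulary(corpus, class_count = 10L)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(tconfig$seed)

  seqs <- .prep_sequences(records, vocab, use_class_token)
  lens <- vapply(seqs, function(s) length(s$src) + length(s$tgt_in), integer(1))
  if (max(lens) > tconfig$batch_tokens)
    stop("batch_tokens must be at least the longest (source+target) sequence: ",
         max(lens))

  val_recs <- split$validation
  if (length(val_recs) > tconfig$val_cap)
    val_recs <- val_recs[seq_len(tconfig$val_cap)]
  val_batches <- if (length(val_recs)) {
    vseqs <- .prep_sequences(val_recs, vocab, use_class_token)
    vlens <- vapply(vseqs, function(s) length(s$src) + length(s$tgt_in),
                    integer(1))
    lapply(pack_batches_by_tokens(vlens, max(tconfig$batch_tokens, max(vlens))),
           function(ix) .make_batch(vseqs, ix))
  } else list()

  params <- init_params(config, vocab_size(vocab), seed = tconfig$seed)
  opt <- .adam_init(params)
  checkpoints <- list()
  log_step <- integer(0); log_train <- numeric(0); log_val <- numeric(0)

  save_ckpt <- function(step, params, opt, vl) {
    checkpoints[[length(checkpoints) + 1L]] <<-
      structure(list(step = step, params = params, opt_state = opt,
                     val_loss = vl), class = "checkpoint")
  }

  if (tconfig$max_steps == 0L) {
    save_ckpt(0L, params, opt, .val_loss(params, config, val_batches))
  } else {
    step <- 0L
    diverged <- FALSE
    while (step < tconfig$max_steps && !diverged) {
      order <- sample.int(length(seqs))
      batches <- pack_batches_by_tokens(lens[order], tconfig$batch_tokens)
      for (ix in batches) {
        step <- step + 1L
        batch <- .make_batch(seqs, order[ix])
        r <- .fwd_bwd(params, config, batch, dropout = config$dropout,
                      grads = TRUE)
        if (!is.finite(r$loss)) {
          warning("loss diverged at step ", step,
                  "; aborting with last good checkpoint retained")
          diverged <- TRUE
          break
        }
        upd <- .adam_step(params, r$grads, opt, config,
                          warmup = tconfig$warmup,
                          lr_factor = tconfig$lr_factor)
        params <- upd$params; opt <- upd$state
        is_ckpt <- step %% tconfig$checkpoint_interval == 0L ||
          step == tconfig$max_steps
        vl <- if (is_ckpt) .val_loss(params, config, val_batches) else NA_real_
        log_step <- c(log_step, step)
        log_train <- c(log_train, r$loss)
        log_val <- c(log_val, vl)
        if (is_ckpt) save_ckpt(step, params, opt, vl)
        if (step >= tconfig$max_steps) break
      }
    }
  }

  structure(list(checkpoints = checkpoints,
                 log = data.frame(step = log_step, train_loss = log_train,
                                  val_loss = log_val),
                 vocab = vocab, config = config, tconfig = tconfig,
                 use_class_token = use_class_token),
            class = "train_run")
}

#' @export
print.checkpoint <- function(x, ...) {
  cat(sprintf("checkpoint at step %d (validation loss %s)\n", x$step,
              formatC(x$val_loss)))
  invisible(x)
}

#' Average the trailing checkpoints of a run
#'
#' Element-wise arithmetic mean, name by name, of the parameter sets of the
#' last `k` checkpoints; optimizer state is discarded. Averaging the tail of
#' a converged run typically beats the final single checkpoint.
#'
#' @param checkpoints List of `checkpoint`s (or a `train_run`).
#' @param k Number of trailing checkpoints to average.
#' @return A `param_set`.
#' @export
average_checkpoints <- function(checkpoints, k) {
  if (inherits(checkpoints, "train_run")) checkpoints <- checkpoints$checkpoints
  if (length(checkpoints) < k)
    stop("need at least k = ", k, " checkpoints, have ", length(checkpoints))
  tail_ck <- checkpoints[(length(checkpoints) - k + 1L):length(checkpoints)]
  ref <- tail_ck[[1L]]$params
  nms <- names(ref)
  for (ck in tail_ck) {
    if (!identical(names(ck$params), nms))
      stop("checkpoint parameter names differ")
    for (nm in nms)
      if (!identical(dim(ck$params[[nm]]), dim(ref[[nm]])))
        stop("checkpoint parameter shapes differ for ", nm)
  }
  avg <- ref
  for (nm in nms) {
    s <- ref[[nm]]
    for (ck in tail_ck[-1L]) s <- s + ck$params[[nm]]
    avg[[nm]] <- s / k
  }
  avg
}
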