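# The user-facing model interface: fit once, then predict / inspect with the
# usual methods.

#' Fit a retrosynthesis translation model
#'
#' Trains the attention-only encoder-decoder on a reaction dataset split
#' (teacher-forced cross-entropy over SMILES tokens, Adam with warmup,
#' periodic checkpoints) and keeps both the final checkpoint and the average
#' of the trailing checkpoints; prediction uses the averaged parameters by
#' default, which is the variant that tends to score best.
#'
#' @param data A `dataset_split` (from [make_splits()] or
#'   [generate_dataset()]), or a plain list of `reaction_record`s, which is
#'   then split 80/10/10 with `seed`.
#' @param config A [model_config()].
#' @param tconfig A [train_config()].
#' @param use_class_token Prefix sources with the reaction-class token.
#' @param seed Used only when `data` is an unsplit record list.
#' @return An object of class `retroformer` with components `params`
#'   (averaged), `params_last`, `run` (the full `train_run` including
#'   checkpoints and the step log), `vocab`, `config`, `tconfig`.
#' @seealso [predict.retroformer()], [evaluate_model()]
#' @export
retroformer <- function(data, config = model_config(),
                        tconfig = train_config(), use_class_token = TRUE,
                        seed = 1L) {
  split <- if (inherits(data, "dataset_split")) data
           else make_splits(data, seed = seed)
  run <- train_model(split, config, tconfig,
                     use_class_token = use_class_token)
  k <- min(tconfig$avg_window, length(run$checkpoints))
  last <- run$checkpoints[[length(run$checkpoints)]]
  structure(list(params = average_checkpoints(run$checkpoints, k),
                 params_last = last$params,
                 run = run, vocab = run$vocab, config = config,
                 tconfig = tconfig, use_class_token = use_class_token,
                 call = match.call()),
            class = "retroformer")
}

#' @export
print.retroformer <- function(x, ...) {
  last <- x$run$checkpoints[[length(x$run$checkpoints)]]
  cat("retrosynthesis transformer\n")
  print(x$config)
  cat(sprintf("  trained %d steps, %d checkpoints; final validation loss %.4f\n",
              last$step, length(x$run$checkpoints),
              last$val_loss))
  invisible(x)
}

#' @export
summary.retroformer <- function(object, ...) {
  log <- object$run$log
  ck <- log[!is.na(log$val_loss), , drop = FALSE]
  out <- list(config = object$config, tconfig = object$tconfig,
              vocab_size = vocab_size(object$vocab),
              n_params = sum(vapply(object$params, length, numeric(1))),
              steps = if (nrow(log)) max(log$step) else 0L,
              first_train_loss = if (nrow(log)) log$train_loss[1] else NA,
              last_train_loss = if (nrow(log))
                log$train_loss[nrow(log)] else NA,
              checkpoints = ck)
  class(out) <- "summary.retroformer"
  out
}

#' @export
print.summary.retroformer <- function(x, ...) {
  print(x$config)
  cat(sprintf("vocabulary %d tokens, %s learnable parameters\n",
              x$vocab_size, format(x$n_params, big.mark = ",")))
  cat(sprintf("training loss %.4f -> %.4f over %d steps\n",
              x$first_train_loss, x$last_train_loss, x$steps))
  if (nrow(x$checkpoints)) {
    cat("checkpoint validation losses:\n")
    print(x$checkpoints[, c("step", "val_loss")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.retroformer <- function(object, averaged = TRUE, ...) {
  if (averaged) object$params else object$params_last
}

#' Predict ranked reactant sets from a fitted model
#'
#' @param object A fitted [retroformer()] model.
#' @param newdata Character vector of product SMILES, or a list of
#'   `reaction_record`s (whose class ids are used when the model was trained
#'   with class tokens).
#' @param class_id Optional integer vector of reaction classes matching
#'   `newdata` when it is a character vector.
#' @param n Ranked predictions per product.
#' @param beam_width Beam size.
#' @param averaged Use the checkpoint-averaged parameters (default) or the
#'   last checkpoint.
#' @param max_len Maximum decoded length.
#' @param length_norm Rank beam hypotheses by per-token log-probability
#'   (see [predict_reactants()]).
#' @param ... Unused.
#' @return Named list, one ranked character vector (with `scores`
#'   attribute) per product.
#' @export
predict.retroformer <- function(object, newdata, class_id = NULL, n = 10L,
                                beam_width = max(n, 10L), averaged = TRUE,
                                max_len = 64L, length_norm = TRUE, ...) {
  params <- coef(object, averaged = averaged)
  if (is.list(newdata) && length(newdata) &&
      inherits(newdata[[1]], "reaction_record")) {
    products <- vapply(newdata, `[[`, character(1), "product")
    class_id <- vapply(newdata, `[[`, integer(1), "class_id")
    ids <- vapply(newdata, `[[`, character(1), "record_id")
  } else {
    products <- as.character(newdata)
    ids <- names(newdata)
    if (is.null(ids)) ids <- as.character(seq_along(products))
  }
  if (!object$use_class_token) class_id <- NULL
  out <- lapply(seq_along(products), function(i)
    predict_reactants(params, object$config, object$vocab, products[i],
                      class_id = if (!is.null(class_id)) class_id[i],
                      n = n, beam_width = beam_width, max_len = max_len,
                      length_norm = length_norm))
  names(out) <- ids
  out
}

#' @export
plot.retroformer <- function(x, ...) {
  log <- x$run$log
  if (!nrow(log)) stop("no training log to plot")
  plot(log$step, log$train_loss, type = "l", xlab = "step",
       ylab = "cross-entropy loss", main = "training curve", ...)
  ck <- log[!is.na(log$val_loss), , drop = FALSE]
  if (nrow(ck)) {
    graphics::lines(ck$step, ck$val_loss, type = "b", lty = 2)
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Evaluate a fitted model on a set of reaction records
#'
#' Beam-decodes every record's product and scores the ranked predictions
#' against the recorded reactants with [evaluate_predictions()].
#'
#' @param object A fitted `retroformer`.
#' @param records List of `reaction_record`s (e.g. the test split).
#' @param n,beam_width Decoding settings.
#' @param Ns Top-N levels to report.
#' @param averaged Use averaged (default) or last-checkpoint parameters.
#' @param annotations Optional plausibility annotations.
#' @param max_len Maximum decoded length.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(object, records, n = 10L, beam_width = max(n, 10L),
                           Ns = c(1L, 3L, 5L, 10L), averaged = TRUE,
                           annotations = NULL, max_len = 64L) {
  preds <- predict(object, records, n = n, beam_width = beam_width,
                   averaged = averaged, max_len = max_len)
  truths <- vapply(records, function(r) paste(r$reactants, collapse = "."),
                   character(1))
  evaluate_predictions(preds, truths,
                       vapply(records, `[[`, integer(1), "class_id"),
                       record_ids = vapply(records, `[[`, character(1),
                                           "record_id"),
                       Ns = Ns, annotations = annotations)
}
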