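# End-to-end pipeline: prepare -> train -> average -> predict -> evaluate ->
# report, driven by a YAML config, with a manifest per stage for provenance.

.require_field <- function(config, path) {
  node <- config
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    node <- node[[p]]
    if (is.null(node))
      stop(structure(class = c("retro_config_error", "error", "condition"),
                     list(message = paste0("config missing `", path, "`"),
                          call = NULL)))
  }
  node
}

.stage_manifest <- function(dir, stage, inputs, seed, config) {
  tf <- tempfile(); on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  input_hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs[file.exists(inputs)])
    as.list(h)
  } else list()
  manifest <- list(stage = stage, inputs = input_hashes, seed = seed,
                   config_hash = unname(tools::md5sum(tf)),
                   tool_version = as.character(utils::packageVersion("retroformer")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full retrosynthesis pipeline from a YAML config
#'
#' Stages run in order: prepare (generate the synthetic dataset or read TSV
#' splits), train, average, predict (test split), evaluate, report. Each
#' stage writes its outputs plus a manifest (input hashes, seed, config
#' hash) into the run directory; rerunning with an identical config and seed
#' reproduces all deterministic artifacts.
#'
#' Config schema (YAML): `out_dir`; `seed`; `data` (`source`:
#' `"synthetic"` or `"tsv"`, `heldout_fraction` or `dir`); `model`
#' (`N`, `d_model`, `h`, `d_ff`, `dropout`, `max_len`); `training`
#' (`batch_tokens`, `max_steps`, `checkpoint_interval`, `avg_window`,
#' `warmup`, `lr_factor`); `evaluate` (`n`, `beam_width`, `max_records`).
#' A missing required field raises a `retro_config_error` naming it.
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Optional override of the config's `out_dir`.
#' @return Invisibly, a list with the fitted model, the evaluation report
#'   and the run directory.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  for (f in c("out_dir", "seed", "data.source", "model.N", "model.d_model",
              "model.h", "model.d_ff", "training.batch_tokens",
              "training.max_steps", "evaluate.n"))
    .require_field(cfg, f)
  dir <- if (is.null(out_dir)) cfg$out_dir else out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  logf <- file.path(dir, "pipeline.log")
  say <- function(stage, ...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), "\t", stage, "\t",
                   paste0(...))
    cat(line, "\n", sep = "")
    cat(line, "\n", sep = "", file = logf, append = TRUE)
  }

  say("prepare", "building dataset")
  split <- if (cfg$data$source == "synthetic") {
    generate_dataset(seed = seed,
                     heldout_fraction = if (is.null(cfg$data$heldout_fraction))
                       0.1 else cfg$data$heldout_fraction)
  } else if (cfg$data$source == "tsv") {
    read_splits(.require_field(cfg, "data.dir"))
  } else stop("unknown data.source: ", cfg$data$source)
  write_splits(split, file.path(dir, "data"))
  .stage_manifest(dir, "prepare", character(0), seed, cfg$data)

  say("train", length(split$train), " records")
  mconf <- model_config(N = cfg$model$N, d_model = cfg$model$d_model,
                        h = cfg$model$h, d_ff = cfg$model$d_ff,
                        max_len = if (is.null(cfg$model$max_len)) 256L
                                  else cfg$model$max_len,
                        dropout = if (is.null(cfg$model$dropout)) 0.1
                                  else cfg$model$dropout)
  targs <- cfg$training
  tconf <- train_config(
    batch_tokens = targs$batch_tokens, max_steps = targs$max_steps,
    checkpoint_interval = if (is.null(targs$checkpoint_interval)) 50L
                          else targs$checkpoint_interval,
    avg_window = if (is.null(targs$avg_window)) 5L else targs$avg_window,
    seed = seed,
    warmup = if (is.null(targs$warmup)) 200 else targs$warmup,
    lr_factor = if (is.null(targs$lr_factor)) 2 else targs$lr_factor)
  fit <- retroformer(split, mconf, tconf)
  write_vocabulary(fit$vocab, file.path(dir, "vocab.tsv"))
  utils::write.table(fit$run$log, file.path(dir, "train.log"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .stage_manifest(dir, "train",
                  file.path(dir, "data", c("train.tsv", "validation.tsv")),
                  seed, cfg[c("model", "training")])
  say("average", "window ", tconf$avg_window)

  test_recs <- split$test
  if (!is.null(cfg$evaluate$max_records) &&
      length(test_recs) > cfg$evaluate$max_records)
    test_recs <- test_recs[seq_len(cfg$evaluate$max_records)]
  n <- cfg$evaluate$n
  bw <- if (is.null(cfg$evaluate$beam_width)) max(n, 10L)
        else cfg$evaluate$beam_width
  say("predict", length(test_recs), " test records, beam ", bw)
  preds <- predict(fit, test_recs, n = n, beam_width = bw)
  pred_df <- do.call(rbind, lapply(seq_along(preds), function(i)
    data.frame(record_id = names(preds)[i],
               rank = seq_along(preds[[i]]),
               score = attr(preds[[i]], "scores"),
               prediction = as.character(preds[[i]]))))
  utils::write.table(pred_df, file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .stage_manifest(dir, "predict", file.path(dir, "data", "test.tsv"),
                  seed, cfg$evaluate)

  say("evaluate", "scoring")
  truths <- vapply(test_recs, function(r) paste(r$reactants, collapse = "."),
                   character(1))
  report <- evaluate_predictions(
    preds, truths, vapply(test_recs, `[[`, integer(1), "class_id"),
    record_ids = vapply(test_recs, `[[`, character(1), "record_id"),
    Ns = sort(unique(c(1L, pmin(n, c(3L, 5L, 10L))))))
  write_report_json(report, file.path(dir, "report.json"))

  say("report", "rendering markdown")
  md <- render_report(report)
  writeLines(md, file.path(dir, "report.md"))
  .stage_manifest(dir, "report", file.path(dir, "report.json"), seed, list())
  say("done", "top-1 ", sprintf("%.1f%%", 100 * report$per_n[["top1"]]))
  invisible(list(fit = fit, report = report, dir = dir))
}

.pct <- function(x) sprintf("%.1f%%", 100 * x)

#' Render an evaluation report as markdown tables
#'
#' Deterministic rendering with one-decimal percentage formatting: top-N
#' accuracies, per-class top-N accuracies, rank-1 invalidity, failure
#' categories, and (when present) the corrected-accuracy breakdown.
#'
#' @param report An `eval_report`, or the path of a JSON file written by
#'   [write_report_json()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  if (is.character(report)) {
    js <- jsonlite::read_json(report)
    need <- c("n_test", "top_n", "per_class", "invalidity",
              "failure_categories")
    miss <- setdiff(need, names(js))
    if (length(miss))
      stop("report is missing section(s): ", paste(miss, collapse = ", "))
    per_n <- unlist(js$top_n)
    per_class <- do.call(rbind, lapply(js$per_class, unlist))
    inval <- js$invalidity
    fc <- do.call(rbind, lapply(js$failure_categories, function(r)
      data.frame(category = r$category, count = r$count, rate = r$rate)))
    corrected <- js$corrected
    corrected_breakdown <- if (!is.null(js$corrected_breakdown))
      do.call(rbind, lapply(js$corrected_breakdown, function(r)
        data.frame(type = r$type, count = r$count, rate = r$rate)))
    n_test <- js$n_test
  } else {
    for (f in c("per_n", "per_class", "invalidity", "failure_categories"))
      if (is.null(report[[f]])) stop("report is missing section(s): ", f)
    per_n <- report$per_n; per_class <- report$per_class
    inval <- report$invalidity; fc <- report$failure_categories
    corrected <- report$corrected
    corrected_breakdown <- report$corrected$breakdown
    n_test <- report$n_test
  }
  out <- c(sprintf("# Retrosynthesis evaluation (%d test records)", n_test),
           "", "## Top-N accuracy", "", "| N | accuracy |", "|---|---|")
  for (nm in names(per_n))
    out <- c(out, sprintf("| %s | %s |", sub("top", "top-", nm),
                          .pct(per_n[[nm]])))
  out <- c(out, "", "## Top-N accuracy per reaction class", "",
           paste0("| class | ", paste(colnames(per_class), collapse = " | "),
                  " |"),
           paste0("|", paste(rep("---", ncol(per_class) + 1), collapse = "|"),
                  "|"))
  for (r in rownames(per_class))
    out <- c(out, paste0("| ", sub("class_", "", r), " | ",
                         paste(.pct(per_class[r, ]), collapse = " | "), " |"))
  out <- c(out, "", "## Grammatical invalidity (rank 1)", "",
           sprintf("Overall: %s", .pct(inval$overall)))
  out <- c(out, "", "## Failure categories", "")
  body <- fc[fc$category != "Total", , drop = FALSE]
  if (sum(body$count) == 0) {
    out <- c(out, "none")
  } else {
    out <- c(out, "| structure | count | rate |", "|---|---|---|")
    for (i in seq_len(nrow(fc)))
      out <- c(out, sprintf("| %s | %d | %s |", fc$category[i],
                            as.integer(fc$count[i]), .pct(fc$rate[i])))
  }
  if (!is.null(corrected)) {
    out <- c(out, "", "## Corrected (\"true\") accuracy", "",
             sprintf("Exact: %s; plausible: %s; corrected top-1: %.1f%%",
                     .pct(corrected$exact_fraction),
                     .pct(corrected$plausible_fraction),
                     corrected$rate_sum_pct), "")
    if (!is.null(corrected_breakdown)) {
      out <- c(out, "| reaction type | count | rate |", "|---|---|---|")
      for (i in seq_len(nrow(corrected_breakdown)))
        out <- c(out, sprintf("| %s | %d | %s |",
                              corrected_breakdown$type[i],
                              as.integer(corrected_breakdown$count[i]),
                              .pct(corrected_breakdown$rate[i])))
    }
  }
  out
}
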