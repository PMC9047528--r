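# Scoring: top-N canonical-match accuracy (overall and per reaction class),
# grammatical-invalidity rates, failure-mode categorization, and
# annotation-corrected ("true") accuracy.

# first matching rank per record (Inf when no prediction matches).
# predictions: list of ranked character vectors, truths: character vector.
.match_ranks <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  if (anyNA(truths)) stop("missing ground truth for a record")
  nper <- lengths(predictions)
  if (any(nper == 0L)) stop("every record needs at least one prediction")
  flat_pred <- unlist(predictions, use.names = FALSE)
  flat_truth <- rep(truths, nper)
  hit <- reactant_set_match(flat_pred, flat_truth)
  ranks <- rep(Inf, length(truths))
  offset <- c(0L, cumsum(nper))
  for (i in seq_along(truths)) {
    h <- which(hit[(offset[i] + 1L):offset[i + 1L]])
    if (length(h)) ranks[i] <- h[1]
  }
  ranks
}

#' Top-N exact-match accuracy
#'
#' For each N, the fraction of records whose ground-truth reactant set is
#' found (canonical multiset match, [reactant_set_match()]) among the N
#' highest-ranked predictions.
#'
#' @param predictions List (one element per record) of ranked character
#'   vectors of predicted dot-separated reactant SMILES.
#' @param truths Character vector of ground-truth reactant strings.
#' @param Ns Integer vector of N values.
#' @return Named numeric vector of fractions, names `top1`, `top3`, ...
#' @export
top_n_accuracy <- function(predictions, truths, Ns = c(1L, 3L, 5L, 10L)) {
  ranks <- .match_ranks(predictions, truths)
  out <- vapply(Ns, function(n) mean(ranks <= n), numeric(1))
  names(out) <- paste0("top", Ns)
  out
}

#' Per-class top-N accuracy
#'
#' Top-N accuracy restricted to each reaction class; classes with no records
#' are absent from the result rather than reported as zero.
#'
#' @inheritParams top_n_accuracy
#' @param class_ids Integer vector of reaction classes per record.
#' @param N Single N.
#' @param n_classes Number of declared classes (ids must be in `1:n_classes`).
#' @return Named numeric vector `class_<k>` -> fraction.
#' @export
per_class_accuracy <- function(predictions, truths, class_ids, N = 10L,
                               n_classes = 10L) {
  if (length(class_ids) != length(truths))
    stop("class ids must be known for all records")
  if (any(is.na(class_ids)) || any(class_ids < 1L | class_ids > n_classes))
    stop("unknown class id")
  ranks <- .match_ranks(predictions, truths)
  present <- sort(unique(class_ids))
  out <- vapply(present, function(k) mean(ranks[class_ids == k] <= N),
                numeric(1))
  names(out) <- paste0("class_", present)
  out
}

#' Grammatical-invalidity rate of rank-1 predictions
#'
#' Fraction of records whose top-ranked prediction fails
#' [is_valid_smiles()], overall and per reaction class.
#'
#' @param rank1_predictions Character vector of rank-1 predictions.
#' @param class_ids Optional integer vector of reaction classes.
#' @return List with `overall` and (when classes are given) `per_class`.
#' @export
invalidity_rate <- function(rank1_predictions, class_ids = NULL) {
  bad <- !is_valid_smiles(rank1_predictions)
  out <- list(overall = mean(bad))
  if (!is.null(class_ids)) {
    present <- sort(unique(class_ids))
    pc <- vapply(present, function(k) mean(bad[class_ids == k]), numeric(1))
    names(pc) <- paste0("class_", present)
    out$per_class <- pc
  }
  out
}

#' Categorize failed predictions by problem substructure
#'
#' Each failed record is checked against the motif registry (Boc, CF3, tBu
#' patterns and the fused/spiro/bridged ring classes) on its ground-truth
#' molecules, and assigned every matching category after precedence
#' suppression (Boc suppresses tBu). The total row is the sum over
#' categories, counting a record once per category it falls in; rates use
#' the number of failed records as denominator.
#'
#' @param failed data.frame with columns `record_id` and `truth`
#'   (dot-separated ground-truth SMILES of records whose prediction failed).
#' @param registry Motif registry, see [default_failure_registry()].
#' @return data.frame with columns `category`, `count`, `rate`, ending in a
#'   `Total` row.
#' @export
categorize_failures <- function(failed, registry = default_failure_registry()) {
  if (!all(c("record_id", "truth") %in% names(failed)))
    stop("failed must have columns record_id and truth")
  ok <- vapply(registry$value[registry$kind == "pattern"], function(p)
    !inherits(tryCatch(parse_smiles(p), error = identity), "error"),
    logical(1))
  if (!all(ok))
    stop("malformed pattern in registry: ",
         paste(registry$value[registry$kind == "pattern"][!ok], collapse = ", "))
  n_failed <- nrow(failed)
  hits <- matrix(FALSE, n_failed, nrow(registry),
                 dimnames = list(NULL, registry$category))
  for (i in seq_len(n_failed)) {
    mols <- strsplit(failed$truth[i], ".", fixed = TRUE)[[1]]
    mols <- mols[is_valid_smiles(mols)]
    if (!length(mols)) next
    rclass <- vapply(mols, classify_ring_system, character(1))
    for (j in seq_len(nrow(registry))) {
      hits[i, j] <- if (registry$kind[j] == "pattern") {
        any(vapply(mols, has_substructure, logical(1),
                   pattern = registry$value[j]))
      } else any(rclass == registry$value[j])
    }
  }
  for (j in which(nzchar(registry$precedence_over))) {
    sup <- strsplit(registry$precedence_over[j], ",", fixed = TRUE)[[1]]
    for (s in trimws(sup)) hits[hits[, registry$category[j]], s] <- FALSE
  }
  counts <- colSums(hits)
  df <- data.frame(category = c(registry$category, "Total"),
                   count = c(counts, sum(counts)),
                   rate = c(counts, sum(counts)) /
                     max(n_failed, 1L),
                   row.names = NULL, stringsAsFactors = FALSE)
  df
}

# the fixed plausibility category list of the annotation scheme
.PLAUSIBLE_TYPES <- c("oxidation", "protection", "hydrolysis", "C-C coupling",
                      "SN2", "reduction", "condensation", "other")

#' Read plausibility annotations
#'
#' TSV with columns `record_id`, `plausible` (true/false), `type` (one of
#' the fixed reaction-type categories).
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("record_id", "plausible", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$plausible <- as.logical(df$plausible)
  bad <- setdiff(unique(df$type), .PLAUSIBLE_TYPES)
  if (length(bad))
    stop("unknown plausibility type(s): ", paste(bad, collapse = ", "))
  df
}

#' Annotation-corrected ("true") accuracy
#'
#' Exact-match accuracy understates a model when predictions that differ
#' from the recorded reactants are nonetheless chemically sound routes. The
#' corrected count adds the expert-annotated plausible records to the exact
#' matches. Two forms are reported: the count form
#' `(exact + plausible) / n_test`, and the rate-sum form -- the exact-match
#' percentage plus the total plausible percentage, each rounded to one
#' decimal before summing, which is how such headline figures are printed.
#'
#' @param n_test Test-set size.
#' @param exact_match_count Number of exact top-1 matches.
#' @param annotations data.frame as from [read_annotations()]; only rows
#'   with `plausible == TRUE` are counted.
#' @param matched_ids Optional character vector of record ids that matched
#'   exactly; used to reject double counting.
#' @return List with `corrected_count`, `corrected_fraction`,
#'   `exact_fraction`, `plausible_fraction`, `rate_sum_pct` and a
#'   per-type `breakdown` data.frame (rates against `n_test`) with a total
#'   row.
#' @export
corrected_accuracy <- function(n_test, exact_match_count, annotations,
                               matched_ids = NULL) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    annotations <- data.frame(record_id = character(0),
                              plausible = logical(0), type = character(0))
  }
  if (anyDuplicated(annotations$record_id))
    stop("duplicate record ids in annotations")
  if (!is.null(matched_ids) &&
      any(annotations$record_id %in% matched_ids))
    stop("annotation of a record that already matches exactly (double counting)")
  plaus <- annotations[annotations$plausible, , drop = FALSE]
  n_plaus <- nrow(plaus)
  corrected <- exact_match_count + n_plaus
  counts <- table(factor(plaus$type, levels = .PLAUSIBLE_TYPES))
  breakdown <- data.frame(type = c(.PLAUSIBLE_TYPES, "Total"),
                          count = c(as.integer(counts), n_plaus),
                          rate = c(as.integer(counts), n_plaus) / n_test,
                          stringsAsFactors = FALSE)
  list(corrected_count = corrected,
       corrected_fraction = corrected / n_test,
       exact_fraction = exact_match_count / n_test,
       plausible_fraction = n_plaus / n_test,
       rate_sum_pct = round(100 * exact_match_count / n_test, 1) +
         round(100 * n_plaus / n_test, 1),
       breakdown = breakdown)
}

#' Headline "true"-accuracy arithmetic from printed rates
#'
#' The rate-sum form of corrected accuracy when only printed percentages are
#' available: the exact-match percentage plus the per-type plausible
#' percentages.
#'
#' @param exact_rate_pct Exact-match top-1 accuracy, in percent.
#' @param plausible_rates_pct Numeric vector of per-type plausible rates, in
#'   percent.
#' @return Corrected accuracy in percent.
#' @examples
#' true_accuracy_rate_sum(54.1, c(0.2, 1.0, 2.5, 0.7, 2.4, 1.4, 2.3))
#' @export
true_accuracy_rate_sum <- function(exact_rate_pct, plausible_rates_pct) {
  exact_rate_pct + sum(plausible_rates_pct)
}

#' Full evaluation report for a prediction set
#'
#' Bundles top-N accuracy, per-class top-N accuracy, rank-1 invalidity,
#' failure-mode categorization and (when annotations are supplied)
#' corrected accuracy into one object.
#'
#' @param predictions List (per record) of ranked prediction vectors.
#' @param truths Character vector of ground-truth reactant strings.
#' @param class_ids Integer reaction classes per record.
#' @param record_ids Character record ids (defaults to index strings).
#' @param Ns N values for top-N accuracy.
#' @param annotations Optional plausibility annotations
#'   (see [read_annotations()]).
#' @param registry Failure-motif registry.
#' @return An object of class `eval_report`.
#' @export
evaluate_predictions <- function(predictions, truths, class_ids,
                                 record_ids = as.character(seq_along(truths)),
                                 Ns = c(1L, 3L, 5L, 10L), annotations = NULL,
                                 registry = default_failure_registry()) {
  ranks <- .match_ranks(predictions, truths)
  per_n <- vapply(Ns, function(n) mean(ranks <= n), numeric(1))
  names(per_n) <- paste0("top", Ns)
  present <- sort(unique(class_ids))
  per_class <- sapply(Ns, function(n)
    vapply(present, function(k) mean(ranks[class_ids == k] <= n), numeric(1)))
  per_class <- matrix(per_class, nrow = length(present),
                      dimnames = list(paste0("class_", present),
                                      paste0("top", Ns)))
  rank1 <- vapply(predictions, `[`, character(1), 1L)
  inval <- invalidity_rate(rank1, class_ids)
  failed_1 <- ranks > 1
  failures <- categorize_failures(
    data.frame(record_id = record_ids[failed_1],
               truth = truths[failed_1], stringsAsFactors = FALSE),
    registry)
  corrected <- if (!is.null(annotations))
    corrected_accuracy(length(truths), sum(ranks == 1), annotations,
                       matched_ids = record_ids[ranks == 1])
  structure(list(n_test = length(truths), per_n = per_n,
                 per_class = per_class, invalidity = inval,
                 failure_categories = failures, corrected = corrected,
                 match_ranks = ranks, record_ids = record_ids),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("retrosynthesis evaluation on", x$n_test, "records\n")
  for (nm in names(x$per_n))
    cat(sprintf("  %-6s accuracy: %5.1f%%\n", nm, 100 * x$per_n[[nm]]))
  cat(sprintf("  rank-1 invalidity: %.1f%%\n", 100 * x$invalidity$overall))
  if (!is.null(x$corrected))
    cat(sprintf("  corrected (true) top-1: %.1f%%\n",
                x$corrected$rate_sum_pct))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Full precision; the rendered markdown tables round to one decimal, the
#' JSON does not.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    n_test = report$n_test,
    top_n = as.list(report$per_n),
    per_class = apply(report$per_class, 1, as.list),
    invalidity = report$invalidity,
    failure_categories = report$failure_categories,
    corrected = report$corrected[c("corrected_count", "corrected_fraction",
                                   "exact_fraction", "plausible_fraction",
                                   "rate_sum_pct")],
    corrected_breakdown = report$corrected$breakdown)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
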