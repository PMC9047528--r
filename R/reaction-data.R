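# Reaction dataset I/O: TSV files with header columns class, reactants,
# product; molecules inside a field are '.'-separated. Records are plain
# lists so the shape stays inspectable.

#' Construct a single-product reaction record
#'
#' @param record_id Opaque string id.
#' @param class_id Integer reaction class (1-10 in the benchmark layout).
#' @param reactants Character vector of reactant SMILES (one molecule each).
#' @param product Single product SMILES (must not contain `.`).
#' @return A list of class `reaction_record`.
#' @export
reaction_record <- function(record_id, class_id, reactants, product) {
  if (grepl(".", product, fixed = TRUE))
    stop("multi-product record, run split_multiproduct first: ", product)
  if (length(reactants) == 0L || any(!nzchar(reactants)))
    stop("reactants must be a non-empty list of non-empty strings")
  if (!nzchar(product)) stop("product must be non-empty")
  structure(list(record_id = as.character(record_id),
                 class_id = as.integer(class_id),
                 reactants = as.character(reactants),
                 product = as.character(product)),
            class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("[%s] class %d: %s >> %s\n", x$record_id, x$class_id,
              paste(x$reactants, collapse = "."), x$product))
  invisible(x)
}

#' Read a reaction TSV into a list of reaction records
#'
#' Expects a header with columns `class`, `reactants`, `product` (an optional
#' `id` column is honoured; otherwise ids are assigned as `L<line>` from the
#' 1-based data line number, which keeps them stable across reruns). Each
#' record must already be single-product; multi-product lines are rejected
#' with their line number so they can be routed through
#' [split_multiproduct()].
#'
#' @param path Path to a TSV file.
#' @return List of `reaction_record`s.
#' @export
read_reactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("class", "reactants", "product")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    if (!nzchar(df$reactants[i]))
      stop("empty reactants field at line ", line, " of ", path)
    if (!nzchar(df$product[i]))
      stop("empty product field at line ", line, " of ", path)
    if (grepl(".", df$product[i], fixed = TRUE))
      stop("multi-product record at line ", line,
           ", run split_multiproduct first")
    reactants <- strsplit(df$reactants[i], ".", fixed = TRUE)[[1]]
    if (any(!nzchar(reactants)))
      stop("empty reactant molecule at line ", line, " of ", path)
    id <- if ("id" %in% names(df)) df$id[i] else sprintf("L%d", i)
    out[[i]] <- reaction_record(id, as.integer(df$class[i]), reactants,
                                df$product[i])
  }
  out
}

#' Write reaction records as a TSV
#'
#' Canonical column order `id`, `class`, `reactants`, `product`;
#' round-trips byte-identically with [read_reactions()].
#'
#' @param records List of `reaction_record`s.
#' @param path Output path.
#' @export
write_reactions <- function(records, path) {
  df <- data.frame(
    id = vapply(records, `[[`, character(1), "record_id"),
    class = vapply(records, `[[`, integer(1), "class_id"),
    reactants = vapply(records, function(r) paste(r$reactants, collapse = "."),
                       character(1)),
    product = vapply(records, `[[`, character(1), "product"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a multi-product reaction into single-product records
#'
#' Each molecule of the dot-separated product string becomes its own record
#' with the reactant list duplicated verbatim, preserving product order --
#' the preprocessing step that puts a raw corpus into the one-product-per-
#' example shape the translation model consumes.
#'
#' @param class_id Integer reaction class.
#' @param reactants Character vector of reactant SMILES.
#' @param products Dot-separated product SMILES string.
#' @param record_id Base id; products get suffixes `.1`, `.2`, ... when
#'   there is more than one.
#' @return List of `reaction_record`s, one per product molecule.
#' @export
split_multiproduct <- function(class_id, reactants, products,
                               record_id = "R") {
  if (!nzchar(products)) stop("empty products string")
  prods <- strsplit(products, ".", fixed = TRUE)[[1]]
  if (length(prods) == 0L || any(!nzchar(prods)))
    stop("empty product token between dots: ", products)
  if (length(prods) == 1L)
    return(list(reaction_record(record_id, class_id, reactants, prods)))
  lapply(seq_along(prods), function(i)
    reaction_record(sprintf("%s.%d", record_id, i), class_id, reactants,
                    prods[i]))
}

# portable Fisher-Yates shuffle driven by a local RNG stream, so that splits
# do not depend on (or disturb) the caller's RNG state
.fisher_yates <- function(n, seed) {
  idx <- seq_len(n)
  rng <- .lcg_stream(seed)
  for (i in n:2) {
    j <- 1L + (rng() %% i)
    tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
  }
  idx
}

# minimal 63-bit linear congruential generator (Knuth MMIX constants reduced
# to doubles-safe arithmetic): the point is a stated, platform-stable stream
.lcg_stream <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647) + 1
  function() {
    state <<- (state * 48271) %% 2147483647
    as.integer(state %% 2147483563)
  }
}

#' Deterministically split records into train/validation/test
#'
#' Records are shuffled with a fixed, platform-independent Fisher-Yates
#' permutation seeded by `seed`, then cut into three parts. Sizes are
#' floor-based with the remainder assigned to train, so
#' `|train|+|val|+|test|` always equals the input size.
#'
#' @param records List of `reaction_record`s.
#' @param fractions Numeric vector of three non-negative fractions summing
#'   to 1 (train, validation, test). Default emulates the benchmark's
#'   80/10/10 shape.
#' @param seed Integer seed.
#' @return A list of class `dataset_split` with elements `train`,
#'   `validation`, `test`, `seed`, `fractions`.
#' @export
make_splits <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0))
    stop("fractions must be three non-negative numbers")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(records)
  if (n < sum(fractions > 0))
    stop("fewer records than non-zero split parts")
  perm <- .fisher_yates(n, seed)
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  shuffled <- records[perm]
  structure(list(
    train = shuffled[seq_len(n_train)],
    validation = if (n_val) shuffled[n_train + seq_len(n_val)] else list(),
    test = if (n_test) shuffled[n_train + n_val + seq_len(n_test)] else list(),
    seed = as.integer(seed), fractions = fractions),
    class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("reaction dataset split (seed %d): %d train / %d validation / %d test\n",
              x$seed, length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Write a dataset split as three TSVs plus a JSON manifest
#'
#' @param split A `dataset_split`.
#' @param dir Output directory (created if needed).
#' @export
write_splits <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reactions(split$train, file.path(dir, "train.tsv"))
  write_reactions(split$validation, file.path(dir, "validation.tsv"))
  write_reactions(split$test, file.path(dir, "test.tsv"))
  manifest <- list(seed = split$seed, fractions = split$fractions,
                   counts = list(train = length(split$train),
                                 validation = length(split$validation),
                                 test = length(split$test)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset split written by [write_splits()]
#' @param dir Directory containing `train.tsv`, `validation.tsv`,
#'   `test.tsv` and `manifest.json`.
#' @return A `dataset_split`.
#' @export
read_splits <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(list(
    train = read_reactions(file.path(dir, "train.tsv")),
    validation = read_reactions(file.path(dir, "validation.tsv")),
    test = read_reactions(file.path(dir, "test.tsv")),
    seed = as.integer(manifest$seed),
    fractions = as.numeric(unlist(manifest$fractions))),
    class = "dataset_split")
}
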