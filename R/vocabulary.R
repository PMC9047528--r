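# Token vocabularies for the translation model. Ids are 0-based so that the
# padding id is literally 0; R-side matrix indexing adds 1 where needed.

#' Build a token vocabulary from a tokenized corpus
#'
#' Ids are consecutive integers from 0: the four special tokens
#' `<PAD>`(0), `<BOS>`(1), `<EOS>`(2), `<UNK>`(3) first, then the reaction
#' class tokens `<RX_1>`..`<RX_k>` when `class_count > 0`, then the distinct
#' corpus tokens in lexicographic order. The assignment is fully
#' deterministic for a given corpus.
#'
#' @param corpus List of character vectors, each a tokenized sequence
#'   (see [tokenize_smiles()]).
#' @param class_count Number of reaction-class tokens to reserve (0 for
#'   none; the benchmark corpus uses 10).
#' @return An object of class `retro_vocab`.
#' @examples
#' v <- build_vocabulary(list(c("C", "C", "O")), class_count = 10)
#' vocab_size(v)
#' @export
build_vocabulary <- function(corpus, class_count = 0L) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list of token vectors")
  specials <- c("<PAD>", "<BOS>", "<EOS>", "<UNK>")
  cls <- if (class_count > 0L) sprintf("<RX_%d>", seq_len(class_count))
         else character(0)
  body <- sort(unique(unlist(corpus, use.names = FALSE)), method = "radix")
  tokens <- c(specials, cls, body)
  if (anyDuplicated(tokens))
    stop("corpus tokens collide with special or class tokens")
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(list(tokens = tokens, ids = ids, class_count = as.integer(class_count)),
            class = "retro_vocab")
}

#' @export
print.retro_vocab <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$tokens), "tokens (",
      x$class_count, "reaction-class tokens )\n")
  invisible(x)
}

#' Vocabulary size
#' @param vocab A `retro_vocab`.
#' @return Integer number of tokens (specials and class tokens included).
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

# reserved singleton ids
.PAD <- 0L; .BOS <- 1L; .EOS <- 2L; .UNK <- 3L

#' Map tokens to integer ids
#'
#' @param vocab A `retro_vocab`.
#' @param tokens Character vector of tokens.
#' @param allow_unknown If `TRUE`, unknown tokens map to the `<UNK>` id;
#'   otherwise they raise an error listing the offenders.
#' @return Integer vector of 0-based ids.
#' @export
encode_tokens <- function(vocab, tokens, allow_unknown = FALSE) {
  ids <- vocab$ids[tokens]
  if (anyNA(ids)) {
    if (!allow_unknown)
      stop("unknown token(s): ",
           paste(unique(tokens[is.na(ids)]), collapse = " "))
    ids[is.na(ids)] <- .UNK
  }
  unname(ids)
}

#' Map integer ids back to tokens
#' @param vocab A `retro_vocab`.
#' @param ids Integer vector of 0-based ids.
#' @return Character vector of tokens.
#' @export
decode_ids <- function(vocab, ids) {
  if (any(ids < 0L | ids >= length(vocab$tokens)))
    stop("id out of vocabulary range")
  vocab$tokens[ids + 1L]
}

#' Write a vocabulary as a two-column TSV (token, id)
#' @param vocab A `retro_vocab`.
#' @param path Output file path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(
    data.frame(token = vocab$tokens, id = vocab$ids),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#' @param path TSV file path.
#' @return A `retro_vocab`.
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  df <- df[order(df$id), ]
  if (!identical(df$id, seq_len(nrow(df)) - 1L) &&
      !identical(as.integer(df$id), seq_len(nrow(df)) - 1L))
    stop("vocabulary ids must be consecutive from 0")
  ids <- seq_len(nrow(df)) - 1L
  names(ids) <- df$token
  structure(list(tokens = df$token, ids = ids,
                 class_count = sum(grepl("^<RX_[0-9]+>$", df$token))),
            class = "retro_vocab")
}
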