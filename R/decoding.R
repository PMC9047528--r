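# Beam-search decoding: product SMILES in, ranked reactant SMILES out.

#' Beam search over the decoder
#'
#' Length-wise beam expansion over [decode_step()] outputs: at every step
#' each live hypothesis is extended by every vocabulary token, the
#' `beam_width` best extensions overall are kept, and hypotheses that just
#' produced `<EOS>` are set aside as finished. Scores are pure sums of token
#' log-probabilities (no length normalization unless requested). Ties are
#' broken lexicographically on the token-id sequence, so the result is
#' deterministic for fixed parameters.
#'
#' @param params A `param_set`.
#' @param config The matching [model_config()].
#' @param src_ids Integer source token ids (0-based).
#' @param beam_width Beam size; at least `n_best`.
#' @param max_len Maximum decoded length (tokens after `<BOS>`); hypotheses
#'   still live at `max_len` are returned flagged unfinished.
#' @param n_best Number of candidates to return.
#' @param vocab Optional `retro_vocab` used to fill each candidate's decoded
#'   SMILES string.
#' @param length_norm Divide scores by hypothesis length when ranking
#'   (off by default).
#' @return List of `beam_candidate`s, sorted by descending score, each with
#'   fields `ids` (`<BOS>`...`<EOS>`), `score`, `rank`, `finished`, `smiles`.
#' @export
beam_search <- function(params, config, src_ids, beam_width = 10L,
                        max_len = 64L, n_best = beam_width, vocab = NULL,
                        length_norm = FALSE) {
  if (n_best < 1L || beam_width < n_best)
    stop("need beam_width >= n_best >= 1")
  memory <- encode(src_ids, params, config)
  keep <- src_ids != .PAD

  live <- list(list(ids = .BOS, score = 0))
  finished <- list()
  vsize <- nrow(params$embed)

  key <- function(ids) paste(sprintf("%06d", ids), collapse = ",")
  rank_order <- function(cands) {
    sc <- vapply(cands, function(cn)
      if (length_norm) cn$score / (length(cn$ids) - 1L) else cn$score,
      numeric(1))
    ks <- vapply(cands, function(cn) key(cn$ids), character(1))
    order(-sc, ks, method = "radix")
  }

  for (t in seq_len(max_len)) {
    if (length(live) == 0L) break
    cand_ids <- list(); cand_scores <- numeric(0)
    for (bm in live) {
      lp <- decode_step(memory, bm$ids, params, config, memory_keep = keep)
      cand_ids <- c(cand_ids, lapply(seq_len(vsize) - 1L,
                                     function(tok) c(bm$ids, tok)))
      cand_scores <- c(cand_scores, bm$score + lp)
    }
    cands <- lapply(seq_along(cand_ids), function(i)
      list(ids = cand_ids[[i]], score = cand_scores[i]))
    ord <- rank_order(cands)
    top <- cands[ord[seq_len(min(beam_width, length(cands)))]]
    live <- list()
    for (cn in top) {
      if (cn$ids[length(cn$ids)] == .EOS) {
        cn$finished <- TRUE
        finished[[length(finished) + 1L]] <- cn
      } else {
        cn$finished <- FALSE
        live[[length(live) + 1L]] <- cn
      }
    }
    # sound early stop: scores are sums of log-probabilities, so a live
    # hypothesis can never exceed its current score (raw ranking) or
    # score / max_len (length-normalized ranking, score <= 0). Stop once no
    # live hypothesis can still displace the kept finished ones.
    if (length(finished) >= min(beam_width, n_best)) {
      rv <- vapply(finished, function(cn)
        if (length_norm) cn$score / (length(cn$ids) - 1L) else cn$score,
        numeric(1))
      worst_kept <- sort(rv, decreasing = TRUE)[min(n_best, length(rv))]
      bound <- vapply(live, function(cn)
        if (length_norm) cn$score / max_len else cn$score, numeric(1))
      if (length(live) == 0L || max(bound) < worst_kept) break
    }
  }

  pool <- c(finished, live)  # truncated hypotheses only fill trailing ranks
  pool <- lapply(pool, function(cn) {
    if (is.null(cn$finished)) cn$finished <- FALSE
    cn
  })
  fin <- vapply(pool, `[[`, logical(1), "finished")
  pool <- c(pool[fin][rank_order(pool[fin])], pool[!fin][rank_order(pool[!fin])])
  pool <- pool[seq_len(min(n_best, length(pool)))]
  for (i in seq_along(pool)) {
    pool[[i]]$rank <- i
    pool[[i]]$smiles <- if (!is.null(vocab)) {
      body <- pool[[i]]$ids[pool[[i]]$ids != .BOS & pool[[i]]$ids != .EOS]
      detokenize_smiles(decode_ids(vocab, body))
    } else NA_character_
    class(pool[[i]]) <- "beam_candidate"
  }
  pool
}

#' @export
print.beam_candidate <- function(x, ...) {
  cat(sprintf("#%d  score %.4f  %s%s\n", x$rank, x$score,
              if (is.na(x$smiles)) paste(x$ids, collapse = " ") else x$smiles,
              if (x$finished) "" else "  [unfinished]"))
  invisible(x)
}

#' Predict ranked reactant sets for a product molecule
#'
#' Tokenizes the product (optionally prefixed with its reaction-class
#' token), beam-decodes candidate reactant strings, collapses candidates
#' that canonicalize to the same molecule multiset (keeping the best rank,
#' with later ranks promoted), and returns the top `n` in rank order.
#' Grammatically invalid candidates are retained -- they feed the
#' invalidity statistics -- but can never match a ground truth.
#'
#' @param params A `param_set` (e.g. from [average_checkpoints()]).
#' @param config The matching [model_config()].
#' @param vocab The `retro_vocab` the model was trained with.
#' @param product Product SMILES string.
#' @param class_id Optional reaction class id (1-10); prepends `<RX_k>`.
#' @param n Number of ranked predictions wanted.
#' @param beam_width Beam size (defaults to `max(n, 10)`).
#' @param max_len Maximum decoded length.
#' @param length_norm Rank hypotheses by per-token log-probability instead
#'   of the raw sum; counters the beam's bias toward short sequences.
#' @return Character vector of at most `n` dot-separated reactant SMILES in
#'   rank order, with a `scores` attribute of matching length.
#' @export
predict_reactants <- function(params, config, vocab, product, class_id = NULL,
                              n = 10L, beam_width = max(n, 10L),
                              max_len = 64L, length_norm = TRUE) {
  toks <- tokenize_smiles(product)
  unknown <- setdiff(toks, vocab$tokens)
  if (length(unknown))
    stop("unknown token(s) in product: ", paste(unknown, collapse = " "))
  if (!is.null(class_id)) toks <- c(sprintf("<RX_%d>", class_id), toks)
  src <- encode_tokens(vocab, toks)
  cands <- beam_search(params, config, src, beam_width = beam_width,
                       max_len = max_len, n_best = beam_width, vocab = vocab,
                       length_norm = length_norm)
  smiles <- vapply(cands, `[[`, character(1), "smiles")
  scores <- vapply(cands, `[[`, numeric(1), "score")
  ok <- is_valid_smiles(smiles)
  sig <- smiles  # dedup signature: canonical multiset for valid strings
  if (any(ok)) {
    ms <- .canonical_multisets(smiles[ok])
    sig[ok] <- vapply(seq_along(ms), function(i)
      if (is.null(ms[[i]])) paste0("\r", smiles[ok][i])
      else paste(ms[[i]], collapse = "."), character(1))
  }
  first <- !duplicated(sig)
  smiles <- smiles[first]; scores <- scores[first]
  keep <- seq_len(min(n, length(smiles)))
  structure(smiles[keep], scores = scores[keep])
}
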