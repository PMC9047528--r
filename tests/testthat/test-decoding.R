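# toy setup: tiny random model over a 5-token vocabulary
# (4 specials + one SMILES token)
toy_model <- function(seed = 1, vsize = 5L, N = 1L) {
  cfg <- tiny_config(N = N)
  list(cfg = cfg, params = init_params(cfg, vsize, seed = seed))
}

greedy_decode <- function(params, cfg, src, max_len) {
  memory <- encode(src, params, cfg)
  ids <- 1L
  for (t in seq_len(max_len)) {
    lp <- decode_step(memory, ids, params, cfg)
    nxt <- which.max(lp) - 1L
    ids <- c(ids, nxt)
    if (nxt == 2L) break
  }
  ids
}

test_that("beam width 1 equals greedy argmax decoding", {
  for (seed in 1:5) {
    m <- toy_model(seed)
    src <- c(4L, 4L, 4L)
    got <- beam_search(m$params, m$cfg, src, beam_width = 1L, max_len = 6L,
                       n_best = 1L)
    expect_equal(got[[1]]$ids, greedy_decode(m$params, m$cfg, src, 6L))
  }
})

test_that("beam search with full width equals exhaustive enumeration", {
  # all instances with vocabulary <= 5 ids and max_len <= 4: the beam kept
  # wide enough to hold every hypothesis must return the exhaustive top-n
  for (seed in 1:4) {
    for (max_len in 2:4) {
      m <- toy_model(seed)
      src <- c(4L, 4L)
      all_seq <- ref_enumerate_sequences(m$params, m$cfg, src, max_len)
      fin <- Filter(function(x) x$finished, all_seq)
      fin <- fin[order(-vapply(fin, `[[`, numeric(1), "score"),
                       vapply(fin, function(x)
                         paste(sprintf("%06d", x$ids), collapse = ","),
                         character(1)))]
      width <- 5^max_len   # exceeds the number of live hypotheses
      got <- beam_search(m$params, m$cfg, src, beam_width = width,
                         max_len = max_len, n_best = length(fin))
      got_fin <- Filter(function(x) x$finished, got)
      expect_equal(lapply(got_fin, `[[`, "ids"), lapply(fin, `[[`, "ids"))
      expect_equal(vapply(got_fin, `[[`, numeric(1), "score"),
                   vapply(fin, `[[`, numeric(1), "score"), tolerance = 1e-10)
    }
  }
})

test_that("candidates come ranked with non-increasing, non-positive scores", {
  m <- toy_model(3)
  got <- beam_search(m$params, m$cfg, c(4L, 4L, 4L), beam_width = 4L,
                     max_len = 8L, n_best = 4L)
  scores <- vapply(got, `[[`, numeric(1), "score")
  expect_true(all(diff(scores[vapply(got, `[[`, logical(1), "finished")])
                  <= 1e-12))
  expect_true(all(scores <= 0))
  expect_equal(vapply(got, `[[`, integer(1), "rank"), seq_along(got))
  fin <- vapply(got, `[[`, logical(1), "finished")
  for (cand in got[fin]) {
    expect_equal(cand$ids[length(cand$ids)], 2L)   # single terminal EOS
    expect_equal(sum(cand$ids == 2L), 1L)
  }
})

test_that("widening the beam never lowers the best finished score", {
  for (seed in c(2, 5, 8)) {
    m <- toy_model(seed)
    best <- function(w) {
      got <- beam_search(m$params, m$cfg, c(4L, 4L), beam_width = w,
                         max_len = 6L, n_best = 1L)
      if (got[[1]]$finished) got[[1]]$score else -Inf
    }
    expect_lte(best(1L), best(3L) + 1e-12)
    expect_lte(best(3L), best(8L) + 1e-12)
  }
})

test_that("beam search validates its arguments", {
  m <- toy_model(1)
  expect_error(beam_search(m$params, m$cfg, c(4L), beam_width = 1L,
                           n_best = 2L), "beam_width >= n_best")
})

test_that("predict_reactants enforces vocabulary and deduplicates candidates", {
  recs <- toy_records(16)
  split <- structure(list(train = recs[1:12], validation = recs[13:16],
                          test = list(), seed = 1L, fractions = c(.75, .25, 0)),
                     class = "dataset_split")
  cfg <- model_config(N = 1, d_model = 16, h = 2, d_ff = 32, max_len = 64,
                      dropout = 0)
  run <- train_model(split, cfg, train_config(batch_tokens = 500,
                                              max_steps = 5, seed = 1))
  params <- run$checkpoints[[length(run$checkpoints)]]$params
  expect_error(predict_reactants(params, cfg, run$vocab, "CC[Se]C"),
               "unknown token")
  out <- predict_reactants(params, cfg, run$vocab, recs[[1]]$product,
                           class_id = 1L, n = 5L, beam_width = 6L,
                           max_len = 30L)
  expect_lte(length(out), 5L)
  expect_length(attr(out, "scores"), length(out))
  valid <- is_valid_smiles(out)
  if (sum(valid) > 1) {
    canon <- vapply(strsplit(out[valid], ".", fixed = TRUE), function(x)
      paste(sort(tryCatch(canonicalize(x), error = function(e) x)),
            collapse = "."), character(1))
    expect_false(anyDuplicated(canon) > 0)   # dedup by canonical multiset
  }
  one <- predict_reactants(params, cfg, run$vocab, recs[[1]]$product,
                           n = 1L, max_len = 30L)
  expect_length(one, 1L)
})
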