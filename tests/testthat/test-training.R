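# independent simulation of the greedy padded-cost packing rule, kept
# deliberately naive
sim_pack <- function(lengths, budget) {
  batches <- list(); cur <- integer(0)
  for (i in seq_along(lengths)) {
    trial <- c(cur, i)
    if (length(cur) && max(lengths[trial]) * length(trial) > budget) {
      batches[[length(batches) + 1]] <- cur
      cur <- i
    } else cur <- trial
  }
  c(batches, list(cur))
}

test_that("token-budget packing follows the greedy padded-cost rule", {
  expect_equal(pack_batches_by_tokens(c(5, 7, 8), 16), list(c(1L, 2L), 3L))
  expect_equal(pack_batches_by_tokens(c(4, 4, 4, 4), 16), list(1:4))
  expect_equal(pack_batches_by_tokens(c(6, 3, 6), 6),
               list(1L, 2L, 3L))               # budget = max length
  expect_error(pack_batches_by_tokens(c(5, 20), 16), "exceeds the token budget")
})

test_that("packing matches the hand-simulated rule on 50 randomized length lists", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(1:60, 1)
    lens <- sample(1:30, n, replace = TRUE)
    budget <- max(lens) + sample(0:60, 1)
    got <- pack_batches_by_tokens(lens, budget)
    expect_equal(lapply(got, as.integer), lapply(sim_pack(lens, budget),
                                                 as.integer))
    # no batch exceeds the budget under padded cost
    for (b in got) expect_lte(max(lens[b]) * length(b), budget)
    # union of batches is a permutation of the indices
    expect_equal(sort(unlist(got)), seq_along(lens))
  }
})

test_that("a larger token budget never yields more batches", {
  set.seed(9)
  for (i in 1:10) {
    lens <- sample(2:20, 40, replace = TRUE)
    b1 <- length(pack_batches_by_tokens(lens, 40))
    b2 <- length(pack_batches_by_tokens(lens, 80))
    expect_lte(b2, b1)
  }
})

test_that("checkpoint averaging equals the brute-force element-wise mean", {
  cfg <- tiny_config()
  mk <- function(seed, step) structure(
    list(step = step, params = init_params(cfg, 8L, seed = seed),
         opt_state = NULL, val_loss = NA_real_), class = "checkpoint")
  cks <- lapply(1:5, function(i) mk(i, i * 10L))
  avg <- average_checkpoints(cks, 4)
  for (nm in names(avg)) {
    brute <- matrix(0, nrow(avg[[nm]]), ncol(avg[[nm]]))
    for (i in 2:5) brute <- brute + cks[[i]]$params[[nm]]
    expect_equal(avg[[nm]], brute / 4, tolerance = 1e-12)
  }
  # averaging identical checkpoints is the identity
  same <- lapply(1:3, function(i) mk(7, i * 10L))
  avg_same <- average_checkpoints(same, 3)
  for (nm in names(avg_same))
    expect_equal(avg_same[[nm]], same[[1]]$params[[nm]], tolerance = 1e-15)
  # two checkpoints with a weight at 0 and 2 average to 1
  a <- mk(1, 1L); b <- mk(1, 2L)
  a$params$embed[1, 1] <- 0; b$params$embed[1, 1] <- 2
  expect_equal(average_checkpoints(list(a, b), 2)$embed[1, 1], 1)
  # permutation invariance over the averaged window
  perm <- average_checkpoints(cks[c(3, 5, 2, 4)][c(2, 4, 1, 3)], 4)
  for (nm in names(avg)) expect_equal(perm[[nm]], avg[[nm]], tolerance = 1e-12)
  expect_error(average_checkpoints(cks, 6), "at least k")
})

test_that("training reduces the loss and is seed-reproducible", {
  recs <- toy_records(24)
  split <- structure(list(train = recs[1:20], validation = recs[21:24],
                          test = list(), seed = 1L,
                          fractions = c(0.8, 0.2, 0)),
                     class = "dataset_split")
  cfg <- model_config(N = 1, d_model = 32, h = 2, d_ff = 64, max_len = 64,
                      dropout = 0.1)
  tc <- train_config(batch_tokens = 600, max_steps = 40,
                     checkpoint_interval = 20, seed = 4, warmup = 40,
                     lr_factor = 1)
  run <- train_model(split, cfg, tc)
  expect_s3_class(run, "train_run")
  expect_lt(mean(tail(run$log$train_loss, 5)),
            run$log$train_loss[1])            # loss strictly improved
  expect_equal(run$checkpoints[[length(run$checkpoints)]]$step, 40L)
  run2 <- train_model(split, cfg, tc)
  expect_equal(run$log$train_loss[10], run2$log$train_loss[10],
               tolerance = 1e-12)             # determinism contract
  # checkpoint steps strictly increase
  steps <- vapply(run$checkpoints, `[[`, integer(1), "step")
  expect_true(all(diff(steps) > 0))
})

test_that("max_steps 0 emits a single initialization checkpoint", {
  recs <- toy_records(8)
  split <- structure(list(train = recs, validation = list(), test = list(),
                          seed = 1L, fractions = c(1, 0, 0)),
                     class = "dataset_split")
  cfg <- tiny_config()
  run <- train_model(split, cfg,
                     train_config(batch_tokens = 400, max_steps = 0,
                                  seed = 2))
  expect_length(run$checkpoints, 1L)
  expect_equal(run$checkpoints[[1]]$step, 0L)
  expect_identical(run$checkpoints[[1]]$params,
                   init_params(cfg, vocab_size(run$vocab), seed = 2L))
})
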