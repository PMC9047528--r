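test_that("config construction enforces h * d_k = d_model", {
  cfg <- model_config(N = 2, d_model = 128, h = 4)
  expect_equal(cfg$d_k * cfg$h, cfg$d_model)
  expect_error(model_config(d_model = 10, h = 4), "divide")
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("parameter sets have config-determined names and shapes", {
  cfg <- tiny_config(N = 2)
  p1 <- init_params(cfg, 11, seed = 1)
  p2 <- init_params(cfg, 11, seed = 2)
  expect_identical(names(p1), names(p2))
  for (nm in names(p1)) expect_identical(dim(p1[[nm]]), dim(p2[[nm]]))
  expect_identical(dim(p1$embed), c(11L, cfg$d_model))
  expect_true(all(c("enc2.self.Wq", "dec2.cross.Wo", "dec1.ln3.g") %in%
                    names(p1)))
  # seeded: same seed reproduces, different seed differs
  expect_identical(init_params(cfg, 11, seed = 1), p1)
  expect_false(identical(p1$embed, p2$embed))
})

test_that("positional encoding follows the sinusoidal closed form", {
  pe <- positional_encoding(10, 16)
  expect_equal(pe[1, seq(1, 16, 2)], rep(0, 8))   # sin(0)
  expect_equal(pe[1, seq(2, 16, 2)], rep(1, 8))   # cos(0)
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_equal(pe[2, 1], 0.84147, tolerance = 1e-5)
  expect_equal(pe[5, 3], sin(4 / 10000^(2 / 16)), tolerance = 1e-12)
  expect_true(max(abs(positional_encoding(50, 30))) <= 1)
  expect_error(positional_encoding(0, 8), "positive")
})

test_that("scaled dot-product attention matches closed forms", {
  # single key: weight 1, output = v
  att <- scaled_dot_product_attention(matrix(rnorm(4), 1), matrix(1, 1, 4),
                                      matrix(c(3, -1), 1))
  expect_equal(att$weights, matrix(1, 1, 1))
  expect_equal(att$output, matrix(c(3, -1), 1))
  # two equal keys: mean of values
  K <- matrix(1, 2, 2); V <- matrix(c(0, 2, 4, 8), 2)
  att2 <- scaled_dot_product_attention(matrix(1, 1, 2), K, V)
  expect_equal(att2$weights, matrix(0.5, 1, 2))
  expect_equal(att2$output, matrix(c(1, 6), 1))
  # scaled logits (1, 0) -> softmax e/(e+1)
  Q <- matrix(c(1, 0), 1); K3 <- rbind(c(sqrt(2), 0), c(0, 0))
  att3 <- scaled_dot_product_attention(Q, K3, matrix(c(1, 0), 2))
  expect_equal(att3$weights[1, ], c(exp(1), 1) / (exp(1) + 1),
               tolerance = 1e-6)
  expect_equal(att3$weights[1, 1], 0.7311, tolerance = 1e-4)
  # fully-masked query row violates the invariant
  expect_error(scaled_dot_product_attention(Q, K3, matrix(0, 2, 1),
                                            mask = rbind(c(FALSE, FALSE))),
               "fully masked")
})

test_that("attention weight rows are probability vectors on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    nq <- sample(1:6, 1); nk <- sample(1:6, 1); dk <- sample(c(2, 4, 8), 1)
    mask <- matrix(TRUE, nq, nk)
    mask[sample(length(mask), floor(length(mask) / 3))] <- FALSE
    mask[rowSums(mask) == 0, 1] <- TRUE
    att <- scaled_dot_product_attention(matrix(rnorm(nq * dk), nq),
                                        matrix(rnorm(nk * dk), nk),
                                        matrix(rnorm(nk * dk), nk), mask)
    expect_equal(rowSums(att$weights), rep(1, nq), tolerance = 1e-6)
    expect_true(all(att$weights >= 0))
    expect_true(all(att$weights[!mask] == 0))
  }
})

test_that("multi-head attention reduces to single attention and matches the straight-line oracle", {
  d <- 6
  x <- matrix(rnorm(3 * d), 3)
  idp <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d))
  expect_equal(multi_head_attention(x, x, idp, h = 1),
               scaled_dot_product_attention(x, x, x)$output,
               tolerance = 1e-12)
  # 2-head composition equals the independent loop implementation
  set.seed(7)
  proj <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
               Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d))
  expect_equal(multi_head_attention(x, x, proj, h = 2),
               ref_mha(x, x, proj$Wq, proj$Wk, proj$Wv, proj$Wo, h = 2),
               tolerance = 1e-10)
  # permuting keys/values (with the mask) leaves the output unchanged
  xkv <- matrix(rnorm(5 * d), 5)
  perm <- sample(5)
  expect_equal(multi_head_attention(x, xkv, proj, h = 2),
               multi_head_attention(x, xkv[perm, ], proj, h = 2),
               tolerance = 1e-10)
})

test_that("encoder stack: degenerate depth, padding invariance, determinism", {
  vsize <- 9L
  cfg0 <- model_config(N = 0, d_model = 8, h = 2, d_ff = 16, max_len = 32,
                       dropout = 0)
  p0 <- init_params(cfg0, vsize, seed = 3)
  ids <- c(4L, 5L, 6L)
  mem0 <- encode(ids, p0, cfg0)
  expect_equal(mem0,
               p0$embed[ids + 1, ] * sqrt(8) + positional_encoding(3, 8),
               tolerance = 1e-12)
  cfg <- tiny_config(N = 2)
  p <- init_params(cfg, vsize, seed = 3)
  mem <- encode(ids, p, cfg)
  mem_pad <- encode(c(ids, 0L, 0L), p, cfg)   # appended <PAD>
  expect_equal(mem_pad[1:3, ], mem, tolerance = 1e-10)
  expect_identical(encode(ids, p, cfg), mem)
  expect_error(encode(integer(0), p, cfg), "empty")
})

test_that("decoder step returns a normalized log-distribution and is causal", {
  cfg <- tiny_config(N = 2)
  p <- init_params(cfg, 9L, seed = 11)
  mem <- encode(c(4L, 5L, 6L, 7L, 8L), p, cfg)
  lp <- decode_step(mem, c(1L, 4L, 5L), p, cfg)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-6)
  expect_error(decode_step(mem, integer(0), p, cfg), "empty")
  expect_error(decode_step(mem, c(4L), p, cfg), "BOS")
  # causality: tokens appended after position t never change the step-t output
  set.seed(99)
  for (len in 1:8) {
    prefix <- c(1L, sample(3:8, len - 1, replace = TRUE))
    base <- decode_step(mem, prefix, p, cfg)
    for (rep in 1:2) {
      fut <- sample(3:8, sample(1:3, 1), replace = TRUE)
      ext <- c(prefix, fut)
      # recompute the distribution at the original position
      states <- decode_step(mem, ext[seq_along(prefix)], p, cfg)
      expect_equal(states, base, tolerance = 1e-12)
    }
  }
})

test_that("full forward pass agrees with the straight-line reference to 1e-5", {
  cfg <- tiny_config(N = 2, d_model = 12, h = 3, d_ff = 20)
  p <- init_params(cfg, 10L, seed = 21)
  src <- c(4L, 7L, 5L, 9L, 6L)      # 5-token input
  mem <- encode(src, p, cfg)
  expect_equal(mem, ref_encode(src, p, cfg), tolerance = 1e-5)
  prefix <- c(1L, 5L, 8L)
  expect_equal(decode_step(mem, prefix, p, cfg),
               ref_decode_logprobs(mem, prefix, p, cfg), tolerance = 1e-5)
})

test_that("the batched training engine reproduces the inference path exactly", {
  cfg <- tiny_config(N = 2)
  p <- init_params(cfg, 9L, seed = 5)
  seqs <- list(list(src = c(4L, 5L, 6L), tgt_in = c(1L, 7L, 8L),
                    tgt_lab = c(7L, 8L, 2L)),
               list(src = c(5L, 8L), tgt_in = c(1L, 6L),
                    tgt_lab = c(6L, 2L)))
  batch <- list(src = c(seqs[[1]]$src, seqs[[2]]$src), off_src = c(0L, 3L, 5L),
                tgt_in = c(seqs[[1]]$tgt_in, seqs[[2]]$tgt_in),
                tgt_lab = c(seqs[[1]]$tgt_lab, seqs[[2]]$tgt_lab),
                off_tgt = c(0L, 3L, 5L))
  loss <- retroformer:::.fwd_bwd(p, cfg, batch, dropout = 0,
                                 grads = FALSE)$loss
  manual <- 0
  for (s in seqs) {
    mem <- encode(s$src, p, cfg)
    for (t in seq_along(s$tgt_lab)) {
      lp <- decode_step(mem, s$tgt_in[seq_len(t)], p, cfg)
      manual <- manual - lp[s$tgt_lab[t] + 1]
    }
  }
  expect_equal(loss, manual / 5, tolerance = 1e-12)
})
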