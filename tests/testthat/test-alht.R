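# Hierarchical transformer operator surface: projection, positional codes,
# encoder, noise suppression, attention fusion, classification head, losses.

test_that("feature projection is the stated affine map", {
  X <- matrix(rnorm(12), 4, 3)
  expect_identical(feature_project(X, diag(3)), X)
  b <- c(1, 2, 3)
  Z <- feature_project(X, matrix(0, 3, 3), b)
  expect_true(all(t(Z) == b))
  set.seed(6)
  W <- matrix(rnorm(15), 3, 5); bb <- rnorm(5)
  expect_equal(feature_project(X, W, bb),
               X %*% W + matrix(bb, 4, 5, byrow = TRUE), tolerance = 1e-6)
  expect_error(feature_project(X, matrix(0, 4, 2)), "dimension")
})

test_that("projection is invariant to a joint column/row permutation", {
  set.seed(13)
  X <- matrix(rnorm(20), 4, 5); W <- matrix(rnorm(15), 5, 3)
  perm <- sample(5)
  expect_equal(feature_project(X, W), feature_project(X[, perm], W[perm, ]))
})

test_that("sinusoidal positional codes match their closed form", {
  P <- positional_encoding(4, 6)
  expect_true(all(P[1, c(1, 3, 5)] == 0))       # sin components at t = 0
  expect_true(all(P[1, c(2, 4, 6)] == 1))       # cosine counterparts
  expect_equal(P[2, 1], sin(1), tolerance = 1e-12)  # t = 1, k = 0
  expect_equal(P[2, 2], cos(1), tolerance = 1e-12)
  expect_equal(P[3, 3], sin(2 / 10000^(2 / 6)), tolerance = 1e-12)
  Ps <- positional_encoding(4, 6, "sine_only")
  expect_true(all(Ps[, 4:6] == 0))
  expect_equal(Ps[2, 1], sin(1))
  # content independence: the added code is the same for any input
  A <- matrix(rnorm(24), 4, 6); B <- matrix(rnorm(24), 4, 6)
  expect_equal(positional_encode(A) - A, positional_encode(B) - B)
})

test_that("encoder stack preserves shape and zero layers is the identity", {
  set.seed(3)
  X <- matrix(rnorm(5 * 8), 5, 8)
  expect_identical(encoder_stack(X, list()), X)
  cfg <- model_config(tiny_preset = TRUE)
  params <- init_alht_params(cfg, 8, 4, seed = 1)
  layers <- lapply(1:2, function(l) {
    nm <- function(s) params[[paste0("enc", l, "_", s)]]
    list(Wq = nm("Wq"), Wk = nm("Wk"), Wv = nm("Wv"), Wo = nm("Wo"),
         ln1_g = nm("ln1_g"), ln1_b = nm("ln1_b"), ffn_W1 = nm("ffn_W1"),
         ffn_b1 = nm("ffn_b1"), ffn_W2 = nm("ffn_W2"), ffn_b2 = nm("ffn_b2"),
         ln2_g = nm("ln2_g"), ln2_b = nm("ln2_b"))
  })
  X32 <- matrix(rnorm(5 * 32), 5, 32)
  out1 <- encoder_stack(X32, layers, n_heads = 2)
  expect_equal(dim(out1), dim(X32))
  expect_identical(out1, encoder_stack(X32, layers, n_heads = 2))  # deterministic
})

test_that("noise-suppression convolution matches a sliding-window oracle", {
  set.seed(9)
  X <- matrix(rnorm(10 * 3), 10, 3)
  expect_equal(conv_noise_suppress(X, c(0, 1, 0)), X)
  C <- matrix(2, 6, 2)
  avg <- conv_noise_suppress(C, c(1, 1, 1) / 3)
  expect_true(all(abs(avg[2:5, ] - 2) < 1e-12))  # interior (zero-pad edges)
  k <- c(0.2, -0.5, 0.1, 0.7, -0.3)
  expect_equal(conv_noise_suppress(X, k), conv_oracle(X, k), tolerance = 1e-12)
  expect_error(conv_noise_suppress(X, c(1, 1)), "odd")
})

test_that("frame weighting is row-stochastic scaled dot-product attention", {
  one <- frame_weighting(matrix(2, 1, 1))
  expect_equal(as.numeric(one$attention$weights), 1)
  expect_equal(as.numeric(one$weighted), 2)
  same <- frame_weighting(matrix(1, 4, 2))
  expect_equal(same$attention$weights, matrix(0.25, 4, 4), tolerance = 1e-12)
  # hand-computed 2-frame case
  fw <- scaled_dot_attention(matrix(c(1, 0), 2, 1), matrix(c(1, 0), 2, 1),
                             matrix(c(2, 4), 2, 1), d_key = 1)
  expect_equal(fw$attended[1, 1], 0.7310586 * 2 + 0.2689414 * 4, tolerance = 1e-6)
})

test_that("temporal focus attention matches the direct formula oracle", {
  v <- matrix(5, 1, 1)
  tf <- temporal_focus(matrix(1, 1, 1), v)
  expect_equal(tf$C_focus, v)
  same <- temporal_focus(matrix(rnorm(3), 3, 1), matrix(2, 6, 1))
  expect_true(all(abs(same$C_focus - 2) < 1e-12))  # identical frames
  set.seed(14)
  tok <- matrix(rnorm(4), 2, 2); ac <- matrix(rnorm(4), 2, 2)
  Wq <- matrix(rnorm(4), 2); Wk <- matrix(rnorm(4), 2); Wv <- matrix(rnorm(4), 2)
  got <- temporal_focus(tok, ac, Wq, Wk, Wv)
  ref <- attention_oracle(tok %*% Wq, ac %*% Wk, ac %*% Wv, 2)
  expect_equal(got$attention$weights, ref$weights, tolerance = 1e-6)
  expect_equal(got$C_focus, ref$attended, tolerance = 1e-6)
})

test_that("contextual aggregation normalizes rows and supports a zero FFN", {
  set.seed(15)
  Cf <- matrix(rnorm(12), 3, 4)
  S <- rnorm(4); E <- rnorm(4)
  agg0 <- contextual_aggregate(Cf, S, E, alpha = 0, beta = 0)
  expect_equal(agg0$C_agg, layer_norm_rows(Cf), tolerance = 1e-12)
  agg <- contextual_aggregate(Cf, S, E, alpha = 0.5, beta = 0.2)
  expect_lt(max(abs(rowMeans(agg$C_agg))), 1e-5)          # pre-affine defaults
  expect_identical(agg$C_final, agg$C_agg)                # NULL FFN
  ffn0 <- list(W1 = matrix(0, 4, 8), b1 = rep(0, 8),
               W2 = matrix(0, 8, 4), b2 = rep(0, 4))
  expect_equal(contextual_aggregate(Cf, S, E, 0.5, 0.2, ffn = ffn0)$C_final,
               agg$C_agg)
})

test_that("cross-modal refinement produces row-stochastic recalibrated weights", {
  K <- matrix(rnorm(8), 4, 2)
  refined <- cross_modal_refine(matrix(0, 3, 2), K)
  expect_equal(refined$weights, matrix(0.25, 3, 4), tolerance = 1e-12)
  set.seed(16)
  Y <- matrix(rnorm(6), 3, 2); Wq <- matrix(rnorm(4), 2)
  got <- cross_modal_refine(Y, K, Wq)
  expect_equal(rowSums(got$weights), rep(1, 3), tolerance = 1e-6)
  ref <- attention_oracle(Y %*% Wq, K, K, 2)
  expect_equal(got$weights, ref$weights, tolerance = 1e-8)
})

test_that("the classification head mean-pools, projects, and softmaxes", {
  out0 <- classify(matrix(rnorm(8), 2, 4), matrix(0, 4, 2))
  expect_equal(out0$confidence, 0.5)
  set.seed(17)
  for (i in 1:20) {
    C <- matrix(rnorm(12), 3, 4); W <- matrix(rnorm(8), 4, 2); b <- rnorm(2)
    got <- classify(C, W, b)
    logit <- colMeans(C) %*% W + b
    p <- exp(logit - max(logit)); p <- p / sum(p)
    expect_equal(got$probs, as.numeric(p), tolerance = 1e-9)
    expect_equal(got$label, which.max(p) - 1L)
    expect_gte(got$confidence, 0.5)
    expect_lte(got$confidence, 1)
  }
})

test_that("linguistic loss is the clamped negative log-likelihood", {
  perfect <- diag(3)[, 1:3]
  expect_equal(linguistic_loss(perfect, c(1L, 2L, 3L)), 0, tolerance = 1e-9)
  unif <- matrix(0.5, 4, 2)
  expect_equal(linguistic_loss(unif, rep(1L, 4)), 4 * log(2), tolerance = 1e-9)
  set.seed(18)
  P <- softmax_rows(matrix(rnorm(12), 4, 3)); y <- sample(3, 4, replace = TRUE)
  expect_equal(linguistic_loss(P, y), -sum(log(P[cbind(1:4, y)])),
               tolerance = 1e-12)
  # batch mean reduction
  expect_equal(linguistic_loss(list(P, P), list(y, y)), linguistic_loss(P, y))
  hard <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_warning(linguistic_loss(hard, c(2L, 1L)), "clamped")
})

test_that("consistency loss is the pooled squared distance", {
  A <- matrix(rnorm(10), 5, 2)
  expect_equal(consistency_loss(A, A), 0)
  expect_equal(consistency_loss(matrix(c(1, 2), 1), matrix(c(0, 0), 1)), 5)
  B <- matrix(rnorm(6), 3, 2)
  expect_equal(consistency_loss(3 * A, 3 * B), 9 * consistency_loss(A, B),
               tolerance = 1e-9)
})

test_that("total loss combines terms with the configured weights", {
  lb <- total_loss(0.3, 0.2, lambda1 = 1, lambda2 = 1)
  expect_equal(lb$total, 0.5)
  expect_equal(total_loss(0.3, 0.2, 2, 0)$total, 0.6)
  expect_equal(total_loss(0.3, 0.2, 0, 3)$total, 0.6)
  expect_named(lb$terms, c("linguistic", "consistency"))
  expect_error(total_loss(1, 1, -1, 0))
})

# --- decoding -------------------------------------------------------------

test_that("decode_step yields a proper distribution and a uniform one at zero logits", {
  cfg <- tiny_seq_config()
  params <- init_alht_params(cfg, 6, 4, seed = 21)
  memory <- matrix(rnorm(3 * cfg$d_model), 3)
  st <- decoder_init(params, cfg, memory)
  p <- decode_step(st)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_named(p, cfg$vocab)
  p0 <- params; p0$out_W <- p0$out_W * 0; p0$out_b <- p0$out_b * 0
  expect_equal(as.numeric(decode_step(decoder_init(p0, cfg, memory))),
               rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("beam width 1 equals greedy decoding across random tiny models", {
  cfg <- tiny_seq_config()
  for (s in 1:100) {
    params <- init_alht_params(cfg, 6, 4, seed = 1000 + s)
    set.seed(s)
    memory <- matrix(rnorm(2 * cfg$d_model), 2)
    greedy <- integer()
    st <- decoder_init(params, cfg, memory)
    for (i in 1:3) {
      p <- decode_step(st)
      greedy <- c(greedy, as.integer(which.max(p)))
      st <- decoder_append(st, which.max(p))
    }
    expect_identical(beam_search(params, cfg, memory, 1, 3)$tokens, greedy)
  }
})

test_that("an exhaustive beam reproduces the brute-force argmax", {
  cfg <- tiny_seq_config()
  params <- init_alht_params(cfg, 6, 4, seed = 33)
  set.seed(33)
  memory <- matrix(rnorm(2 * cfg$d_model), 2)
  bf <- beam_bruteforce(params, cfg, memory, 4)
  bs <- beam_search(params, cfg, memory, 3^4, 4)
  expect_identical(bs$tokens, bf$tokens)
  expect_equal(bs$logprob, bf$logprob, tolerance = 1e-10)
  expect_error(beam_search(params, cfg, memory, 0, 2), "width")
})

test_that("tied hypotheses resolve to the lexicographically smallest sequence", {
  cfg <- tiny_seq_config()
  params <- init_alht_params(cfg, 6, 4, seed = 34)
  params$out_W <- params$out_W * 0; params$out_b <- params$out_b * 0  # all ties
  memory <- matrix(0, 2, cfg$d_model)
  expect_identical(beam_search(params, cfg, memory, 5, 3)$tokens, c(1L, 1L, 1L))
})
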