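# Model configuration, parameter initialization, and the end-to-end forward
# pass on the autodiff tape.
#
# The screening model chains: feature projection -> positional encoding ->
# transformer encoder stack -> convolutional noise suppression -> dynamic
# frame weighting -> (a) hierarchical fusion of learned query tokens with the
# weighted acoustic frames and (b) acoustic self-attention, gated-context
# cross-attention -> mean-pooled binary classification head. The composite
# loss combines classification cross-entropy, the temporal consistency term,
# the contextual alignment term, and (optionally) an entropy attention
# regularizer.

#' Model configuration
#'
#' Defaults follow the published architecture (6 encoder/decoder layers, 8
#' heads, hidden size 512, feedforward size 2048, dropout 0.2).
#' `tiny_preset = TRUE` switches to a desk-scale model (d_model 32, 2 layers,
#' 2 heads, feedforward 64) used throughout the tests.
#'
#' @param n_encoder_layers,n_decoder_layers Encoder / decoder depth.
#' @param n_heads Attention heads per layer (must divide `d_model`).
#' @param d_model Hidden size.
#' @param d_ffn Feedforward width.
#' @param dropout Dropout rate in `[0, 1)`, applied after each sub-layer at
#'   train time.
#' @param vocab Token inventory for sequence mode.
#' @param head_mode `"classifier"` (default; binary risk head) or
#'   `"token_sequence"` (autoregressive decoder over `vocab`).
#' @param lambda1,lambda2 Loss mixing weights (cross-entropy; quadratic
#'   alignment/consistency terms).
#' @param sparsity_mode `"literal"` or `"entropy"` attention regularizer.
#' @param sparsity_weight Weight on the regularizer (0 disables; the literal
#'   mode is constant for row-stochastic attention, so it defaults to 0).
#' @param positional_mode `"sinusoidal"` (interleaved sine/cosine) or
#'   `"sine_only"` (literal sine-only fill).
#' @param n_query Number of learned query tokens driving the fusion stage in
#'   classifier mode.
#' @param conv_width Width of the noise-suppression kernel (odd).
#' @param tiny_preset Use the desk-scale preset.
#' @return A validated list of class `model_config`.
#' @export
model_config <- function(n_encoder_layers = 6L, n_decoder_layers = 6L,
                         n_heads = 8L, d_model = 512L, d_ffn = 2048L,
                         dropout = 0.2, vocab = c("NEG", "POS", "EOS"),
                         head_mode = c("classifier", "token_sequence"),
                         lambda1 = 1.0, lambda2 = 0.1,
                         sparsity_mode = c("literal", "entropy"),
                         sparsity_weight = 0,
                         positional_mode = c("sinusoidal", "sine_only"),
                         n_query = 1L, conv_width = 3L, tiny_preset = FALSE) {
  if (tiny_preset) {
    d_model <- 32L; n_encoder_layers <- 2L; n_decoder_layers <- 2L
    n_heads <- 2L; d_ffn <- 64L
  }
  cfg <- list(n_encoder_layers = as.integer(n_encoder_layers),
              n_decoder_layers = as.integer(n_decoder_layers),
              n_heads = as.integer(n_heads), d_model = as.integer(d_model),
              d_ffn = as.integer(d_ffn), dropout = dropout, vocab = vocab,
              head_mode = match.arg(head_mode), lambda1 = lambda1,
              lambda2 = lambda2, sparsity_mode = match.arg(sparsity_mode),
              sparsity_weight = sparsity_weight,
              positional_mode = match.arg(positional_mode),
              n_query = as.integer(n_query), conv_width = as.integer(conv_width),
              tiny_preset = isTRUE(tiny_preset))
  if (cfg$d_model %% cfg$n_heads != 0L) stop("d_model must be divisible by n_heads")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (cfg$lambda1 < 0 || cfg$lambda2 < 0) stop("loss weights must be non-negative")
  if (cfg$conv_width %% 2L == 0L) stop("conv_width must be odd")
  structure(cfg, class = "model_config")
}

# Fan-in scaled uniform initialization.
init_mat <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
}

#' Initialize model parameters
#'
#' Projections use fan-in-scaled uniform draws; layer-norm affines start at
#' (1, 0); the noise-suppression kernel starts as the identity kernel; the
#' fusion scalars start at 0.1. All draws come from `seed`.
#'
#' @param config A [model_config()].
#' @param d_in Input feature dimension (columns of the feature matrices).
#' @param context_dim Length of the per-recording context vector.
#' @param seed Integer seed.
#' @return Named list of parameter matrices (row vectors for biases and
#'   layer-norm affines, 1x1 matrices for scalars).
#' @export
init_alht_params <- function(config, d_in, context_dim, seed = 1L) {
  set.seed(seed)
  d <- config$d_model
  p <- list(proj_W = init_mat(d_in, d), proj_b = matrix(0, 1L, d))
  for (l in seq_len(config$n_encoder_layers)) {
    p[[paste0("enc", l, "_Wq")]] <- init_mat(d, d)
    p[[paste0("enc", l, "_Wk")]] <- init_mat(d, d)
    p[[paste0("enc", l, "_Wv")]] <- init_mat(d, d)
    p[[paste0("enc", l, "_Wo")]] <- init_mat(d, d)
    p[[paste0("enc", l, "_ln1_g")]] <- matrix(1, 1L, d)
    p[[paste0("enc", l, "_ln1_b")]] <- matrix(0, 1L, d)
    p[[paste0("enc", l, "_ffn_W1")]] <- init_mat(d, config$d_ffn)
    p[[paste0("enc", l, "_ffn_b1")]] <- matrix(0, 1L, config$d_ffn)
    p[[paste0("enc", l, "_ffn_W2")]] <- init_mat(config$d_ffn, d)
    p[[paste0("enc", l, "_ffn_b2")]] <- matrix(0, 1L, d)
    p[[paste0("enc", l, "_ln2_g")]] <- matrix(1, 1L, d)
    p[[paste0("enc", l, "_ln2_b")]] <- matrix(0, 1L, d)
  }
  kern <- matrix(0, config$conv_width, 1L)
  kern[(config$conv_width + 1L) %/% 2L, 1L] <- 1
  p$conv_k <- kern
  p$fw_Wq <- init_mat(d, d); p$fw_Wk <- init_mat(d, d); p$fw_Wv <- init_mat(d, d)
  p$query_G <- init_mat(config$n_query, d)
  p$tf_Wq <- init_mat(d, d); p$tf_Wk <- init_mat(d, d); p$tf_Wv <- init_mat(d, d)
  p$sent_S <- init_mat(1L, d); p$spk_E <- init_mat(1L, d)
  p$alpha <- matrix(0.1, 1L, 1L); p$beta <- matrix(0.1, 1L, 1L)
  p$fus_ln_g <- matrix(1, 1L, d); p$fus_ln_b <- matrix(0, 1L, d)
  p$fus_W1 <- init_mat(d, config$d_ffn); p$fus_b1 <- matrix(0, 1L, config$d_ffn)
  p$fus_W2 <- init_mat(config$d_ffn, d); p$fus_b2 <- matrix(0, 1L, d)
  p$asa_ln_g <- matrix(1, 1L, d); p$asa_ln_b <- matrix(0, 1L, d)
  p$gate_Wc <- init_mat(context_dim, context_dim)
  p$gate_bc <- matrix(0, 1L, context_dim)
  p$ctx_W <- init_mat(context_dim, d); p$ctx_b <- matrix(0, 1L, d)
  p$caca_Wq <- init_mat(d, d); p$caca_Wk <- init_mat(d, d)
  p$caca_ln_g <- matrix(1, 1L, d); p$caca_ln_b <- matrix(0, 1L, d)
  p$cls_W <- init_mat(d, 2L); p$cls_b <- matrix(0, 1L, 2L)
  if (config$head_mode == "token_sequence") {
    p <- c(p, init_decoder_params(config))
  }
  p
}

#' Register parameters on a tape
#'
#' Registers every parameter matrix as a differentiable tape leaf.
#'
#' @param tp A tape from [tape_new()].
#' @param params Named list of parameter matrices.
#' @return Named list of integer node ids.
#' @export
register_params <- function(tp, params) {
  lapply(params, function(x) tp_param(tp, x))
}

# Inverted-dropout mask as a tape constant (NULL when disabled).
dropout_mask <- function(tp, dims, rate, training) {
  if (!training || rate <= 0) return(NULL)
  m <- matrix(stats::rbinom(prod(dims), 1L, 1 - rate), dims[1], dims[2]) / (1 - rate)
  tp_const(tp, m)
}

tp_maybe_drop <- function(tp, id, rate, training) {
  m <- dropout_mask(tp, dim(tp_value(tp, id)), rate, training)
  if (is.null(m)) id else tp_ewmul(tp, id, m)
}

# Multi-head self-attention block on the tape (projection + per-head
# attention + output projection); returns the pre-residual sub-layer output.
tp_mhsa <- function(tp, x, Wq, Wk, Wv, Wo, n_heads) {
  d <- ncol(tp_value(tp, x))
  dk <- d %/% n_heads
  Q <- tp_matmul(tp, x, Wq); K <- tp_matmul(tp, x, Wk); V <- tp_matmul(tp, x, Wv)
  heads <- lapply(seq_len(n_heads), function(h) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    s <- tp_scale_const(tp, tp_matmul_tB(tp, tp_cols(tp, Q, idx), tp_cols(tp, K, idx)),
                        1 / sqrt(dk))
    tp_matmul(tp, tp_softmax_rows(tp, s), tp_cols(tp, V, idx))
  })
  tp_matmul(tp, tp_cbind(tp, heads), Wo)
}

tp_ffn <- function(tp, x, W1, b1, W2, b2) {
  h <- tp_relu(tp, tp_add_rowvec(tp, tp_matmul(tp, x, W1), b1))
  tp_add_rowvec(tp, tp_matmul(tp, h, W2), b2)
}

#' Forward pass of the screening model on the autodiff tape
#'
#' Builds the complete computation graph for one window and returns tape node
#' ids for the classifier logits, each loss ingredient, and the main
#' intermediate representations. Ablation flags: `disable_AAE` bypasses the
#' dynamic frame weighting, `disable_DCA` bypasses the context gate (raw
#' context used).
#'
#' @param tp A tape from `tape_new()`.
#' @param pid Named list of parameter node ids from `register_params()`.
#' @param X T x d_in feature matrix for one window.
#' @param context Numeric context vector.
#' @param config A [model_config()].
#' @param flags List of ablation flags.
#' @param training Enable dropout (consumes RNG draws).
#' @return Named list of tape ids: `logits`, `F_enc`, `F_weighted`, `C_agg`,
#'   `C_final`, `H_ASA`, `H_CACA`, `asa_weights`, `caca_weights`,
#'   `fw_weights`.
#' @export
alht_cada_forward <- function(tp, pid, X, context, config,
                              flags = list(disable_AAE = FALSE, disable_DCA = FALSE),
                              training = FALSE) {
  drop <- config$dropout
  d <- config$d_model
  x <- tp_const(tp, X)
  f0 <- tp_add_rowvec(tp, tp_matmul(tp, x, pid$proj_W), pid$proj_b)
  pe <- positional_encoding(nrow(X), d,
                            if (config$positional_mode == "sinusoidal") "interleave" else "sine_only")
  h <- tp_add(tp, f0, tp_const(tp, pe))
  for (l in seq_len(config$n_encoder_layers)) {
    g <- function(nm) pid[[paste0("enc", l, "_", nm)]]
    a <- tp_mhsa(tp, h, g("Wq"), g("Wk"), g("Wv"), g("Wo"), config$n_heads)
    a <- tp_maybe_drop(tp, a, drop, training)
    h <- tp_layer_norm(tp, tp_add(tp, h, a), g("ln1_g"), g("ln1_b"))
    f <- tp_ffn(tp, h, g("ffn_W1"), g("ffn_b1"), g("ffn_W2"), g("ffn_b2"))
    f <- tp_maybe_drop(tp, f, drop, training)
    h <- tp_layer_norm(tp, tp_add(tp, h, f), g("ln2_g"), g("ln2_b"))
  }
  F_enc <- h

  clean <- tp_conv1d(tp, F_enc, pid$conv_k)
  if (isTRUE(flags$disable_AAE)) {
    F_weighted <- clean
    fw_weights <- NULL
  } else {
    q <- tp_matmul(tp, clean, pid$fw_Wq)
    k <- tp_matmul(tp, clean, pid$fw_Wk)
    v <- tp_matmul(tp, clean, pid$fw_Wv)
    w <- tp_softmax_rows(tp, tp_scale_const(tp, tp_matmul_tB(tp, q, k), 1 / sqrt(d)))
    F_weighted <- tp_matmul(tp, w, v)
    fw_weights <- w
  }

  # hierarchical fusion: learned query tokens attend over weighted frames
  qf <- tp_matmul(tp, pid$query_G, pid$tf_Wq)
  kf <- tp_matmul(tp, F_weighted, pid$tf_Wk)
  vf <- tp_matmul(tp, F_weighted, pid$tf_Wv)
  af <- tp_softmax_rows(tp, tp_scale_const(tp, tp_matmul_tB(tp, qf, kf), 1 / sqrt(d)))
  C_focus <- tp_matmul(tp, af, vf)
  agg_in <- tp_add_scaled_rowvec(tp, C_focus, pid$sent_S, pid$alpha)
  agg_in <- tp_add_scaled_rowvec(tp, agg_in, pid$spk_E, pid$beta)
  C_agg <- tp_layer_norm(tp, agg_in, pid$fus_ln_g, pid$fus_ln_b)
  ff <- tp_ffn(tp, C_agg, pid$fus_W1, pid$fus_b1, pid$fus_W2, pid$fus_b2)
  C_final <- tp_add(tp, C_agg, tp_maybe_drop(tp, ff, drop, training))

  # acoustic self-attention (literal, no projections) with residual + norm
  asa_s <- tp_scale_const(tp, tp_matmul_tB(tp, F_weighted, F_weighted), 1 / sqrt(d))
  asa_w <- tp_softmax_rows(tp, asa_s)
  H_ASA <- tp_layer_norm(tp, tp_add(tp, tp_matmul(tp, asa_w, F_weighted), F_weighted),
                         pid$asa_ln_g, pid$asa_ln_b)

  # gated context, projected to model space and broadcast over frames
  ctx <- tp_const(tp, matrix(context, 1L))
  if (isTRUE(flags$disable_DCA)) {
    c_dyn <- ctx
  } else {
    gate <- tp_sigmoid(tp, tp_add_rowvec(tp, tp_matmul_tB(tp, ctx, pid$gate_Wc),
                                         pid$gate_bc))
    gate <- tp_maybe_drop(tp, gate, drop, training)
    c_dyn <- tp_ewmul(tp, gate, ctx)
  }
  c_proj <- tp_add_rowvec(tp, tp_matmul(tp, c_dyn, pid$ctx_W), pid$ctx_b)
  c_rows <- tp_broadcast_rows(tp, c_proj, nrow(tp_value(tp, H_ASA)))

  # context-aware cross-attention from the fused states
  V_aug <- tp_add(tp, H_ASA, c_rows)
  qc <- tp_matmul(tp, C_final, pid$caca_Wq)
  kc <- tp_matmul(tp, V_aug, pid$caca_Wk)
  cw <- tp_softmax_rows(tp, tp_scale_const(tp, tp_matmul_tB(tp, qc, kc), 1 / sqrt(d)))
  attended <- tp_matmul(tp, cw, V_aug)
  attended <- tp_maybe_drop(tp, attended, drop, training)
  resid <- tp_broadcast_rows(tp, tp_row_mean(tp, H_ASA), config$n_query)
  H_CACA <- tp_layer_norm(tp, tp_add(tp, attended, resid),
                          pid$caca_ln_g, pid$caca_ln_b)

  logits <- tp_add_rowvec(tp, tp_matmul(tp, tp_row_mean(tp, H_CACA), pid$cls_W),
                          pid$cls_b)
  list(logits = logits, F_enc = F_enc, F_weighted = F_weighted, C_agg = C_agg,
       C_final = C_final, H_ASA = H_ASA, H_CACA = H_CACA,
       asa_weights = asa_w, caca_weights = cw, fw_weights = fw_weights)
}

#' Composite training loss for one window on the tape
#'
#' `L = lambda1 * L_CE + lambda2 * (L_consistency + L_CA) +
#' sparsity_weight * R`, where `L_CE` is the classification cross-entropy,
#' `L_consistency` the pooled squared distance between the encoder output and
#' the aggregated states, `L_CA` the pooled squared distance between the
#' self- and cross-attention outputs, and `R` the (entropy-mode) attention
#' regularizer. `disable_ALD = TRUE` sets lambda2 to zero.
#'
#' @inheritParams alht_cada_forward
#' @param target One-hot (or soft, under mixup) length-2 label vector.
#' @return List with tape id `loss`, the forward ids, and a numeric
#'   `breakdown` of the loss terms.
#' @export
alht_cada_loss <- function(tp, pid, X, context, target, config,
                           flags = list(), training = FALSE) {
  fw <- alht_cada_forward(tp, pid, X, context, config, flags, training)
  lce <- tp_softmax_ce(tp, fw$logits, matrix(target, 1L))
  lcons <- tp_sqdist(tp, tp_row_mean(tp, fw$F_enc), tp_row_mean(tp, fw$C_agg))
  lca <- tp_sqdist(tp, tp_row_mean(tp, fw$H_ASA), tp_row_mean(tp, fw$H_CACA))
  lam2 <- if (isTRUE(flags$disable_ALD)) 0 else config$lambda2
  ids <- c(lce, lcons, lca)
  wts <- c(config$lambda1, lam2, lam2)
  if (config$sparsity_weight > 0 && config$sparsity_mode == "entropy") {
    ids <- c(ids, tp_row_entropy(tp, fw$asa_weights))
    wts <- c(wts, config$sparsity_weight)
  }
  loss <- tp_weighted_sum(tp, ids, wts)
  list(loss = loss, forward = fw,
       breakdown = c(cross_entropy = as.numeric(tp_value(tp, lce)),
                     consistency = as.numeric(tp_value(tp, lcons)),
                     alignment = as.numeric(tp_value(tp, lca)),
                     total = as.numeric(tp_value(tp, loss))))
}

#' Predict risk labels for feature windows
#'
#' Runs the deterministic forward pass (no dropout, no augmentation) and
#' returns the classifier decision per window.
#'
#' @param params Parameter list (from [init_alht_params()] or a trained
#'   checkpoint).
#' @param features List of `feature_matrix` objects (or plain matrices with a
#'   `context` attribute supplied via `contexts`).
#' @param config A [model_config()].
#' @param contexts Optional list of context vectors overriding those on the
#'   features.
#' @param flags Ablation flags (see [alht_cada_forward()]).
#' @return Data frame with `label` (0/1), `confidence`, and `p_high` (the
#'   high-risk class probability) per window.
#' @export
predict_windows <- function(params, features, config, contexts = NULL,
                            flags = list()) {
  res <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    X <- if (inherits(f, "feature_matrix")) f$values else as.matrix(f)
    ctx <- if (!is.null(contexts)) contexts[[i]] else f$context
    tp <- tape_new()
    pid <- register_params(tp, params)
    fw <- alht_cada_forward(tp, pid, X, ctx, config, flags, training = FALSE)
    p <- as.numeric(softmax_rows(tp_value(tp, fw$logits)))
    data.frame(label = which.max(p) - 1L, confidence = max(p), p_high = p[2])
  })
  do.call(rbind, res)
}
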