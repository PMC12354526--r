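# Plain-matrix operator surface of the hierarchical transformer.
#
# These functions expose each architectural stage on ordinary matrices with
# explicit parameters, independent of the training tape. The trainable
# forward pass (model-forward.R) composes the same numeric kernels on the
# autodiff tape.

#' Attention result container
#'
#' @param weights Row-stochastic attention weight matrix.
#' @param attended Attended output (`weights %*% values`).
#' @param scores Pre-softmax score matrix.
#' @return List of class `attention_result`.
#' @export
attention_result <- function(weights, attended, scores = NULL) {
  structure(list(weights = weights, attended = attended, scores = scores),
            class = "attention_result")
}

#' Project input frames into model space
#'
#' Affine map applied per frame: `X %*% W + b`.
#'
#' @param features T x d_in matrix (or a `feature_matrix`).
#' @param W d_in x d_model weight matrix.
#' @param b Length-d_model bias (default 0).
#' @return T x d_model matrix.
#' @export
feature_project <- function(features, W, b = rep(0, ncol(W))) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  assert_finite(X, "features")
  if (ncol(X) != nrow(W)) stop("feature dimension does not match projection")
  sweep(X %*% W, 2L, b, `+`)
}

#' Sinusoidal positional encoding matrix
#'
#' Positions are 0-based. In `"interleave"` mode dimension `2k+1` carries
#' `sin(t / 10000^(2k/d))` and dimension `2k+2` the matching cosine; in
#' `"sine_only"` mode the first `d/2` dimensions carry the sines and the rest
#' are zero.
#'
#' @param T_ Number of positions.
#' @param d Model dimension.
#' @param mode `"interleave"` (default) or `"sine_only"`.
#' @return T x d matrix; identical for any input content at a given (T, d).
#' @export
positional_encoding <- function(T_, d, mode = c("interleave", "sine_only")) {
  mode <- match.arg(mode)
  P <- matrix(0, T_, d)
  t <- seq_len(T_) - 1L
  half <- d %/% 2L
  for (k in seq_len(half) - 1L) {
    ang <- t / 10000^(2 * k / d)
    if (mode == "interleave") {
      P[, 2L * k + 1L] <- sin(ang)
      if (2L * k + 2L <= d) P[, 2L * k + 2L] <- cos(ang)
    } else {
      P[, k + 1L] <- sin(ang)
    }
  }
  P
}

#' Add positional encodings to projected frames
#'
#' @param F0 T x d_model matrix.
#' @param mode Passed to [positional_encoding()].
#' @return `F0 + P`.
#' @export
positional_encode <- function(F0, mode = c("interleave", "sine_only")) {
  F0 + positional_encoding(nrow(F0), ncol(F0), match.arg(mode))
}

# Multi-head self-attention on plain matrices (post-norm convention is
# applied by the caller).
mhsa_plain <- function(X, Wq, Wk, Wv, Wo, n_heads) {
  d <- ncol(X)
  dk <- d %/% n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  out <- matrix(0, nrow(X), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    att <- scaled_dot_attention(Q[, idx, drop = FALSE], K[, idx, drop = FALSE],
                                V[, idx, drop = FALSE], d_key = dk)
    out[, idx] <- att$attended
  }
  out %*% Wo
}

#' Transformer encoder stack
#'
#' Applies `length(layers)` encoder blocks, each consisting of multi-head
#' self-attention and a position-wise feedforward network, with residual
#' connection and layer normalization after each sub-layer (post-norm). An
#' empty layer list is the identity.
#'
#' @param F0 T x d_model input.
#' @param layers List of per-layer parameter lists (`Wq, Wk, Wv, Wo, ln1_g,
#'   ln1_b, ffn_W1, ffn_b1, ffn_W2, ffn_b2, ln2_g, ln2_b`), e.g. the `enc`
#'   component of [init_alht_params()].
#' @param n_heads Number of attention heads (must divide d_model).
#' @return T x d_model output.
#' @export
encoder_stack <- function(F0, layers, n_heads = 2L) {
  X <- as.matrix(F0)
  for (ly in layers) {
    A <- mhsa_plain(X, ly$Wq, ly$Wk, ly$Wv, ly$Wo, n_heads)
    X <- layer_norm_rows(X + A, ly$ln1_g, ly$ln1_b)
    H <- sweep(pmax(sweep(X %*% ly$ffn_W1, 2L, ly$ffn_b1, `+`), 0) %*% ly$ffn_W2,
               2L, ly$ffn_b2, `+`)
    X <- layer_norm_rows(X + H, ly$ln2_g, ly$ln2_b)
  }
  X
}

#' Convolutional noise suppression
#'
#' 1-D convolution along the time axis applied to every feature column with a
#' shared odd-width kernel, zero padded to the same length.
#'
#' @param F_mask T x d matrix.
#' @param kernel Odd-length numeric kernel (default identity `c(0, 1, 0)`).
#' @return T x d matrix `F_clean`.
#' @export
conv_noise_suppress <- function(F_mask, kernel = c(0, 1, 0)) {
  if (length(kernel) %% 2L == 0L) stop("kernel width must be odd")
  conv1d_cols(as.matrix(F_mask), as.numeric(kernel))
}

#' Dynamic frame weighting
#'
#' Self-attention over cleaned frames: `W_t = softmax(Q K' / sqrt(d_k))`,
#' `F_weighted = W_t V`, with Q, K, V affine projections of `F_clean`.
#'
#' @param F_clean T x d matrix.
#' @param Wq,Wk,Wv d x d projection matrices (defaults: identity).
#' @return List with `weighted` (T x d) and `attention`
#'   (an [attention_result()]).
#' @export
frame_weighting <- function(F_clean, Wq = diag(ncol(F_clean)),
                            Wk = diag(ncol(F_clean)), Wv = diag(ncol(F_clean))) {
  X <- as.matrix(F_clean)
  att <- scaled_dot_attention(X %*% Wq, X %*% Wk, X %*% Wv, d_key = ncol(Wk))
  list(weighted = att$attended,
       attention = attention_result(att$weights, att$attended, att$scores))
}

#' Temporal focus attention
#'
#' Cross-attention from token states onto acoustic frames:
#' `A_focus = softmax(ProjQ(tokens) ProjK(acoustic)' / sqrt(d_key))`,
#' `C_focus = A_focus ProjV(acoustic)`.
#'
#' @param tokens N x d token-state matrix.
#' @param acoustic T x d acoustic feature matrix.
#' @param Wq,Wk,Wv d x d projection matrices (defaults: identity).
#' @return List with `C_focus` (N x d) and `attention` (A_focus as an
#'   [attention_result()]).
#' @export
temporal_focus <- function(tokens, acoustic, Wq = diag(ncol(tokens)),
                           Wk = diag(ncol(acoustic)), Wv = diag(ncol(acoustic))) {
  att <- scaled_dot_attention(as.matrix(tokens) %*% Wq,
                              as.matrix(acoustic) %*% Wk,
                              as.matrix(acoustic) %*% Wv, d_key = ncol(Wk))
  list(C_focus = att$attended,
       attention = attention_result(att$weights, att$attended, att$scores))
}

#' Contextual aggregation with global and speaker embeddings
#'
#' `C_agg = LayerNorm(C_focus + alpha * S + beta * E)`, then
#' `C_final = FFN(C_agg) + C_agg`. With `ffn = NULL` the feedforward term is
#' zero and `C_final = C_agg`.
#'
#' @param C_focus N x d matrix.
#' @param S,E Length-d sentence-level and speaker embeddings.
#' @param alpha,beta Scalar mixing weights.
#' @param ffn Optional list `(W1, b1, W2, b2)` for the feedforward network.
#' @param ln_g,ln_b Layer-norm affine parameters (defaults 1 and 0).
#' @return List with `C_agg` and `C_final` (both N x d).
#' @export
contextual_aggregate <- function(C_focus, S, E, alpha = 0, beta = 0, ffn = NULL,
                                 ln_g = rep(1, ncol(C_focus)),
                                 ln_b = rep(0, ncol(C_focus))) {
  X <- sweep(as.matrix(C_focus), 2L, alpha * S + beta * E, `+`)
  C_agg <- layer_norm_rows(X, ln_g, ln_b)
  C_final <- if (is.null(ffn)) {
    C_agg
  } else {
    sweep(pmax(sweep(C_agg %*% ffn$W1, 2L, ffn$b1, `+`), 0) %*% ffn$W2,
          2L, ffn$b2, `+`) + C_agg
  }
  list(C_agg = C_agg, C_final = C_final)
}

#' Cross-modal attention recalibration
#'
#' Recomputes attention weights from decoder predictions against the acoustic
#' keys: `A_refined = softmax(ProjQ(Y_pred) K_focus' / sqrt(d_key))`.
#'
#' @param Y_pred N x d prediction-state matrix.
#' @param K_focus T x d_key key matrix.
#' @param Wq d x d_key query projection (default identity).
#' @return An [attention_result()] with row-stochastic `weights` (attended is
#'   `NULL`; this op recalibrates weights only).
#' @export
cross_modal_refine <- function(Y_pred, K_focus, Wq = diag(ncol(Y_pred))) {
  scores <- (as.matrix(Y_pred) %*% Wq) %*% t(as.matrix(K_focus)) / sqrt(ncol(K_focus))
  attention_result(softmax_rows(scores), NULL, scores)
}

#' Binary classification head
#'
#' Mean-pools the aggregated states over positions, applies a linear map to
#' two logits, and takes a softmax over {low-risk, high-risk}.
#'
#' @param C_agg N x d matrix of aggregated states.
#' @param W d x 2 weight matrix.
#' @param b Length-2 bias (default 0).
#' @return List with `label` (0/1), `confidence` (max class probability, in
#'   `[0.5, 1]` for a binary head), and `probs` (length-2).
#' @export
classify <- function(C_agg, W, b = c(0, 0)) {
  pooled <- matrix(colMeans(as.matrix(C_agg)), 1L)
  probs <- as.numeric(softmax_rows(sweep(pooled %*% W, 2L, b, `+`)))
  label <- which.max(probs) - 1L
  list(label = label, confidence = max(probs), probs = probs)
}

#' Linguistic (cross-entropy) loss
#'
#' Negative log-likelihood of the target tokens under the predicted
#' distributions, summed over sequence positions and mean-reduced over the
#' batch. Probabilities below `1e-12` are clamped with a warning.
#'
#' @param predictions N x V matrix of row distributions, or a list of such
#'   matrices (a batch).
#' @param targets Integer vector of 1-based target indices per row (or a list
#'   matching `predictions`).
#' @return Scalar loss.
#' @export
linguistic_loss <- function(predictions, targets) {
  if (!is.list(predictions)) { predictions <- list(predictions); targets <- list(targets) }
  per_seq <- mapply(function(P, y) {
    p <- P[cbind(seq_along(y), y)]
    if (any(p < 1e-12)) {
      warning("zero probability on a target token; clamped at 1e-12")
      p <- pmax(p, 1e-12)
    }
    -sum(log(p))
  }, predictions, targets)
  mean(per_seq)
}

#' Temporal consistency loss
#'
#' Squared Euclidean distance between the time-mean-pooled acoustic
#' representation and the position-mean-pooled aggregated representation
#' (pooling reconciles the T x d vs N x d shapes).
#'
#' @param F_audio T x d acoustic representation.
#' @param C_agg N x d aggregated representation.
#' @return Scalar loss.
#' @export
consistency_loss <- function(F_audio, C_agg) {
  a <- colMeans(as.matrix(F_audio))
  b <- colMeans(as.matrix(C_agg))
  sum((a - b)^2)
}

#' Weighted total loss (linguistic + consistency)
#'
#' `L = lambda1 * L_linguistic + lambda2 * L_consistency`.
#'
#' @param L_ling,L_cons Scalar loss terms.
#' @param lambda1,lambda2 Non-negative mixing weights.
#' @return A `loss_breakdown`: list with `total`, `terms`, `weights`.
#' @export
total_loss <- function(L_ling, L_cons, lambda1 = 1.0, lambda2 = 0.1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  structure(list(total = lambda1 * L_ling + lambda2 * L_cons,
                 terms = c(linguistic = L_ling, consistency = L_cons),
                 weights = c(lambda1 = lambda1, lambda2 = lambda2)),
            class = "loss_breakdown")
}
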