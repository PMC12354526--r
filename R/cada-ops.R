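# Context-adaptive dual attention: acoustic self-attention with a sparsity
# regularizer, a sigmoid context gate, context-aware cross-attention, and the
# alignment/composite losses.

#' Acoustic self-attention
#'
#' Literal form: `A = softmax(H H' / sqrt(d_h))` with no learned projections;
#' `attended = A H`. Setting `use_projections = TRUE` (with `Wq`, `Wk`)
#' enables projected queries/keys for ablation comparisons.
#'
#' @param H T x d_h embedding matrix (positional encodings assumed added).
#' @param use_projections Use learned query/key projections instead of the
#'   literal `H H'` form.
#' @param Wq,Wk d_h x d_h projections (only used when
#'   `use_projections = TRUE`).
#' @return An [attention_result()].
#' @export
asa_attention <- function(H, use_projections = FALSE, Wq = NULL, Wk = NULL) {
  H <- as.matrix(H)
  assert_finite(H, "H")
  Q <- if (use_projections) H %*% Wq else H
  K <- if (use_projections) H %*% Wk else H
  att <- scaled_dot_attention(Q, K, H, d_key = ncol(H))
  attention_result(att$weights, att$attended, att$scores)
}

#' Attention sparsity penalty
#'
#' `"literal"` mode returns the entrywise L1 norm of the weight matrix. For a
#' row-stochastic matrix this is identically the number of rows, so it cannot
#' induce sparsity; it is retained as stated, with weight 0 by default in the
#' composite loss. `"entropy"` mode returns the mean row entropy, which is 0
#' at one-hot rows and `log(T)` at uniform rows and does reward concentrated
#' attention.
#'
#' @param weights Row-stochastic attention matrix.
#' @param mode `"literal"` or `"entropy"`.
#' @return Scalar penalty.
#' @export
sparsity_penalty <- function(weights, mode = c("literal", "entropy")) {
  mode <- match.arg(mode)
  W <- as.matrix(weights)
  if (mode == "literal") sum(abs(W)) else -mean(rowSums(W * log(pmax(W, 1e-12))))
}

#' Acoustic self-attention block with residual and layer norm
#'
#' `H_ASA = LayerNorm(attended + H)` where `attended` comes from
#' [asa_attention()].
#'
#' @param H T x d_h embedding matrix.
#' @param ln_g,ln_b Layer-norm affine parameters (defaults 1 and 0).
#' @param ... Passed to [asa_attention()].
#' @return List with `H_ASA` (T x d_h) and `attention`.
#' @export
asa_block <- function(H, ln_g = rep(1, ncol(H)), ln_b = rep(0, ncol(H)), ...) {
  att <- asa_attention(H, ...)
  list(H_ASA = layer_norm_rows(att$attended + as.matrix(H), ln_g, ln_b),
       attention = att)
}

#' Sigmoid context gate
#'
#' `C_dyn = sigmoid(Wc C + bc) * C` (elementwise). Because the gate lies in
#' (0, 1), `|C_dyn| <= |C|` componentwise, and every component of `C_dyn` is
#' monotone increasing in `bc`. An optional dropout mask (training only)
#' applies to the sigmoid activations, not to `C` itself.
#'
#' @param C Context vector (length p).
#' @param Wc p x p gate weight matrix.
#' @param bc Length-p gate bias.
#' @param gate_mask Optional multiplicative mask on the sigmoid activations.
#' @return List with `C_dyn` and `gate` (the sigmoid activations).
#' @export
context_gate <- function(C, Wc, bc, gate_mask = NULL) {
  C <- as.numeric(C)
  g <- sigmoid(as.numeric(Wc %*% C) + as.numeric(bc))
  if (!is.null(gate_mask)) g <- g * gate_mask
  list(C_dyn = g * C, gate = g)
}

#' Context-aware cross-attention
#'
#' `Q = G Wq`, `K = (H_ASA + C) Wk`, `V = H_ASA + C`, where `C` is the gated
#' context already projected/broadcast to T x d (use a zero matrix or `NULL`
#' for no context). The attended output receives a residual connection and
#' layer normalization; when the query count N differs from T the residual
#' uses the row-mean of `H_ASA` broadcast to N rows (the same pooling rule as
#' the alignment loss).
#'
#' @param G N x d linguistic-state (query) matrix.
#' @param H_ASA T x d acoustic embedding matrix.
#' @param C Optional T x d context matrix added to the acoustic embeddings.
#' @param Wq,Wk d x d projection matrices (defaults: identity).
#' @param ln_g,ln_b Layer-norm affine parameters.
#' @return List with `H_CACA` (N x d), `attended_raw` (pre-residual), and
#'   `attention`.
#' @export
caca_attention <- function(G, H_ASA, C = NULL, Wq = diag(ncol(G)),
                           Wk = diag(ncol(H_ASA)),
                           ln_g = rep(1, ncol(H_ASA)),
                           ln_b = rep(0, ncol(H_ASA))) {
  G <- as.matrix(G); H_ASA <- as.matrix(H_ASA)
  V <- if (is.null(C)) H_ASA else H_ASA + as.matrix(C)
  att <- scaled_dot_attention(G %*% Wq, V %*% Wk, V, d_key = ncol(Wk))
  resid <- if (nrow(G) == nrow(H_ASA)) {
    H_ASA
  } else {
    matrix(colMeans(H_ASA), nrow(G), ncol(H_ASA), byrow = TRUE)
  }
  list(H_CACA = layer_norm_rows(att$attended + resid, ln_g, ln_b),
       attended_raw = att$attended,
       attention = attention_result(att$weights, att$attended, att$scores))
}

#' Contextual alignment loss
#'
#' Squared Euclidean distance between the mean-pooled acoustic
#' self-attention output and the mean-pooled cross-attention output (pooling
#' reconciles T x d vs N x d shapes, matching the consistency-loss rule).
#'
#' @param H_ASA T x d matrix.
#' @param H_CACA N x d matrix.
#' @return Scalar loss (non-negative; 0 for identical pooled inputs).
#' @export
alignment_loss <- function(H_ASA, H_CACA) {
  a <- colMeans(as.matrix(H_ASA))
  b <- colMeans(as.matrix(H_CACA))
  sum((a - b)^2)
}

#' Composite dual-attention loss
#'
#' `L = lambda1 * L_CE + lambda2 * L_CA + sparsity_weight * R`. In literal
#' sparsity mode the regularizer is a constant for row-stochastic attention,
#' so its default weight is 0; supply the entropy-mode penalty with a
#' positive weight to actually reward concentrated attention.
#'
#' @param L_CE Cross-entropy loss term.
#' @param L_CA Alignment loss term.
#' @param lambda1,lambda2 Non-negative mixing weights.
#' @param sparsity Regularizer value (see [sparsity_penalty()]).
#' @param sparsity_weight Non-negative weight on the regularizer (default 0).
#' @return A `loss_breakdown`: list with `total`, `terms`, `weights`.
#' @export
cada_total_loss <- function(L_CE, L_CA, lambda1 = 1.0, lambda2 = 0.1,
                            sparsity = 0, sparsity_weight = 0) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, sparsity_weight >= 0)
  structure(list(total = lambda1 * L_CE + lambda2 * L_CA + sparsity_weight * sparsity,
                 terms = c(cross_entropy = L_CE, alignment = L_CA, sparsity = sparsity),
                 weights = c(lambda1 = lambda1, lambda2 = lambda2,
                             sparsity_weight = sparsity_weight)),
            class = "loss_breakdown")
}
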