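# Shared numeric kernels. Both the plain (inference/test) operator surface and
# the autodiff tape call these, so the two paths cannot drift apart.

#' Row-wise softmax
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape whose rows are non-negative and sum to 1.
#' @export
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

#' Row-wise layer normalization
#'
#' Standardizes each row to zero mean and unit variance (population variance,
#' stabilized by `eps`), then applies the learned affine map
#' `gamma * xhat + beta`.
#'
#' @param x Numeric matrix (rows are positions, columns features).
#' @param gamma,beta Affine parameters, length `ncol(x)` (defaults 1 and 0).
#' @param eps Variance stabilizer.
#' @return Matrix of the same shape.
#' @export
layer_norm_rows <- function(x, gamma = NULL, beta = NULL, eps = 1e-6) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (is.null(gamma)) gamma <- rep(1, d)
  if (is.null(beta)) beta <- rep(0, d)
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2
  xhat <- (x - mu) / sqrt(v + eps)
  sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
}

#' Numerically safe sigmoid
#' @param x Numeric array.
#' @return `1 / (1 + exp(-x))`, elementwise.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# Scaled dot-product attention on plain matrices.
# Returns weights softmax(Q K^T / sqrt(d_key)) and attended = weights %*% V.
scaled_dot_attention <- function(Q, K, V, d_key = ncol(K)) {
  scores <- (Q %*% t(K)) / sqrt(d_key)
  W <- softmax_rows(scores)
  list(weights = W, attended = W %*% V, scores = scores)
}

# 1-D convolution of each column of x along the row (time) axis with an odd
# length kernel, zero padded to the same length.
conv1d_cols <- function(x, kernel) {
  x <- as.matrix(x)
  w <- length(kernel)
  stopifnot(w %% 2L == 1L)
  half <- (w - 1L) %/% 2L
  T_ <- nrow(x)
  out <- matrix(0, T_, ncol(x))
  for (j in seq_len(w)) {
    off <- j - 1L - half
    src <- seq_len(T_) + off
    ok <- src >= 1L & src <= T_
    out[ok, ] <- out[ok, ] + kernel[j] * x[src[ok], , drop = FALSE]
  }
  out
}

# Internal check that every entry is finite.
assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}
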