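# Minimal reverse-mode automatic differentiation on a tape of matrix ops.
#
# The model's training loop needs exact analytic gradients of the composite
# loss with respect to every parameter; this tape provides them. Nodes are
# created in topological order by construction, so backpropagation is a
# single reverse sweep. Each node stores the op name and whatever forward
# quantities its vector-Jacobian product needs; the backward rules live in
# one static dispatch table (no per-node closures, which keeps the hot
# training loop free of repeated closure compilation).
#
# The API is intentionally small: each tp_* function appends a node and
# returns its integer id. Scalars are 1x1 matrices.

#' Create an empty autodiff tape
#'
#' The tape records matrix operations in topological order so that
#' [tp_backward()] can return exact gradients in one reverse sweep. Used by
#' the training loop; exposed for gradient checking and extension.
#'
#' @return A tape environment.
#' @export
tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = integer(), op = NULL, ctx = NULL) {
  force(value); force(parents); force(ctx)  # nested tp_* calls must land first
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(value = value, parents = parents, op = op, ctx = ctx)
  tp$n <- n
  n
}

#' Value of a tape node
#' @param tp A tape.
#' @param id Integer node id.
#' @return The node's numeric matrix value.
#' @export
tp_value <- function(tp, id) {
  force(id)  # the id argument may itself push nodes; force before indexing
  tp$nodes[[id]]$value
}

# Fast helpers ------------------------------------------------------------

add_row <- function(A, v) A + rep(v, each = nrow(A))       # v has length ncol(A)
mul_row <- function(A, v) A * rep(v, each = nrow(A))

# Leaves -----------------------------------------------------------------

tp_const <- function(tp, x) tp_push(tp, as.matrix(x))

tp_param <- function(tp, x) tp_push(tp, as.matrix(x), op = "leaf")

# Ops --------------------------------------------------------------------

tp_matmul <- function(tp, a, b) {
  tp_push(tp, tp_value(tp, a) %*% tp_value(tp, b), c(a, b), "matmul")
}

# A %*% t(B)
tp_matmul_tB <- function(tp, a, b) {
  tp_push(tp, tcrossprod(tp_value(tp, a), tp_value(tp, b)), c(a, b), "matmul_tB")
}

tp_add <- function(tp, a, b) {
  A <- tp_value(tp, a); B <- tp_value(tp, b)
  stopifnot(all(dim(A) == dim(B)))
  tp_push(tp, A + B, c(a, b), "add")
}

# A (n x d) + row vector rv (1 x d), broadcast over rows.
tp_add_rowvec <- function(tp, a, rv) {
  tp_push(tp, add_row(tp_value(tp, a), as.numeric(tp_value(tp, rv))),
          c(a, rv), "add_rowvec")
}

# A + s * rv with learnable scalar s (1x1) and row vector rv (1 x d).
tp_add_scaled_rowvec <- function(tp, a, rv, s) {
  R <- as.numeric(tp_value(tp, rv)); S <- as.numeric(tp_value(tp, s))
  tp_push(tp, add_row(tp_value(tp, a), S * R), c(a, rv, s),
          "add_scaled_rowvec", list(R = R, S = S))
}

tp_scale_const <- function(tp, a, k) {
  tp_push(tp, k * tp_value(tp, a), a, "scale_const", list(k = k))
}

# Elementwise product (equal shapes).
tp_ewmul <- function(tp, a, b) {
  A <- tp_value(tp, a); B <- tp_value(tp, b)
  stopifnot(all(dim(A) == dim(B)))
  tp_push(tp, A * B, c(a, b), "ewmul")
}

tp_sigmoid <- function(tp, a) {
  tp_push(tp, sigmoid(tp_value(tp, a)), a, "sigmoid")
}

tp_relu <- function(tp, a) {
  tp_push(tp, pmax(tp_value(tp, a), 0), a, "relu")
}

tp_softmax_rows <- function(tp, a) {
  tp_push(tp, softmax_rows(tp_value(tp, a)), a, "softmax_rows")
}

tp_layer_norm <- function(tp, a, gamma, beta, eps = 1e-6) {
  A <- tp_value(tp, a)
  G <- as.numeric(tp_value(tp, gamma)); B <- as.numeric(tp_value(tp, beta))
  mu <- rowMeans(A)
  v <- rowMeans(A * A) - mu * mu
  inv <- 1 / sqrt(v + eps)
  xhat <- (A - mu) * inv
  tp_push(tp, add_row(mul_row(xhat, G), B), c(a, gamma, beta), "layer_norm",
          list(G = G, xhat = xhat, inv = inv))
}

# Convolution of each feature column along time with a learnable odd kernel.
tp_conv1d <- function(tp, a, kernel) {
  K <- as.numeric(tp_value(tp, kernel))
  tp_push(tp, conv1d_cols(tp_value(tp, a), K), c(a, kernel), "conv1d",
          list(K = K, kdim = dim(tp_value(tp, kernel))))
}

# Mean over rows -> 1 x d.
tp_row_mean <- function(tp, a) {
  tp_push(tp, matrix(colMeans(tp_value(tp, a)), 1L), a, "row_mean")
}

# Repeat a 1 x d row n times -> n x d.
tp_broadcast_rows <- function(tp, a, n) {
  A <- tp_value(tp, a)
  stopifnot(nrow(A) == 1L)
  tp_push(tp, matrix(as.numeric(A), n, ncol(A), byrow = TRUE), a, "broadcast_rows")
}

# Column subset (used to split attention heads); backward scatters.
tp_cols <- function(tp, a, idx) {
  tp_push(tp, tp_value(tp, a)[, idx, drop = FALSE], a, "cols",
          list(idx = idx, dims = dim(tp_value(tp, a))))
}

tp_cbind <- function(tp, ids) {
  vals <- lapply(ids, tp_value, tp = tp)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  tp_push(tp, do.call(cbind, vals), as.integer(ids), "cbind",
          list(starts = ends - widths + 1L, ends = ends))
}

# Squared Euclidean distance between equal-shape arrays -> scalar.
tp_sqdist <- function(tp, a, b) {
  D <- tp_value(tp, a) - tp_value(tp, b)
  tp_push(tp, matrix(sum(D * D), 1L, 1L), c(a, b), "sqdist", list(D = D))
}

# Cross-entropy between row-wise softmax(logits) and fixed target rows
# (one-hot or soft), averaged over rows -> scalar.
tp_softmax_ce <- function(tp, logits, targets) {
  P <- softmax_rows(tp_value(tp, logits))
  n <- nrow(P)
  val <- -sum(targets * log(pmax(P, 1e-12))) / n
  tp_push(tp, matrix(val, 1L, 1L), logits, "softmax_ce",
          list(P = P, targets = targets, n = n))
}

# Mean row entropy of a row-stochastic matrix -> scalar (entropy-mode
# attention regularizer).
tp_row_entropy <- function(tp, a, eps = 1e-12) {
  A <- tp_value(tp, a)
  lA <- log(pmax(A, eps))
  tp_push(tp, matrix(-sum(A * lA) / nrow(A), 1L, 1L), a, "row_entropy",
          list(lA = lA, n = nrow(A)))
}

# Weighted sum of scalar nodes -> scalar.
tp_weighted_sum <- function(tp, ids, weights) {
  vals <- vapply(ids, function(i) as.numeric(tp_value(tp, i)), 0)
  tp_push(tp, matrix(sum(weights * vals), 1L, 1L), as.integer(ids),
          "weighted_sum", list(weights = weights))
}

# Backward dispatch -------------------------------------------------------

# Vector-Jacobian products: given the adjoint g of the node output, return
# the adjoint contribution for each parent, in parent order.
tp_vjp <- function(tp, node, g) {
  ctx <- node$ctx
  pv <- function(k) tp$nodes[[node$parents[k]]]$value
  switch(node$op,
    matmul = list(tcrossprod(g, pv(2L)), crossprod(pv(1L), g)),
    matmul_tB = list(g %*% pv(2L), crossprod(g, pv(1L))),
    add = list(g, g),
    add_rowvec = list(g, matrix(colSums(g), 1L)),
    add_scaled_rowvec = list(g, matrix(ctx$S * colSums(g), 1L),
                             matrix(sum(mul_row(g, ctx$R)), 1L, 1L)),
    scale_const = list(ctx$k * g),
    ewmul = list(g * pv(2L), g * pv(1L)),
    sigmoid = { S <- node$value; list(g * S * (1 - S)) },
    relu = list(g * (node$value > 0)),
    softmax_rows = { S <- node$value; list(S * (g - rowSums(g * S))) },
    layer_norm = {
      dxhat <- mul_row(g, ctx$G)
      list((dxhat - rowMeans(dxhat) - ctx$xhat * rowMeans(dxhat * ctx$xhat)) * ctx$inv,
           matrix(colSums(g * ctx$xhat), 1L),
           matrix(colSums(g), 1L))
    },
    conv1d = {
      A <- pv(1L); K <- ctx$K
      w <- length(K); half <- (w - 1L) %/% 2L; T_ <- nrow(A)
      dA <- matrix(0, T_, ncol(A)); dK <- numeric(w)
      for (j in seq_len(w)) {
        off <- j - 1L - half
        src <- seq_len(T_) + off
        ok <- src >= 1L & src <= T_
        dK[j] <- sum(g[ok, , drop = FALSE] * A[src[ok], , drop = FALSE])
        dA[src[ok], ] <- dA[src[ok], , drop = FALSE] + K[j] * g[ok, , drop = FALSE]
      }
      list(dA, matrix(dK, ctx$kdim[1], ctx$kdim[2]))
    },
    row_mean = {
      T_ <- nrow(pv(1L))
      list(matrix(rep(as.numeric(g) / T_, each = T_), T_))
    },
    broadcast_rows = list(matrix(colSums(g), 1L)),
    cols = {
      dA <- matrix(0, ctx$dims[1], ctx$dims[2]); dA[, ctx$idx] <- g; list(dA)
    },
    cbind = lapply(seq_along(node$parents), function(i) {
      g[, ctx$starts[i]:ctx$ends[i], drop = FALSE]
    }),
    sqdist = { k <- as.numeric(g); list(2 * k * ctx$D, -2 * k * ctx$D) },
    softmax_ce = list(as.numeric(g) * (ctx$P - ctx$targets) / ctx$n),
    row_entropy = list(as.numeric(g) * (-(ctx$lA + 1)) / ctx$n),
    weighted_sum = lapply(ctx$weights, function(w) {
      matrix(w * as.numeric(g), 1L, 1L)
    }),
    stop(sprintf("no backward rule for op '%s'", node$op))
  )
}

#' Reverse sweep: gradients of a scalar node
#'
#' Seeds d(loss)/d(loss) = 1 at `loss_id` and accumulates vector-Jacobian
#' products back to every reachable node.
#'
#' @param tp A tape.
#' @param loss_id Id of the scalar output node.
#' @return List of gradients indexed by node id (non-NULL only where a path
#'   to the loss exists).
#' @export
tp_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  v <- tp_value(tp, loss_id)
  grads[[loss_id]] <- matrix(1, nrow(v), ncol(v))
  for (i in seq(loss_id, 1L)) {
    g <- grads[[i]]
    node <- tp$nodes[[i]]
    if (is.null(g) || is.null(node$op) || node$op == "leaf") next
    pg <- tp_vjp(tp, node, g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}
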