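# Autoregressive token decoder and beam search.
#
# The screening task is binary, but the decoding pathway is kept fully
# functional in `head_mode = "token_sequence"`: a stack of transformer
# decoder layers (causal self-attention + cross-attention over the aggregated
# memory + feedforward, post-norm) projects onto a small vocabulary, and
# inference can run greedily or with beam search.

# Decoder parameter block (token embeddings, per-layer attention/FFN, output
# projection). Drawn from the RNG stream active in init_alht_params().
init_decoder_params <- function(config) {
  d <- config$d_model
  V <- length(config$vocab)
  p <- list(tok_E = init_mat(V, d), start_emb = init_mat(1L, d),
            out_W = init_mat(d, V), out_b = matrix(0, 1L, V))
  for (l in seq_len(config$n_decoder_layers)) {
    for (nm in c("sWq", "sWk", "sWv", "sWo", "cWq", "cWk", "cWv", "cWo")) {
      p[[paste0("dec", l, "_", nm)]] <- init_mat(d, d)
    }
    p[[paste0("dec", l, "_ln1_g")]] <- matrix(1, 1L, d)
    p[[paste0("dec", l, "_ln1_b")]] <- matrix(0, 1L, d)
    p[[paste0("dec", l, "_ln2_g")]] <- matrix(1, 1L, d)
    p[[paste0("dec", l, "_ln2_b")]] <- matrix(0, 1L, d)
    p[[paste0("dec", l, "_ffn_W1")]] <- init_mat(d, config$d_ffn)
    p[[paste0("dec", l, "_ffn_b1")]] <- matrix(0, 1L, config$d_ffn)
    p[[paste0("dec", l, "_ffn_W2")]] <- init_mat(config$d_ffn, d)
    p[[paste0("dec", l, "_ffn_b2")]] <- matrix(0, 1L, d)
    p[[paste0("dec", l, "_ln3_g")]] <- matrix(1, 1L, d)
    p[[paste0("dec", l, "_ln3_b")]] <- matrix(0, 1L, d)
  }
  p
}

# Causal (lower-triangular) masked multi-head attention on plain matrices.
masked_mhsa_plain <- function(X, Wq, Wk, Wv, Wo, n_heads) {
  d <- ncol(X); dk <- d %/% n_heads; m <- nrow(X)
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  mask <- matrix(-Inf, m, m); mask[lower.tri(mask, diag = TRUE)] <- 0
  out <- matrix(0, m, d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    s <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk) + mask
    out[, idx] <- softmax_rows(s) %*% V[, idx, drop = FALSE]
  }
  out %*% Wo
}

# Cross multi-head attention (queries from decoder states, keys/values from
# the memory).
cross_mhsa_plain <- function(X, M, Wq, Wk, Wv, Wo, n_heads) {
  d <- ncol(X); dk <- d %/% n_heads
  Q <- X %*% Wq; K <- M %*% Wk; V <- M %*% Wv
  out <- matrix(0, nrow(X), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    att <- scaled_dot_attention(Q[, idx, drop = FALSE], K[, idx, drop = FALSE],
                                V[, idx, drop = FALSE], d_key = dk)
    out[, idx] <- att$attended
  }
  out %*% Wo
}

# Full teacher-forced decoder forward: states for positions
# [start, tokens...], (m+1) x d.
dec_forward <- function(params, config, memory, tokens) {
  d <- config$d_model
  emb <- rbind(params$start_emb,
               if (length(tokens)) params$tok_E[tokens, , drop = FALSE])
  X <- emb + positional_encoding(nrow(emb), d,
                                 if (config$positional_mode == "sinusoidal") "interleave" else "sine_only")
  for (l in seq_len(config$n_decoder_layers)) {
    g <- function(nm) params[[paste0("dec", l, "_", nm)]]
    a <- masked_mhsa_plain(X, g("sWq"), g("sWk"), g("sWv"), g("sWo"), config$n_heads)
    X <- layer_norm_rows(X + a, g("ln1_g"), g("ln1_b"))
    cawt <- cross_mhsa_plain(X, memory, g("cWq"), g("cWk"), g("cWv"), g("cWo"),
                             config$n_heads)
    X <- layer_norm_rows(X + cawt, g("ln2_g"), g("ln2_b"))
    f <- sweep(pmax(sweep(X %*% g("ffn_W1"), 2L, g("ffn_b1"), `+`), 0) %*% g("ffn_W2"),
               2L, g("ffn_b2"), `+`)
    X <- layer_norm_rows(X + f, g("ln3_g"), g("ln3_b"))
  }
  X
}

#' Initialize a decoder state
#'
#' @param params Parameter list containing a decoder block (see
#'   [init_alht_params()] with `head_mode = "token_sequence"`).
#' @param config A [model_config()].
#' @param memory N x d aggregated memory the decoder cross-attends to.
#' @return A `decoder_state` with an empty prefix (the start token).
#' @export
decoder_init <- function(params, config, memory) {
  structure(list(params = params, config = config, memory = as.matrix(memory),
                 tokens = integer()),
            class = "decoder_state")
}

#' One autoregressive decoding step
#'
#' Computes `P(y_i | y_<i, memory) = softmax(W_out L_i)` for the current
#' prefix; the distribution sums to 1.
#'
#' @param state A `decoder_state`.
#' @return Named numeric vector of next-token probabilities over the vocab.
#' @export
decode_step <- function(state) {
  X <- dec_forward(state$params, state$config, state$memory, state$tokens)
  logits <- X[nrow(X), , drop = FALSE] %*% state$params$out_W + state$params$out_b
  p <- as.numeric(softmax_rows(logits))
  names(p) <- state$config$vocab
  p
}

#' Append a token to a decoder state
#'
#' @param state A `decoder_state`.
#' @param token 1-based vocabulary index.
#' @return Updated state.
#' @export
decoder_append <- function(state, token) {
  state$tokens <- c(state$tokens, as.integer(token))
  state
}

# -1 / 0 / 1 lexicographic comparison of integer sequences.
seq_compare <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0) {
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(-1L)
      if (a[i] > b[i]) return(1L)
    }
  }
  sign(length(a) - length(b))
}

#' Beam search decoding
#'
#' Expands `width` hypotheses per step for `max_len` steps and returns the
#' sequence maximizing the product of step probabilities. Ties (in total
#' log-probability) break toward the lexicographically smaller token
#' sequence, so decoding is fully deterministic. With `width = 1` this is
#' greedy decoding; with `width >= |vocab|^max_len` it is exhaustive.
#'
#' @param params,config,memory As in [decoder_init()].
#' @param width Beam width (>= 1).
#' @param max_len Number of decoding steps (fixed horizon).
#' @return List with `tokens` (1-based indices), `labels` (vocab strings),
#'   and `logprob`.
#' @export
beam_search <- function(params, config, memory, width, max_len) {
  if (width < 1) stop("beam width must be at least 1")
  V <- length(config$vocab)
  hyps <- list(list(tokens = integer(), logp = 0))
  for (step in seq_len(max_len)) {
    cand <- list()
    for (h in hyps) {
      st <- decoder_init(params, config, memory)
      st$tokens <- h$tokens
      p <- decode_step(st)
      for (v in seq_len(V)) {
        cand[[length(cand) + 1L]] <- list(tokens = c(h$tokens, v),
                                          logp = h$logp + log(p[v]))
      }
    }
    ord <- order(-vapply(cand, `[[`, 0, "logp"))
    # stable tie resolution: among equal log-probs keep lexicographic order
    cand <- cand[ord]
    if (length(cand) > 1) {
      for (i in seq_len(length(cand) - 1L)) {
        for (j in seq(i + 1L, length(cand))) {
          if (abs(cand[[i]]$logp - cand[[j]]$logp) < 1e-12 &&
              seq_compare(cand[[j]]$tokens, cand[[i]]$tokens) < 0) {
            tmp <- cand[[i]]; cand[[i]] <- cand[[j]]; cand[[j]] <- tmp
          }
        }
      }
    }
    hyps <- cand[seq_len(min(width, length(cand)))]
  }
  best <- hyps[[1]]
  list(tokens = best$tokens, labels = config$vocab[best$tokens],
       logprob = best$logp)
}
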