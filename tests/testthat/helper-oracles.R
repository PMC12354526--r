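# Independent oracles used to freeze expected values. These deliberately use
# different computational routes than the implementation they check.

# Welch power spectral density: averaged Hann-windowed periodograms over
# non-overlapping segments. Returns band power for one channel.
welch_band_power <- function(x, fs, band, seg_len = 512L) {
  K <- floor(length(x) / seg_len)
  stopifnot(K >= 1)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / seg_len)
  f <- (0:(seg_len - 1)) * fs / seg_len
  sel <- f >= band[1] & f <= band[2]
  p <- 0
  for (k in seq_len(K)) {
    seg <- x[((k - 1) * seg_len + 1):(k * seg_len)] * w
    p <- p + sum(Mod(stats::fft(seg))[sel]^2)
  }
  p / K
}

# Mean band power of a recording across channels.
rec_band_power <- function(recording, band) {
  mean(apply(recording$signal, 1L, welch_band_power,
             fs = recording$sampling_rate, band = band))
}

# O(n^2) pairwise AUC with explicit half-credit for ties.
auc_pairwise <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Direct scaled-dot-product attention, written independently (explicit loops
# over rows).
attention_oracle <- function(Q, K, V, d_key) {
  S <- matrix(0, nrow(Q), nrow(K))
  for (i in seq_len(nrow(Q))) for (j in seq_len(nrow(K))) {
    S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_key)
  }
  W <- t(apply(S, 1L, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  if (nrow(S) == 1L) W <- matrix(W, 1L)
  list(weights = W, attended = W %*% V)
}

# Naive sliding-window 1-D convolution (zero padded), one column at a time.
conv_oracle <- function(x, kernel) {
  half <- (length(kernel) - 1) / 2
  out <- x * 0
  for (cc in seq_len(ncol(x))) {
    for (t in seq_len(nrow(x))) {
      acc <- 0
      for (j in seq_along(kernel)) {
        src <- t + j - 1 - half
        if (src >= 1 && src <= nrow(x)) acc <- acc + kernel[j] * x[src, cc]
      }
      out[t, cc] <- acc
    }
  }
  out
}

# Brute-force best fixed-length token sequence by enumerating every sequence
# and teacher-forcing the decoder's step distributions.
beam_bruteforce <- function(params, config, memory, max_len) {
  V <- length(config$vocab)
  grid <- expand.grid(rep(list(seq_len(V)), max_len))
  best <- NULL; best_lp <- -Inf
  for (r in seq_len(nrow(grid))) {
    toks <- as.integer(grid[r, ])
    st <- decoder_init(params, config, memory)
    lp <- 0
    for (i in seq_len(max_len)) {
      p <- decode_step(st)
      lp <- lp + log(p[toks[i]])
      st <- decoder_append(st, toks[i])
    }
    if (lp > best_lp + 1e-12 ||
        (abs(lp - best_lp) <= 1e-12 && !is.null(best) &&
         eegrisk:::seq_compare(toks, best) < 0)) {
      best_lp <- lp; best <- toks
    }
  }
  list(tokens = best, logprob = best_lp)
}

# Central finite-difference gradient of a scalar function of a parameter
# list, at a sampled set of entries per parameter.
fd_grad_entries <- function(lossfun, params, entries_per_param = 2L, h = 1e-5) {
  out <- list()
  for (nm in names(params)) {
    ks <- sample(length(params[[nm]]), min(entries_per_param, length(params[[nm]])))
    vals <- vapply(ks, function(k) {
      p2 <- params
      p2[[nm]][k] <- p2[[nm]][k] + h
      fp <- lossfun(p2)
      p2[[nm]][k] <- p2[[nm]][k] - 2 * h
      fm <- lossfun(p2)
      (fp - fm) / (2 * h)
    }, 0)
    out[[nm]] <- list(idx = ks, fd = vals)
  }
  out
}

# Small random SPD matrix.
random_spd <- function(d) {
  A <- matrix(rnorm(d * d), d)
  A %*% t(A) + diag(d) * 0.1
}
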