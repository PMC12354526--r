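# Signal preprocessing pipeline.
#
# Stage order is fixed: band-pass filter -> (artifact hook) -> per-channel
# standardization -> fixed-length overlapping windows -> CSP spatial
# filtering (fit on training windows only) -> STFT log-spectrograms ->
# train-time masking/mixup augmentation. `preprocess_cohort()` runs the whole
# chain and records the executed stage sequence in a manifest.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so the
#' passband is preserved with zero phase distortion.
#'
#' @param recording A `labeled_recording`.
#' @param low,high Band edges in Hz (defaults 0.5 and 45).
#' @return The recording with each channel filtered; other fields unchanged.
#' @export
bandpass_filter <- function(recording, low = 0.5, high = 45) {
  fs <- recording$sampling_rate
  if (!(low > 0 && low < high)) stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  out <- recording
  out$signal <- t(apply(recording$signal, 1L, function(ch) signal::filtfilt(bf, ch)))
  out
}

#' Artifact-removal hook
#'
#' Identity pass-through kept so the pipeline's stage sequence has an explicit
#' artifact-cleaning slot. Synthetic recordings contain no ocular or muscular
#' artifacts, so no decomposition is performed; a notice is logged once per
#' call via `message()` unless `quiet = TRUE`.
#'
#' @param recording A `labeled_recording`.
#' @param quiet Suppress the notice.
#' @return The recording, unchanged.
#' @export
ica_clean <- function(recording, quiet = TRUE) {
  if (!quiet) message("artifact hook: identity (no artifact model configured)")
  recording
}

#' Standardize each channel to zero mean and unit variance
#'
#' Uses the population standard deviation (denominator n). Constant channels
#' are an error because they cannot be scaled to unit variance.
#'
#' @param signal Channels x samples numeric matrix.
#' @return Matrix of the same shape with per-channel mean 0 and variance 1.
#' @export
standardize_channels <- function(signal) {
  signal <- as.matrix(signal)
  n <- ncol(signal)
  mu <- rowMeans(signal)
  v <- rowMeans(signal^2) - mu^2
  bad <- which(v <= .Machine$double.eps * 100)
  if (length(bad) > 0) {
    stop(sprintf("channel(s) %s are constant and cannot be standardized",
                 paste(bad, collapse = ", ")))
  }
  (signal - mu) / sqrt(v)
}

#' Segment a recording into fixed-length overlapping windows
#'
#' Windows start at `k * window * (1 - overlap)` seconds for k = 0, 1, ...;
#' the trailing incomplete window is dropped. Each window inherits the
#' recording's label, context, and subject id.
#'
#' @param recording A `labeled_recording`.
#' @param window Window length in seconds (default 60).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return List of window objects (`signal`, `sampling_rate`, `label`,
#'   `context`, `subject_id`, `start`); empty (with a warning) if the
#'   recording is shorter than one window.
#' @export
segment_windows <- function(recording, window = 60, overlap = 0.5) {
  stopifnot(overlap >= 0, overlap < 1)
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  wlen <- round(window * fs)
  step <- round(window * (1 - overlap) * fs)
  if (n < wlen) {
    warning("recording shorter than one window; returning no windows")
    return(list())
  }
  starts <- seq(1L, n - wlen + 1L, by = step)
  lapply(starts, function(s) {
    list(signal = recording$signal[, s:(s + wlen - 1L), drop = FALSE],
         sampling_rate = fs, label = recording$label,
         context = recording$context, subject_id = recording$subject_id,
         start = (s - 1L) / fs)
  })
}

#' Fit common spatial pattern (CSP) filters
#'
#' Estimates trace-normalized spatial covariances per class (with a small
#' shrinkage ridge for numerical stability), whitens their sum, and
#' eigendecomposes the whitened class-1 covariance. The resulting filters w
#' are generalized eigenvectors of (Sigma1, Sigma1 + Sigma2) normalized so
#' that w' (Sigma1 + Sigma2) w = 1; eigenvalues lie in (0, 1) and measure the
#' fraction of (whitened) variance attributable to class 1. The bank keeps
#' the `m` filters from each spectral end, ordered by descending eigenvalue.
#'
#' @param windows List of labeled windows (both classes must be present; each
#'   window needs at least as many samples as channels).
#' @param m Filters kept per spectral end (default 3).
#' @param shrinkage Ridge added to each class covariance as
#'   `shrinkage * trace/dim * I`.
#' @return A `spatial_filter_bank`: `filters` (channels x 2m), `eigenvalues`,
#'   `fitted_on` descriptor.
#' @export
csp_fit <- function(windows, m = 3L, shrinkage = 1e-6) {
  labels <- vapply(windows, function(w) w$label, 0L)
  if (length(unique(labels)) < 2L) stop("CSP requires windows from both classes")
  covs <- lapply(windows, function(w) {
    X <- w$signal
    if (ncol(X) < nrow(X)) stop("each window needs at least `channels` samples")
    X <- X - rowMeans(X)
    C <- X %*% t(X)
    C / sum(diag(C))
  })
  avg_cov <- function(idx) Reduce(`+`, covs[idx]) / length(idx)
  d <- nrow(covs[[1]])
  reg <- function(C) C + shrinkage * (sum(diag(C)) / d) * diag(d)
  S1 <- reg(avg_cov(which(labels == 1L)))
  S2 <- reg(avg_cov(which(labels == 0L)))
  sol <- csp_eigen(S1, S2)
  W_full <- sol$filters
  es <- list(values = sol$eigenvalues)
  m <- min(as.integer(m), floor(d / 2))
  keep <- c(seq_len(m), seq(d - m + 1L, d))
  structure(list(filters = W_full[, keep, drop = FALSE],
                 eigenvalues = es$values[keep],
                 fitted_on = sprintf("%d windows (%d high-risk, %d low-risk)",
                                     length(windows), sum(labels == 1L),
                                     sum(labels == 0L))),
            class = "spatial_filter_bank")
}

#' Generalized eigendecomposition for a CSP covariance pair
#'
#' Solves the pair (Sigma1, Sigma1 + Sigma2) by whitening the composite
#' covariance and eigendecomposing the whitened class-1 covariance. Filters
#' satisfy `w' (Sigma1 + Sigma2) w = 1`; eigenvalues lie in (0, 1) and are
#' returned in descending order.
#'
#' @param S1,S2 Symmetric positive-definite class covariance matrices.
#' @return List with `filters` (columns) and `eigenvalues`.
#' @export
csp_eigen <- function(S1, S2) {
  Sc <- S1 + S2
  ec <- eigen(Sc, symmetric = TRUE)
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)        # whitener: P Sc P' = I
  es <- eigen(P %*% S1 %*% t(P), symmetric = TRUE)         # eigenvalues in (0,1)
  list(filters = t(P) %*% es$vectors, eigenvalues = es$values)
}

#' Apply a CSP filter bank to a window
#'
#' @param window A window object (or any list with a channels x samples
#'   `signal`).
#' @param bank A `spatial_filter_bank` from [csp_fit()].
#' @return The window with `signal` replaced by the `n_filters` x samples
#'   spatially filtered signal `t(filters) %*% signal`.
#' @export
csp_apply <- function(window, bank) {
  if (nrow(window$signal) != nrow(bank$filters)) {
    stop("channel count of window does not match the filter bank")
  }
  out <- window
  out$signal <- t(bank$filters) %*% window$signal
  out
}

#' Short-time Fourier log-magnitude spectrogram
#'
#' Hann-windowed one-sided STFT per spatial channel. Frames of `stft_window`
#' seconds are advanced by `hop * stft_window`; magnitudes are scaled by
#' `1/sqrt(nfft)`, floored at `1e-10`, and (by default) log-transformed.
#' Frames are stacked into a time-major matrix with
#' `d = channels * (nfft/2 + 1)` columns, channel blocks in order.
#'
#' @param window A window object with a channels x samples `signal`.
#' @param stft_window Frame length in seconds (default 1).
#' @param hop Fractional hop in (0, 1] (default 0.5).
#' @param log Apply the log transform (set `FALSE` for linear magnitudes,
#'   e.g. for energy checks).
#' @return A `feature_matrix`: list with `values` (T x d), `frame_rate`,
#'   `axis_meta` (`freqs` per bin, `channels`, `bins_per_channel`), and the
#'   window's `label`, `context`, `subject_id`.
#' @export
stft_spectrogram <- function(window, stft_window = 1.0, hop = 0.5, log = TRUE) {
  if (hop <= 0) stop("hop must be positive")
  fs <- window$sampling_rate
  nfft <- round(stft_window * fs)
  nsamp <- ncol(window$signal)
  if (nfft > nsamp) stop("stft_window longer than the window itself")
  step <- max(1L, round(hop * nfft))
  starts <- seq(1L, nsamp - nfft + 1L, by = step)
  win <- hann_window(nfft)
  nbins <- nfft %/% 2L + 1L
  nch <- nrow(window$signal)
  vals <- matrix(0, length(starts), nch * nbins)
  for (ch in seq_len(nch)) {
    for (fi in seq_along(starts)) {
      seg <- window$signal[ch, starts[fi]:(starts[fi] + nfft - 1L)] * win
      mag <- Mod(stats::fft(seg))[seq_len(nbins)] / sqrt(nfft)
      vals[fi, ((ch - 1L) * nbins + 1L):(ch * nbins)] <- pmax(mag, 1e-10)
    }
  }
  if (log) vals <- base::log(vals)
  structure(list(values = vals, frame_rate = fs / step,
                 axis_meta = list(freqs = (seq_len(nbins) - 1L) * fs / nfft,
                                  channels = nch, bins_per_channel = nbins),
                 label = window$label, context = window$context,
                 subject_id = window$subject_id),
            class = "feature_matrix")
}

# Periodic Hann window (matches the usual STFT analysis window).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Time / frequency masking augmentation
#'
#' Sets `n_masks` contiguous spans along the chosen axis to the per-feature
#' column mean (which keeps batch statistics stable); all other entries are
#' untouched. Span widths are drawn uniformly from 0..`max_width` and
#' placements uniformly along the axis.
#'
#' @param features A `feature_matrix` (or plain matrix).
#' @param axis `"time"` (mask rows) or `"frequency"` (mask feature columns).
#' @param max_width Maximum span width (0 disables masking).
#' @param n_masks Number of spans.
#' @return Object of the same type with masked values.
#' @export
apply_masking <- function(features, axis = c("time", "frequency"),
                          max_width = 4L, n_masks = 2L) {
  axis <- match.arg(axis)
  is_fm <- inherits(features, "feature_matrix")
  X <- if (is_fm) features$values else as.matrix(features)
  len <- if (axis == "time") nrow(X) else ncol(X)
  if (max_width >= len) stop("max_width must be smaller than the axis length")
  fill <- colMeans(X)
  for (k in seq_len(n_masks)) {
    w <- sample.int(max_width + 1L, 1L) - 1L
    if (w == 0L) next
    s <- sample.int(len - w + 1L, 1L)
    idx <- s:(s + w - 1L)
    if (axis == "time") {
      X[idx, ] <- matrix(fill, length(idx), ncol(X), byrow = TRUE)
    } else {
      X[, idx] <- matrix(fill[idx], nrow(X), length(idx), byrow = TRUE)
    }
  }
  if (is_fm) { features$values <- X; features } else X
}

#' Mixup augmentation
#'
#' Convex combination of two feature matrices and their (one-hot or soft)
#' labels: `lam * a + (1 - lam) * b`.
#'
#' @param features_a,features_b Matrices of identical shape.
#' @param label_a,label_b Numeric label vectors of identical length.
#' @param lam Mixing weight in `[0, 1]`.
#' @return List with `features` and soft `label`.
#' @export
mixup <- function(features_a, features_b, label_a, label_b, lam) {
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  stopifnot(all(dim(as.matrix(features_a)) == dim(as.matrix(features_b))),
            length(label_a) == length(label_b))
  list(features = lam * features_a + (1 - lam) * features_b,
       label = lam * label_a + (1 - lam) * label_b)
}

#' Run the full preprocessing pipeline on a cohort
#'
#' Applies, in order: band-pass filter, artifact hook, per-channel
#' standardization, windowing, CSP (fit on the training subjects' windows
#' only), STFT, and feature-column standardization with statistics computed
#' on the training split and frozen for the rest. No masking or mixup is
#' applied here; those are train-time augmentations owned by the trainer.
#'
#' @param cohort List of `labeled_recording`s.
#' @param train_subjects Character vector of subject ids forming the training
#'   split (CSP and feature statistics are fit on these only).
#' @param low,high Band-pass edges in Hz.
#' @param window,overlap Windowing parameters in seconds / fraction.
#' @param csp_m CSP filters kept per spectral end.
#' @param stft_window,hop STFT parameters.
#' @return List with `features` (list of `feature_matrix`), `labels`,
#'   `subject_ids`, `contexts` (list), `bank` (the CSP bank), `feature_stats`
#'   (frozen column means/sds), and `manifest` (ordered stage log with
#'   parameters).
#' @export
preprocess_cohort <- function(cohort, train_subjects, low = 0.5, high = 45,
                              window = 60, overlap = 0.5, csp_m = 3L,
                              stft_window = 1.0, hop = 0.5) {
  stages <- list()
  log_stage <- function(name, ...) {
    stages[[length(stages) + 1L]] <<- c(list(stage = name), list(...))
  }
  rec <- lapply(cohort, bandpass_filter, low = low, high = high)
  log_stage("bandpass_filter", low = low, high = high, order = 4)
  rec <- lapply(rec, ica_clean)
  log_stage("artifact_hook", method = "identity")
  rec <- lapply(rec, function(r) { r$signal <- standardize_channels(r$signal); r })
  log_stage("standardize_channels", scope = "per-recording")
  wins <- unlist(lapply(rec, segment_windows, window = window, overlap = overlap),
                 recursive = FALSE)
  log_stage("segment_windows", window = window, overlap = overlap)
  subj <- vapply(wins, function(w) w$subject_id, "")
  train_idx <- which(subj %in% train_subjects)
  if (length(train_idx) == 0L) stop("no training windows: check train_subjects")
  bank <- csp_fit(wins[train_idx], m = csp_m)
  wins <- lapply(wins, csp_apply, bank = bank)
  log_stage("csp", m = csp_m, fitted_on = bank$fitted_on)
  feats <- lapply(wins, stft_spectrogram, stft_window = stft_window, hop = hop)
  log_stage("stft_spectrogram", stft_window = stft_window, hop = hop)

  train_mat <- do.call(rbind, lapply(feats[train_idx], function(f) f$values))
  mu <- colMeans(train_mat)
  sdv <- sqrt(pmax(colMeans(train_mat^2) - mu^2, 1e-12))
  feats <- lapply(feats, function(f) {
    f$values <- sweep(sweep(f$values, 2L, mu, `-`), 2L, sdv, `/`)
    f
  })
  log_stage("feature_standardize", scope = "train-split statistics, frozen")

  list(features = feats,
       labels = vapply(feats, function(f) f$label, 0L),
       subject_ids = vapply(feats, function(f) f$subject_id, ""),
       contexts = lapply(feats, function(f) f$context),
       bank = bank,
       feature_stats = list(mean = mu, sd = sdv),
       manifest = list(stages = stages,
                       train_subjects = train_subjects,
                       augmentation = list(masking = FALSE, mixup = FALSE)))
}
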