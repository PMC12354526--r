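# Preprocessing: filtering, standardization, windowing, CSP, STFT, and the
# augmentations.

make_rec <- function(signal, fs = 128) {
  list(signal = signal, sampling_rate = fs, label = 0L, context = numeric(4),
       subject_id = "S01", stimulus_onsets = numeric())
}

test_that("bandpass removes DC, passes 10 Hz, and rejects 60 Hz", {
  fs <- 128
  tt <- (0:(fs * 4 - 1)) / fs
  dc <- make_rec(matrix(1, 1, fs * 30), fs)
  dc_out <- bandpass_filter(dc)$signal[1, (2 * fs):(28 * fs)]  # interior, past
  expect_lt(sqrt(mean(dc_out^2)), 0.01)                        # edge transients

  s10 <- make_rec(matrix(sin(2 * pi * 10 * tt), 1), fs)
  r10 <- sqrt(mean(bandpass_filter(s10)$signal^2)) / sqrt(mean(s10$signal^2))
  expect_gte(r10, 0.9)

  fs2 <- 200
  tt2 <- (0:(fs2 * 4 - 1)) / fs2
  s60 <- make_rec(matrix(sin(2 * pi * 60 * tt2), 1), fs2)
  r60 <- sqrt(mean(bandpass_filter(s60)$signal^2)) / sqrt(mean(s60$signal^2))
  expect_lte(r60, 0.1)

  expect_error(bandpass_filter(s10, high = 70), "Nyquist")
})

test_that("standardization yields exact zero mean / unit population variance", {
  out <- standardize_channels(matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(out), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  set.seed(4)
  x <- matrix(rnorm(3 * 100, mean = 5, sd = 2), 3)
  z <- standardize_channels(x)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(rowMeans(z^2) - 1)), 1e-9)
  expect_equal(standardize_channels(z), z, tolerance = 1e-9)  # idempotent
  expect_error(standardize_channels(rbind(x[1, ], rep(2, 100))), "constant")
})

test_that("windowing enumerates the documented start grid", {
  fs <- 64
  rec <- make_rec(matrix(rnorm(2 * 180 * fs), 2), fs)
  w <- segment_windows(rec, 60, 0.5)
  expect_length(w, 5)
  expect_equal(vapply(w, `[[`, 0, "start"), c(0, 30, 60, 90, 120))
  expect_length(segment_windows(make_rec(matrix(rnorm(60 * fs), 1), fs), 60, 0.5), 1)
  expect_length(segment_windows(rec, 60, 0), 3)
  expect_warning(out <- segment_windows(make_rec(matrix(rnorm(10 * fs), 1), fs), 60),
                 "shorter")
  expect_length(out, 0)
})

test_that("windows inherit the recording label", {
  fs <- 64
  rec <- make_rec(matrix(rnorm(90 * fs), 1), fs)
  rec$label <- 1L
  expect_true(all(vapply(segment_windows(rec, 30), `[[`, 0L, "label") == 1L))
})

test_that("CSP recovers a planted discriminative axis on the 2x2 toy", {
  set.seed(10)
  mk <- function(sd1, sd2, label) {
    as_window(rbind(rnorm(500, sd = sd1), rnorm(500, sd = sd2)), label = label)
  }
  wins <- c(lapply(1:20, function(i) mk(2, 1, 1L)),
            lapply(1:20, function(i) mk(1, 2, 0L)))
  bank <- csp_fit(wins, m = 1L)
  lead <- bank$filters[, 1] / sqrt(sum(bank$filters[, 1]^2))
  expect_gte(abs(lead[1]), 0.99)   # |cosine| with axis 1
  expect_true(all(diff(bank$eigenvalues) <= 1e-12))  # descending order
  # normalization: w' (S1+S2) w = 1 for every kept filter
  covs <- lapply(wins, function(w) {
    X <- w$signal - rowMeans(w$signal); C <- X %*% t(X); C / sum(diag(C))
  })
  labs <- vapply(wins, `[[`, 0L, "label")
  S1 <- Reduce(`+`, covs[labs == 1]) / sum(labs == 1)
  S2 <- Reduce(`+`, covs[labs == 0]) / sum(labs == 0)
  for (j in seq_len(ncol(bank$filters))) {
    w <- bank$filters[, j]
    expect_equal(as.numeric(t(w) %*% (S1 + S2) %*% w), 1, tolerance = 1e-4)
  }
  expect_error(csp_fit(wins[1:20]), "both classes")
})

test_that("identical class covariances give eigenvalues of one half", {
  sol <- csp_eigen(diag(3), diag(3))
  expect_equal(sol$eigenvalues, rep(0.5, 3), tolerance = 1e-12)
})

test_that("csp_eigen matches a dense generalized-eigen solve on random SPD pairs", {
  set.seed(77)
  for (i in 1:50) {
    d <- sample(3:6, 1)
    S1 <- random_spd(d); S2 <- random_spd(d)
    sol <- csp_eigen(S1, S2)
    # independent route: non-symmetric standard eigenproblem of (S1+S2)^-1 S1
    ref <- sort(Re(eigen(solve(S1 + S2) %*% S1)$values), decreasing = TRUE)
    expect_equal(sol$eigenvalues, ref, tolerance = 1e-8)
    # filters diagonalize both scaled covariances
    expect_equal(t(sol$filters) %*% (S1 + S2) %*% sol$filters, diag(d),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("csp_apply is the stated matrix product", {
  w <- as_window(matrix(rnorm(2 * 100), 2))
  id_bank <- structure(list(filters = diag(2), eigenvalues = c(0.5, 0.5)),
                       class = "spatial_filter_bank")
  expect_identical(csp_apply(w, id_bank)$signal, w$signal)
  pick <- structure(list(filters = matrix(c(1, 0), 2, 1), eigenvalues = 0.6),
                    class = "spatial_filter_bank")
  expect_equal(csp_apply(w, pick)$signal, w$signal[1, , drop = FALSE],
               ignore_attr = TRUE)
  set.seed(2)
  B <- structure(list(filters = matrix(rnorm(6), 2, 3), eigenvalues = 1:3),
                 class = "spatial_filter_bank")
  expect_equal(csp_apply(w, B)$signal, t(B$filters) %*% w$signal)
  expect_error(csp_apply(as_window(matrix(0, 3, 10)), pick), "channel count")
})

test_that("spectrogram localizes a pure tone in the right frequency bin", {
  fs <- 128
  tt <- (0:(fs * 8 - 1)) / fs
  w <- as_window(matrix(sin(2 * pi * 10 * tt), 1), fs)
  fm <- stft_spectrogram(w, stft_window = 1, hop = 0.5)
  freqs <- fm$axis_meta$freqs
  peak_bins <- apply(fm$values, 1L, which.max)
  expect_true(all(freqs[peak_bins] == 10))
  expect_equal(fm$frame_rate, 2)
})

test_that("all-zero signal gives the log floor everywhere", {
  fm <- stft_spectrogram(as_window(matrix(0, 1, 256), 128))
  expect_true(all(fm$values == log(1e-10)))
})

test_that("one frame of the linear spectrogram satisfies Parseval", {
  fs <- 64
  set.seed(12)
  x <- rnorm(fs * 2)
  w <- as_window(matrix(x, 1), fs)
  fm <- stft_spectrogram(w, stft_window = 1, hop = 1, log = FALSE)
  win <- eegrisk:::hann_window(fs)
  nb <- fm$axis_meta$bins_per_channel
  # one-sided reconstruction: double the interior bins (DC and Nyquist once)
  mults <- c(1, rep(2, nb - 2), 1)
  frame_energy <- sum(mults * fm$values[1, 1:nb]^2)
  expect_equal(frame_energy, sum((x[1:fs] * win)^2), tolerance = 1e-6)
})

test_that("masking fills spans with column means and leaves the rest intact", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20)
  expect_identical(apply_masking(X, "time", max_width = 0L), X)
  set.seed(99)
  M <- apply_masking(X, "time", max_width = 5L, n_masks = 2L)
  changed <- which(rowSums(M != X) > 0)
  if (length(changed)) {
    for (r in changed) expect_equal(M[r, ], colMeans(X), ignore_attr = TRUE)
  }
  untouched <- setdiff(seq_len(20), changed)
  expect_identical(M[untouched, ], X[untouched, ])
  set.seed(99)
  expect_identical(apply_masking(X, "time", max_width = 5L, n_masks = 2L), M)
  set.seed(1)
  Mf <- apply_masking(X, "frequency", max_width = 3L, n_masks = 1L)
  chc <- which(colSums(Mf != X) > 0)
  for (cc in chc) expect_true(all(Mf[, cc] == mean(X[, cc])))
})

test_that("mixup interpolates features and labels convexly", {
  a <- matrix(1, 2, 2); b <- matrix(3, 2, 2)
  expect_identical(mixup(a, b, c(1, 0), c(0, 1), 1)$features, a)
  expect_identical(mixup(a, b, c(1, 0), c(0, 1), 0)$features, b)
  half <- mixup(a, b, c(1, 0), c(0, 1), 0.5)
  expect_equal(half$label, c(0.5, 0.5))
  expect_equal(half$features, matrix(2, 2, 2))
  expect_error(mixup(a, b, c(1, 0), c(0, 1), 1.5), "lam")
})

test_that("filtering commutes with windowing away from window edges", {
  fs <- 128
  set.seed(21)
  rec <- make_rec(matrix(rnorm(180 * fs), 1), fs)
  filtered_first <- segment_windows(bandpass_filter(rec), 60, 0.5)[[3]]$signal
  windowed_first <- bandpass_filter(segment_windows(rec, 60, 0.5)[[3]])$signal
  trim <- (2 * fs):(58 * fs)   # drop 2 s of edge frames on each side
  rel_rms <- sqrt(mean((filtered_first[, trim] - windowed_first[, trim])^2)) /
    sqrt(mean(filtered_first[, trim]^2))
  expect_lt(rel_rms, 1e-3)
})

test_that("pipeline manifest records the fixed stage order and no eval augmentation", {
  pp <- small_preprocessed()$pp
  stages <- vapply(pp$manifest$stages, `[[`, "", "stage")
  expect_equal(stages, c("bandpass_filter", "artifact_hook",
                         "standardize_channels", "segment_windows", "csp",
                         "stft_spectrogram", "feature_standardize"))
  expect_false(pp$manifest$augmentation$masking)
  expect_false(pp$manifest$augmentation$mixup)
  # training-split feature columns are standardized
  tr <- which(pp$subject_ids %in% pp$manifest$train_subjects)
  M <- do.call(rbind, lapply(pp$features[tr], `[[`, "values"))
  expect_lt(max(abs(colMeans(M))), 1e-6)
  expect_lt(max(abs(apply(M, 2, function(x) sqrt(mean(x^2) - mean(x)^2)) - 1)), 1e-3)
})

test_that("CSP-filtered variances are monotone in eigenvalue order", {
  pp <- small_preprocessed()  # bank fitted on the training windows
  cohort <- simulate_cohort(small_cohort_config())
  rec <- lapply(cohort, function(r) { r$signal <- standardize_channels(
    bandpass_filter(r)$signal); r })
  wins <- unlist(lapply(rec, segment_windows), recursive = FALSE)
  labs <- vapply(wins, `[[`, 0L, "label")
  filt <- lapply(wins, csp_apply, bank = pp$pp$bank)
  v1 <- rowMeans(vapply(filt[labs == 1], function(w) apply(w$signal, 1, var),
                        numeric(ncol(pp$pp$bank$filters))))
  # the share of class-1 variance should decrease along the filter order
  v0 <- rowMeans(vapply(filt[labs == 0], function(w) apply(w$signal, 1, var),
                        numeric(ncol(pp$pp$bank$filters))))
  ratio <- v1 / (v1 + v0)
  expect_true(all(diff(ratio) < 0.05))
  expect_gt(ratio[1], ratio[length(ratio)])
})
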