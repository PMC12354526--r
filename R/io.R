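# File interchange: EDF recordings, cohort round-trips, run manifests, and
# model checkpoints.
#
# EDF (European Data Format) is the interchange standard for biosignals; the
# reader/writer here covers the plain continuous-EDF subset used by the
# cohort generator (one data record per second, 16-bit samples). EDF is
# 16-bit quantized, so a lossless RDS container is also provided for
# internal round-trips.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording to an EDF file
#'
#' One data record per second; the sampling rate must therefore be a whole
#' number of samples per second, and the signal is truncated to whole
#' seconds. Physical scaling is per channel over the 16-bit digital range.
#'
#' @param recording A `labeled_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  sig <- recording$signal
  ns <- nrow(sig)
  n_rec <- floor(ncol(sig) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  sig <- sig[, seq_len(n_rec * fs), drop = FALSE]
  # round the physical range outward so no sample clips against the printed
  # (2-decimal) header fields
  pmin_ <- floor(apply(sig, 1L, min) * 100) / 100
  pmax_ <- ceiling(apply(sig, 1L, max) * 100) / 100
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8L),
                pad_field(recording$subject_id, 80L),
                pad_field("eegrisk synthetic cohort", 80L),
                pad_field("01.01.26", 8L), pad_field("00.00.00", 8L),
                pad_field(256L + ns * 256L, 8L),
                pad_field("", 44L),
                pad_field(n_rec, 8L), pad_field(1L, 8L), pad_field(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(seq_len(ns), function(i) pad_field(sprintf("EEG %02d", i), 16L), ""),
    rep(pad_field("synthetic", 80L), ns),
    rep(pad_field("uV", 8L), ns),
    vapply(pmin_, function(x) pad_field(sprintf("%.2f", x), 8L), ""),
    vapply(pmax_, function(x) pad_field(sprintf("%.2f", x), 8L), ""),
    rep(pad_field(dmin, 8L), ns),
    rep(pad_field(dmax, 8L), ns),
    rep(pad_field("BP 0.5-45Hz (generator band)", 80L), ns),
    rep(pad_field(fs, 8L), ns),
    rep(pad_field("", 32L), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  # header stores the printed physical range; quantize against it
  pr_min <- as.numeric(sprintf("%.2f", pmin_))
  pr_max <- as.numeric(sprintf("%.2f", pmax_))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      x <- sig[ch, ((r - 1L) * fs + 1L):(r * fs)]
      dig <- round((x - pr_min[ch]) / (pr_max[ch] - pr_min[ch]) * (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `signal` (channels x samples matrix in physical units),
#'   `sampling_rate`, `subject_id` (the patient-id header field), and
#'   `channel_labels`. Errors carry class `eegrisk_io_error` with distinct
#'   messages for malformed headers and mismatched sampling rates.
#' @export
read_edf <- function(path) {
  io_err <- function(msg) stop(structure(class = c("eegrisk_io_error", "error", "condition"),
                                         list(message = msg, call = NULL)))
  if (!file.exists(path)) io_err(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8L))
  if (version != "0") io_err("malformed EDF header: bad version field")
  patient <- trimws(rd(80L)); rd(80L); rd(8L); rd(8L)
  hdr_bytes <- suppressWarnings(as.integer(trimws(rd(8L))))
  rd(44L)
  n_rec <- suppressWarnings(as.integer(trimws(rd(8L))))
  dur <- suppressWarnings(as.numeric(trimws(rd(8L))))
  ns <- suppressWarnings(as.integer(trimws(rd(4L))))
  if (anyNA(c(hdr_bytes, n_rec, dur, ns)) || ns < 1) {
    io_err("malformed EDF header: unparseable size fields")
  }
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), ""))
  for (i in seq_len(ns)) rd(80L)              # transducer
  for (i in seq_len(ns)) rd(8L)               # physical dimension
  pmin_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  pmax_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  for (i in seq_len(ns)) rd(80L)              # prefiltering
  spr <- as.integer(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  for (i in seq_len(ns)) rd(32L)
  if (length(unique(spr)) != 1L) {
    io_err("sampling rate differs across channels; uniform-rate EDF expected")
  }
  fs <- spr[1] / dur
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[ch]) io_err("truncated EDF data section")
      phys <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax_[ch] - pmin_[ch]) + pmin_[ch]
      sig[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- phys
    }
  }
  list(signal = sig, sampling_rate = fs, subject_id = patient,
       channel_labels = labels)
}

#' Write a cohort to disk
#'
#' `format = "edf"` writes one EDF file per subject plus a `labels.csv`
#' sidecar (subject_id, label, context columns, stimulus onsets, seed);
#' `format = "rds"` writes a single lossless container file `cohort.rds`.
#'
#' @param cohort List of `labeled_recording`s.
#' @param dir Output directory (created if needed).
#' @param format `"edf"` or `"rds"`.
#' @param seed Seed recorded in the sidecar for provenance.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("edf", "rds"), seed = NA) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "rds") {
    saveRDS(cohort, file.path(dir, "cohort.rds"))
    return(invisible(dir))
  }
  rows <- lapply(cohort, function(r) {
    write_edf(r, file.path(dir, paste0(r$subject_id, ".edf")))
    ctx <- as.data.frame(t(r$context))
    names(ctx) <- paste0("context_", seq_along(r$context))
    cbind(data.frame(subject_id = r$subject_id, label = r$label,
                     sampling_rate = r$sampling_rate,
                     onsets = paste(r$stimulus_onsets, collapse = ";"),
                     seed = seed),
          ctx)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read one labeled recording back from a cohort directory
#'
#' @param dir Cohort directory written by [write_cohort()].
#' @param subject_id Subject to load.
#' @param format `"edf"` or `"rds"`.
#' @return A `labeled_recording`. Missing label rows and missing files raise
#'   `eegrisk_io_error`s (never a silent default label).
#' @export
read_recording <- function(dir, subject_id, format = c("edf", "rds")) {
  format <- match.arg(format)
  io_err <- function(msg) stop(structure(class = c("eegrisk_io_error", "error", "condition"),
                                         list(message = msg, call = NULL)))
  if (format == "rds") {
    cohort <- readRDS(file.path(dir, "cohort.rds"))
    hit <- Filter(function(r) r$subject_id == subject_id, cohort)
    if (length(hit) == 0) io_err(sprintf("no recording for subject %s", subject_id))
    return(hit[[1]])
  }
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) io_err("labels.csv sidecar is missing")
  labs <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  row <- labs[labs$subject_id == subject_id, , drop = FALSE]
  if (nrow(row) == 0) io_err(sprintf("no label row for subject %s", subject_id))
  edf <- read_edf(file.path(dir, paste0(subject_id, ".edf")))
  ctx_cols <- grep("^context_", names(row), value = TRUE)
  onsets <- if (nzchar(row$onsets[1])) as.numeric(strsplit(row$onsets[1], ";")[[1]]) else numeric()
  structure(list(signal = edf$signal, sampling_rate = edf$sampling_rate,
                 label = as.integer(row$label[1]),
                 context = as.numeric(row[1, ctx_cols]),
                 subject_id = subject_id, stimulus_onsets = onsets),
            class = "labeled_recording")
}

#' Write a run manifest
#'
#' Records the configuration snapshot, ordered stage sequence, seeds, and
#' input/output digests of a pipeline run as JSON.
#'
#' @param path Output JSON path.
#' @param config Configuration snapshot (any JSON-serializable list).
#' @param stages Ordered list of stage descriptors.
#' @param seeds Named seed list.
#' @param files Named character vector of involved files (digested with
#'   md5).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), stages = list(),
                           seeds = list(), files = character()) {
  digests <- if (length(files)) {
    vapply(files, function(f) if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_, "")
  } else character()
  manifest <- list(tool = "eegrisk",
                   version = as.character(utils::packageVersion("eegrisk")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config, stages = stages, seeds = seeds,
                   file_digests = as.list(digests))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Save / load a model checkpoint
#'
#' Single-file container holding the parameter list and the embedded model
#' configuration.
#'
#' @param params Parameter list.
#' @param config A [model_config()].
#' @param path Checkpoint path.
#' @return `path` invisibly (save); list with `params` and `config` (load).
#' @export
save_checkpoint <- function(params, config, path) {
  saveRDS(list(params = params, config = unclass(config)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  ck$config <- do.call(model_config, ck$config[setdiff(names(ck$config), "tiny_preset")])
  ck
}
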