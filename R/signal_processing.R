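#' Band-pass filter and decimate raw EMG
#'
#' Applies a 4th-order Butterworth band-pass (default 100–500 Hz) and then
#' decimates by simple stride to the target rate, mirroring the real-time
#' rig's front end (raw acquisition at 30 kSps, decoding at 1 kSps). The
#' 500 Hz cutoff keeps the decimated stream below the 1 kSps Nyquist limit,
#' so no extra anti-alias stage is needed. Zero-phase (forward-backward)
#' filtering is used for offline analysis; set `causal = TRUE` for the
#' streaming path.
#'
#' @param rec an [emg_recording].
#' @param band pass band in Hz.
#' @param target_rate output rate in samples/s (default 1000).
#' @param causal use a causal single-pass filter instead of zero-phase.
#' @return an [emg_recording] at `target_rate`, with labels and trial
#'   annotations carried over (sample indices rescaled).
#' @export
preprocess <- function(rec, band = c(100, 500), target_rate = 1000,
                       causal = FALSE) {
  fs <- rec$sample_rate
  if (fs < target_rate) stop("sample rate below ", target_rate, " sps", call. = FALSE)
  check_that(fs %% target_rate == 0, "sample_rate must be divisible by target_rate")
  ratio <- fs %/% target_rate
  hi <- min(band[2], fs / 2 * 0.999)
  flt <- if (band[1] <= 0) {
    signal::butter(4, hi / (fs / 2), type = "low")
  } else if (hi >= fs / 2 * 0.999 && fs <= 2 * band[2]) {
    signal::butter(4, band[1] / (fs / 2), type = "high")
  } else {
    signal::butter(4, c(band[1], hi) / (fs / 2), type = "pass")
  }
  apply_filter <- function(x) {
    if (causal) as.numeric(signal::filter(flt, x)) else signal::filtfilt(flt, x)
  }
  filtered <- t(apply(rec$samples, 1, apply_filter))
  idx <- seq(1, ncol(filtered), by = ratio)
  out <- filtered[, idx, drop = FALSE]
  rownames(out) <- rownames(rec$samples)
  labels <- if (!is.null(rec$labels)) rec$labels[idx]
  trials <- rec$trials
  if (!is.null(trials)) {
    for (col in c("start", "end", "active_start", "active_end")) {
      if (col %in% names(trials)) trials[[col]] <- trials[[col]] %/% ratio
    }
  }
  emg_recording(out, target_rate, labels, trials, rec$channel_specs)
}

#' Mean-absolute-value feature sequence
#'
#' Extracts the MAV time-domain feature in non-overlapping bins (default
#' 50 ms): each bin value is the mean of the rectified samples falling in
#' the bin. A trailing partial bin is discarded, never padded.
#'
#' @param rec an [emg_recording] (typically at 1 kSps).
#' @param bin_width bin width in ms.
#' @return a `feature_sequence`: list with `mav` (channels x bins matrix,
#'   uV), `bin_width` (ms), `origin` (sample index of the first bin) and
#'   `labels` (per-bin majority movement label, if the recording is
#'   labelled).
#' @export
compute_mav <- function(rec, bin_width = 50) {
  fs <- rec$sample_rate
  spb <- round(bin_width / 1000 * fs)
  check_that(spb >= 1, "bin narrower than one sample")
  n_bins <- ncol(rec$samples) %/% spb
  check_that(n_bins >= 1, "recording shorter than one bin")
  n_use <- n_bins * spb
  grp <- rep(seq_len(n_bins), each = spb)
  mav <- t(apply(abs(rec$samples[, seq_len(n_use), drop = FALSE]), 1,
                 function(x) tapply(x, grp, mean)))
  dimnames(mav) <- list(rownames(rec$samples), NULL)
  labels <- NULL
  if (!is.null(rec$labels)) {
    labels <- vapply(seq_len(n_bins), function(b) {
      lb <- rec$labels[((b - 1) * spb + 1):(b * spb)]
      names(sort(table(lb), decreasing = TRUE))[1]
    }, character(1))
  }
  structure(list(mav = mav, bin_width = bin_width, origin = 0L,
                 labels = labels, sample_rate = fs, samples_per_bin = spb),
            class = "feature_sequence")
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat("MAV feature sequence: ", nrow(x$mav), " channels x ", ncol(x$mav),
      " bins @ ", x$bin_width, " ms\n", sep = "")
  invisible(x)
}

# map a 0-based sample interval [start, end) to the 1-based feature bins
# fully contained in it
bins_in_interval <- function(features, start, end) {
  spb <- features$samples_per_bin
  first <- floor(start / spb) + 1
  if ((first - 1) * spb < start) first <- first + 1
  last <- min(floor(end / spb), ncol(features$mav))
  if (first > last) return(integer(0))
  seq.int(first, last)
}

#' Root-mean-square amplitude
#'
#' @param x numeric vector, or a channels x time matrix (per-row RMS).
#' @return RMS value(s), same units as `x`.
#' @export
compute_rms <- function(x) {
  if (is.matrix(x)) {
    check_that(ncol(x) > 0, "empty segment")
    return(apply(x, 1, function(r) sqrt(mean(r^2))))
  }
  check_that(length(x) > 0, "empty segment")
  sqrt(mean(x^2))
}

#' Per-channel signal-to-noise ratio
#'
#' SNR for each electrode channel is the RMS of the EMG during volitional
#' movement divided by the RMS of the channel's resting noise floor.
#'
#' @param movement_segment channels x time matrix (uV) during movement.
#' @param rest_segment channels x time matrix (uV) at rest.
#' @return a data frame with one row per channel: `channel`, `snr`,
#'   `emg_rms`, `noise_rms`.
#' @export
compute_snr <- function(movement_segment, rest_segment) {
  if (!is.matrix(movement_segment)) movement_segment <- matrix(movement_segment, 1)
  if (!is.matrix(rest_segment)) rest_segment <- matrix(rest_segment, 1)
  check_that(nrow(movement_segment) == nrow(rest_segment),
             "segments must have the same channels")
  emg_rms <- compute_rms(movement_segment)
  noise_rms <- compute_rms(rest_segment)
  if (any(noise_rms == 0)) stop("degenerate noise floor: rest RMS is zero", call. = FALSE)
  ch <- rownames(movement_segment)
  if (is.null(ch)) ch <- paste0("ch", seq_along(emg_rms))
  data.frame(channel = ch, snr = emg_rms / noise_rms,
             emg_rms = emg_rms, noise_rms = noise_rms,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rest-bin MAV statistics for onset detection
#'
#' @param features a `feature_sequence` with per-bin labels, or a channels x
#'   bins MAV matrix of pure rest.
#' @return list with per-channel `mean` and `sd` of rest MAV.
#' @export
rest_mav_stats <- function(features) {
  mav <- if (inherits(features, "feature_sequence")) {
    if (!is.null(features$labels)) {
      features$mav[, features$labels == "rest", drop = FALSE]
    } else features$mav
  } else features
  check_that(ncol(mav) >= 10, "need >= 10 rest bins for onset statistics")
  list(mean = apply(mav, 1, mean), sd = apply(mav, 1, stats::sd))
}

#' Detect EMG onset in a feature stream
#'
#' Onset is the first bin at which any channel's MAV exceeds its rest mean
#' plus `k` rest standard deviations for `consecutive` bins in a row. The
#' threshold rule is a pipeline convention (configurable), not a measured
#' physiological quantity.
#'
#' @param features a `feature_sequence`.
#' @param rest_stats output of [rest_mav_stats()].
#' @param k threshold in rest SDs (default 3).
#' @param consecutive required consecutive supra-threshold bins (default 2).
#' @return 1-based bin index of onset, or `NA` if never reached.
#' @export
detect_onset <- function(features, rest_stats, k = 3, consecutive = 2) {
  thr <- rest_stats$mean + k * rest_stats$sd
  above <- apply(features$mav > thr, 2, any)
  if (consecutive <= 1) return(if (any(above)) which(above)[1] else NA_integer_)
  run <- 0L
  for (b in seq_along(above)) {
    run <- if (above[b]) run + 1L else 0L
    if (run >= consecutive) return(b - consecutive + 1L)
  }
  NA_integer_
}
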