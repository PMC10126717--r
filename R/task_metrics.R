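#' Virtual posture-matching task configuration
#'
#' The real-time task: a cued grip must be held for `hold_duration`
#' continuously within a `timeout` window, with the decoder emitting one
#' class per `bin_width` timestep.
#'
#' @param hold_duration required continuous hold, ms (default 1000).
#' @param timeout trial timeout from cue, ms (default 5000).
#' @param bin_width decoder timestep, ms (default 50).
#' @param arm_position categorical condition label: `"side"`, `"front"`,
#'   `"across"` or `"raised"`.
#' @param n_trials trials per run (default 30).
#' @param trial_end `"timeout"` (default): the cue period always lasts the
#'   full timeout, the posture is held until the next cue, and decoding
#'   errors count over the whole period — so accuracy reflects both the
#'   occurrence and the duration of transition errors. `"hold"`: the trial
#'   is truncated at the completion of the first successful hold.
#' @return a `task_config` list.
#' @export
task_config <- function(hold_duration = 1000, timeout = 5000, bin_width = 50,
                        arm_position = c("side", "front", "across", "raised"),
                        n_trials = 30, trial_end = c("timeout", "hold")) {
  arm_position <- match.arg(arm_position)
  trial_end <- match.arg(trial_end)
  check_that(hold_duration <= timeout, "hold_duration must be <= timeout")
  check_that(hold_duration %% bin_width == 0 && timeout %% bin_width == 0,
             "hold_duration and timeout must be multiples of bin_width")
  structure(list(hold_duration = hold_duration, timeout = timeout,
                 bin_width = bin_width, arm_position = arm_position,
                 n_trials = n_trials, trial_end = trial_end),
            class = "task_config")
}

# dispatch per-bin decoding: HMM, static model, or a plain function of the
# feature sequence (used for oracle decoders in tests)
decode_bins <- function(decoder, features) {
  if (inherits(decoder, "hmm_nb")) forward_filter(decoder, features)$argmax
  else if (is.function(decoder)) decoder(features)
  else predict_bins(decoder, features)
}

#' Build a synthetic feature-stream source for the virtual task
#'
#' Returns a function `(cue, seed)` producing the MAV stream a trial would
#' present to the decoder: a rest lead-in (the reaction time between cue and
#' EMG onset) followed by a sustained activation of the cued movement until
#' the end of the timeout window. Streams are generated at 1 kSps (the
#' post-decimation rate the decoder consumes).
#'
#' @param gen_config an [emg_config] (its sample rate is overridden to 1000).
#' @param config a [task_config] (sets the stream duration).
#' @param scale named per-channel session amplitude factors.
#' @param rest_pre rest lead-in, seconds (default 0.4).
#' @param bin_width feature bin width, ms.
#' @return function of `(cue, seed)` returning a `feature_sequence`.
#' @export
make_stream_source <- function(gen_config, config = task_config(),
                               scale = NULL, rest_pre = 0.4, bin_width = 50) {
  stream_cfg <- gen_config
  stream_cfg$sample_rate <- 1000
  stream_cfg$fall_ms <- 0 # the movement is held until the trial ends
  duration <- config$timeout / 1000
  function(cue, seed) {
    rec <- generate_trial(cue, duration, stream_cfg, scale = scale,
                          seed = seed, rest_pre = rest_pre)
    compute_mav(rec, bin_width = bin_width)
  }
}

#' Run the simulated virtual posture-matching task
#'
#' Cues are drawn pseudo-randomly without immediate repetition. Each trial
#' presents the decoder with a feature stream from `stream_source`; success
#' means an uninterrupted hold of the cued grip for the configured duration
#' within the timeout. The trial window ends per `config$trial_end` (full
#' cue period by default, or truncated at hold completion). Every decoder
#' timestep is logged. The analyzed window of a trial runs from detected
#' EMG onset to the trial end; trials without a detected onset are flagged
#' and excluded from latency.
#'
#' @param decoder an `hmm_nb` or `static_model`.
#' @param stream_source function `(cue, seed)` returning a
#'   `feature_sequence` covering at least the timeout window (see
#'   [make_stream_source()]).
#' @param config a [task_config].
#' @param rest_stats rest MAV statistics from [rest_mav_stats()] (for onset
#'   detection).
#' @param cues candidate cue set (default: the decoder's non-rest classes).
#' @param seed integer seed for cue order and stream generation.
#' @return a list of `trial_log` objects; each has `cue`, `outputs` (one
#'   class per 50 ms timestep up to the trial end), `onset_bin`, `success`,
#'   `success_bin` (first bin of the completed hold), `analyzed` (bin
#'   indices from onset to trial end), `bin_width`, `arm_position`.
#' @export
run_virtual_task <- function(decoder, stream_source, config = task_config(),
                             rest_stats, cues = NULL, seed = 1) {
  if (is.null(cues)) {
    check_that(!is.function(decoder),
               "a function decoder needs an explicit cue set")
    cues <- setdiff(decoder$classes, "rest")
  }
  check_that(length(cues) >= 1, "empty cue set")
  hold_bins <- config$hold_duration %/% config$bin_width
  timeout_bins <- config$timeout %/% config$bin_width

  set.seed(derive_seed(seed, 0))
  cue_seq <- character(config$n_trials)
  for (t in seq_len(config$n_trials)) {
    pool <- if (t > 1 && length(cues) > 1) setdiff(cues, cue_seq[t - 1]) else cues
    cue_seq[t] <- pool[sample.int(length(pool), 1)]
  }

  logs <- vector("list", config$n_trials)
  for (t in seq_len(config$n_trials)) {
    cue <- cue_seq[t]
    stream <- stream_source(cue, derive_seed(seed, t))
    n_avail <- ncol(stream$mav)
    check_that(n_avail >= hold_bins, "stream shorter than the hold window")
    n_use <- min(timeout_bins, n_avail)
    sub <- stream
    sub$mav <- stream$mav[, seq_len(n_use), drop = FALSE]
    sub$labels <- stream$labels[seq_len(n_use)]
    outputs <- decode_bins(decoder, sub)
    onset <- detect_onset(sub, rest_stats)

    # first uninterrupted run of >= hold_bins correct timesteps
    correct <- outputs == cue
    r <- rle(correct)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- which(r$values & r$lengths >= hold_bins)
    success <- length(ok) > 0
    success_bin <- if (success) starts[ok[1]] else NA_integer_
    trial_end <- if (success && config$trial_end == "hold") {
      success_bin + hold_bins - 1L
    } else n_use
    outputs <- outputs[seq_len(trial_end)]
    analyzed <- if (!is.na(onset) && onset <= trial_end) onset:trial_end
                else integer(0)
    logs[[t]] <- structure(
      list(cue = cue, outputs = outputs, onset_bin = onset,
           success = success, success_bin = success_bin,
           analyzed = analyzed, bin_width = config$bin_width,
           arm_position = config$arm_position),
      class = "trial_log")
  }
  logs
}

#' Count transition errors in one trial
#'
#' A transition error is any timestep in the analyzed window (EMG onset to
#' trial end) at which the decoder predicted a class other than the cue. A
#' trial without detected onset contributes zero errors by convention and is
#' flagged via the `"no_onset"` attribute.
#'
#' @param log a `trial_log`.
#' @return integer error count (attribute `no_onset` set when onset was
#'   never detected).
#' @export
count_transition_errors <- function(log) {
  if (is.na(log$onset_bin) || length(log$analyzed) == 0) {
    return(structure(0L, no_onset = TRUE))
  }
  sum(log$outputs[log$analyzed] != log$cue)
}

#' Per-class and overall timestep decoding accuracy
#'
#' For each cued movement c, accuracy is the percentage of correctly
#' classified timesteps pooled over that movement's analyzed windows:
#' `A_c = 100 * sum_i [x_i = c] / n(T_c)`. The overall figure pools all
#' classes (it is the pooled ratio, not the mean of per-class values). A
#' class whose pooled analyzed window is empty is reported as `NA`, not 0.
#'
#' @param logs list of `trial_log` objects.
#' @return an `accuracy_result`: list with `per_class` data frame (`class`,
#'   `accuracy`, `n_bins`, `n_errors`), `overall` (percentage),
#'   `transition_error_count`, and `n_no_onset` (flagged trials).
#' @export
compute_accuracy <- function(logs) {
  check_that(length(logs) > 0, "no trial logs")
  cues <- unique(vapply(logs, `[[`, "", "cue"))
  n_bins <- n_err <- stats::setNames(numeric(length(cues)), cues)
  n_no_onset <- 0L
  for (log in logs) {
    e <- count_transition_errors(log)
    if (isTRUE(attr(e, "no_onset"))) n_no_onset <- n_no_onset + 1L
    n_bins[log$cue] <- n_bins[log$cue] + length(log$analyzed)
    n_err[log$cue] <- n_err[log$cue] + as.integer(e)
  }
  acc <- ifelse(n_bins > 0, 100 * (1 - n_err / n_bins), NA_real_)
  overall <- if (sum(n_bins) > 0) 100 * (1 - sum(n_err) / sum(n_bins)) else NA_real_
  structure(list(
    per_class = data.frame(class = cues, accuracy = as.numeric(acc),
                           n_bins = as.numeric(n_bins),
                           n_errors = as.numeric(n_err),
                           row.names = NULL, stringsAsFactors = FALSE),
    overall = overall,
    transition_error_count = sum(n_err),
    n_no_onset = n_no_onset), class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat("Timestep decoding accuracy: overall ",
      formatC(x$overall, digits = 1, format = "f"), "% (",
      x$transition_error_count, " transition errors)\n", sep = "")
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("  %-10s %6.1f%%  (%d bins)\n", x$per_class$class[i],
                x$per_class$accuracy[i], as.integer(x$per_class$n_bins[i])))
  }
  if (x$n_no_onset > 0) cat("  [", x$n_no_onset, " trial(s) without detected onset]\n", sep = "")
  invisible(x)
}

#' Decoder latency of a successful trial
#'
#' The time between the onset of new EMG activity and the start of the
#' successfully held posture: `(success_bin - onset_bin) * bin_width`.
#'
#' @param log a `trial_log`.
#' @return latency in ms, or `NA` for unsuccessful trials or trials without
#'   detected onset.
#' @export
compute_latency <- function(log) {
  if (!isTRUE(log$success) || is.na(log$onset_bin)) return(NA_real_)
  (log$success_bin - log$onset_bin) * log$bin_width
}

#' Online confusion matrix over analyzed timesteps
#'
#' Rows are cued movements, columns predicted classes, normalized to 100%
#' per row; the diagonal equals the per-class timestep accuracy.
#'
#' @param logs list of `trial_log` objects.
#' @param classes column class set (default: union of cues and outputs).
#' @return matrix of row percentages (cues x classes).
#' @export
confusion_matrix <- function(logs, classes = NULL) {
  check_that(length(logs) > 0, "no trial logs")
  cues <- unique(vapply(logs, `[[`, "", "cue"))
  if (is.null(classes)) {
    classes <- unique(c(cues, unlist(lapply(logs, `[[`, "outputs"))))
  }
  cm <- matrix(0, length(cues), length(classes),
               dimnames = list(cued = cues, predicted = classes))
  for (log in logs) {
    if (length(log$analyzed) == 0) next
    tab <- table(factor(log$outputs[log$analyzed], classes))
    cm[log$cue, ] <- cm[log$cue, ] + as.numeric(tab)
  }
  keep <- rowSums(cm) > 0
  cm[keep, ] <- 100 * cm[keep, , drop = FALSE] / rowSums(cm[keep, , drop = FALSE])
  cm
}
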