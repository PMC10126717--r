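#' Channel specification
#'
#' Describes one implanted bipolar intramuscular electrode: either a
#' regenerative peripheral nerve interface (RPNI) graft or a residual
#' innervated forearm muscle. The noise floor is the RMS amplitude recorded
#' at rest; `activation_gain` gives the RMS amplitude (uV) of the
#' movement-related EMG carrier at full effort for each movement class.
#'
#' @param name channel name.
#' @param source_kind `"rpni"` or `"residual_muscle"`.
#' @param noise_floor_rms resting noise floor RMS in uV (> 0 unless the
#'   channel is deliberately silent).
#' @param activation_gain named numeric vector, uV RMS at full effort per
#'   movement; must contain `rest` with gain 0.
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(name, source_kind = c("rpni", "residual_muscle"),
                         noise_floor_rms, activation_gain) {
  source_kind <- match.arg(source_kind)
  check_that(noise_floor_rms >= 0, "noise_floor_rms must be non-negative")
  check_that(!is.null(names(activation_gain)), "activation_gain must be named by movement")
  check_that("rest" %in% names(activation_gain), "activation_gain must include 'rest'")
  check_that(activation_gain[["rest"]] == 0, "rest activation gain must be 0")
  check_that(all(activation_gain >= 0), "activation gains must be non-negative")
  structure(list(name = name, source_kind = source_kind,
                 noise_floor_rms = noise_floor_rms,
                 activation_gain = activation_gain),
            class = "channel_spec")
}

#' Session specification
#'
#' A recording session within a longitudinal series: days post electrode
#' implantation, the per-channel multiplicative amplitude drift factor for
#' that day (the noise floor is held stable; only movement-related EMG
#' amplitude drifts), and the session seed.
#'
#' @param day integer days post-implant, >= 0.
#' @param amplitude_scale named positive numeric vector, one factor per channel.
#' @param seed integer session seed.
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(day, amplitude_scale, seed) {
  check_that(day >= 0, "day must be >= 0")
  check_that(all(amplitude_scale > 0), "amplitude_scale factors must be > 0")
  structure(list(day = as.integer(day), amplitude_scale = amplitude_scale,
                 seed = as.integer(seed)), class = "session_spec")
}

# full activation-gain table (uV RMS at full effort) for the default
# six-channel roster: three RPNIs and three residual muscles.
.gain_table <- function() {
  movements <- c("rest", "fist", "pinch", "point", "open",
                 "thumb_flex", "index_flex", "middle_flex", "ring_flex",
                 "small_flex", "wrist_flex", "abduction", "adduction",
                 "thumb_opposition")
  g <- rbind(
    median_rpni  = c(0, 35, 55,  8,  5, 50, 15, 10,  5,  2, 20,  4,  6, 40),
    ulnar_rpni_1 = c(0, 45,  6, 10, 12,  4,  5, 12, 25, 50, 10, 20, 30, 12),
    ulnar_rpni_2 = c(0, 40, 12, 45, 10,  6,  8,  8, 18, 25, 15, 45, 35, 30),
    fdl          = c(0, 60, 18,  6,  4, 10,  6, 45, 40, 20, 35,  5,  8,  6),
    fdp_index    = c(0, 38, 50, 42,  6,  8, 55, 25, 10,  5, 12,  6,  5, 10),
    edc          = c(0,  6, 10, 35, 55,  5, 12,  8,  6,  8,  4, 20, 10,  5))
  colnames(g) <- movements
  g
}

#' Default synthetic-EMG generator configuration
#'
#' Six channels — median RPNI, ulnar RPNI 1, ulnar RPNI 2 (RPNIs) and FDL,
#' FDP index, EDC (residual muscles) — each with a 1.43 uV RMS noise floor
#' and a distinct activation-gain vector per movement. Movement sets:
#' \describe{
#'   \item{grips}{rest, fist, pinch, point — the four functional grips used
#'     online.}
#'   \item{grips_open}{the four grips plus hand open (finger abduction used
#'     as an active open), as in the physical-prosthesis controller.}
#'   \item{nine}{rest plus thumb/index/middle/ring/small finger flexion,
#'     wrist flexion, finger abduction and adduction.}
#'   \item{intrinsic}{rest, thumb opposition, finger abduction/adduction,
#'     thumb and index flexion.}
#' }
#'
#' @param movement_set one of `"grips"`, `"grips_open"`, `"nine"`,
#'   `"intrinsic"`.
#' @param noise_floor_rms noise floor RMS in uV (default 1.43).
#' @param sample_rate raw sampling rate in samples/s (default 30000; 1000 is
#'   a fast path that skips the decimation stage).
#' @return an `emg_config` list with `channels` (list of [channel_spec]),
#'   `movements`, carrier `band` (Hz), envelope rise/fall times (ms) and
#'   `sample_rate`.
#' @export
default_config <- function(movement_set = c("grips", "grips_open", "nine", "intrinsic"),
                           noise_floor_rms = 1.43, sample_rate = 30000) {
  movement_set <- match.arg(movement_set)
  movements <- switch(movement_set,
    grips      = c("rest", "fist", "pinch", "point"),
    grips_open = c("rest", "fist", "pinch", "point", "open"),
    nine       = c("rest", "thumb_flex", "index_flex", "middle_flex",
                   "ring_flex", "small_flex", "wrist_flex", "abduction",
                   "adduction"),
    intrinsic  = c("rest", "thumb_opposition", "abduction", "adduction",
                   "thumb_flex", "index_flex"))
  g <- .gain_table()[, movements, drop = FALSE]
  kinds <- c(median_rpni = "rpni", ulnar_rpni_1 = "rpni", ulnar_rpni_2 = "rpni",
             fdl = "residual_muscle", fdp_index = "residual_muscle",
             edc = "residual_muscle")
  channels <- lapply(rownames(g), function(ch) {
    channel_spec(ch, kinds[[ch]], noise_floor_rms, g[ch, ])
  })
  emg_config(channels, movements, sample_rate = sample_rate)
}

#' Build a generator configuration from channel specs
#'
#' @param channels list of [channel_spec] objects.
#' @param movements character vector of movement labels; must include
#'   `"rest"` and every movement must have a nonzero gain on at least one
#'   channel.
#' @param band carrier pass band in Hz (default `c(100, 500)`).
#' @param rise_ms,fall_ms trapezoidal activation envelope rise/fall, ms.
#' @param sample_rate samples per second.
#' @return an `emg_config` object.
#' @export
emg_config <- function(channels, movements, band = c(100, 500),
                       rise_ms = 200, fall_ms = 200, sample_rate = 30000) {
  check_that("rest" %in% movements, "'rest' must be among the movements")
  check_that(!anyDuplicated(movements), "movement labels must be unique")
  for (m in setdiff(movements, "rest")) {
    gains <- vapply(channels, function(ch) ch$activation_gain[[m]], numeric(1))
    if (all(gains == 0)) {
      warning("movement '", m, "' has zero gain on every channel")
    }
  }
  structure(list(channels = channels, movements = movements, band = band,
                 rise_ms = rise_ms, fall_ms = fall_ms,
                 sample_rate = sample_rate),
            class = "emg_config")
}

#' @export
print.emg_config <- function(x, ...) {
  kinds <- vapply(x$channels, `[[`, "", "source_kind")
  cat("EMG generator config: ", length(x$channels), " channels (",
      sum(kinds == "rpni"), " RPNI, ", sum(kinds == "residual_muscle"),
      " residual), ", length(x$movements), " movements, ",
      x$sample_rate, " sps\n", sep = "")
  invisible(x)
}

#' Multichannel EMG recording container
#'
#' @param samples channels x time numeric matrix, uV.
#' @param sample_rate samples per second.
#' @param labels per-sample movement label (length = ncol(samples)).
#' @param trials data frame with 0-based half-open sample intervals
#'   `[start, end)` per trial: columns `start`, `end`, `movement`,
#'   `active_start`, `active_end` (the envelope-active span within the trial).
#' @param channel_specs list of [channel_spec] (optional).
#' @return an `emg_recording`.
#' @export
emg_recording <- function(samples, sample_rate, labels = NULL, trials = NULL,
                          channel_specs = NULL) {
  check_that(is.matrix(samples), "samples must be a channels x time matrix")
  check_that(sample_rate > 0, "sample_rate must be > 0")
  check_that(all(is.finite(samples)), "samples must be finite")
  if (!is.null(labels)) {
    check_that(length(labels) == ncol(samples),
               "labels length must equal the number of samples")
  }
  if (!is.null(trials) && nrow(trials) > 1) {
    o <- order(trials$start)
    check_that(all(trials$end[o][-nrow(trials)] <= trials$start[o][-1]),
               "trial intervals must not overlap")
    check_that(all(trials$end <= ncol(samples)) && all(trials$start >= 0),
               "trial intervals must lie within the recording")
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 labels = labels, trials = trials,
                 channel_specs = channel_specs),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("EMG recording: ", nrow(x$samples), " channels x ", ncol(x$samples),
      " samples @ ", x$sample_rate, " sps (",
      round(ncol(x$samples) / x$sample_rate, 2), " s), ",
      if (is.null(x$trials)) 0 else nrow(x$trials), " trials\n", sep = "")
  invisible(x)
}

# band-limited unit-RMS Gaussian carrier, synthesized in the frequency
# domain (hard band edges, so out-of-band energy is at the numerical floor)
.bandlimited_carrier <- function(n, sample_rate, band) {
  if (n < 4) return(rnorm(n))
  x <- rnorm(n)
  f <- abs(seq(0, sample_rate, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, sample_rate - f) # two-sided frequency axis
  keep <- f >= band[1] & f <= min(band[2], sample_rate / 2)
  X <- stats::fft(x)
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# trapezoidal activation envelope over n samples
.trapezoid <- function(n, sample_rate, rise_ms, fall_ms) {
  t_ms <- (seq_len(n) - 1) / sample_rate * 1000
  dur_ms <- n / sample_rate * 1000
  rise <- if (rise_ms > 0) pmin(1, t_ms / rise_ms) else 1
  fall <- if (fall_ms > 0) pmin(1, (dur_ms - t_ms) / fall_ms) else 1
  pmax(0, pmin(rise, fall))
}

#' Generate one synthetic movement trial
#'
#' Each channel is the sum of a Gaussian noise floor (RMS =
#' `noise_floor_rms`, unaffected by session drift) and an independent
#' Gaussian carrier, amplitude-modulated by a trapezoidal envelope that
#' reaches `activation_gain x scale`. Both processes are band-limited to
#' the acquisition pass band (100–500 Hz by default): the reported noise
#' floor is what the band-passed front end sees at rest, so the configured
#' RMS survives preprocessing. Samples under an active envelope are
#' labelled with the movement; all others are `rest`.
#'
#' @param movement movement label; must be in the gain map of every channel.
#' @param duration movement duration, seconds.
#' @param config an [emg_config].
#' @param scale named per-channel amplitude factors (default all 1).
#' @param seed integer seed.
#' @param rest_pre,rest_post seconds of pure noise floor before/after the
#'   movement (labelled rest).
#' @param effort effort level in `[0, 1]` scaling the plateau (default 1).
#' @return an [emg_recording] with one trial annotation.
#' @export
generate_trial <- function(movement, duration, config, scale = NULL, seed = 1,
                           rest_pre = 0, rest_post = 0, effort = 1) {
  fs <- config$sample_rate
  ch_names <- vapply(config$channels, `[[`, "", "name")
  if (is.null(scale)) scale <- stats::setNames(rep(1, length(ch_names)), ch_names)
  for (ch in config$channels) {
    if (!movement %in% names(ch$activation_gain)) {
      stop("channel '", ch$name, "' has no activation gain for movement '",
           movement, "'", call. = FALSE)
    }
  }
  check_that(duration > 0, "duration must be > 0")
  n_pre <- round(rest_pre * fs); n_mov <- round(duration * fs)
  n_post <- round(rest_post * fs)
  n <- n_pre + n_mov + n_post
  env_mov <- if (movement == "rest") rep(0, n_mov) else
    .trapezoid(n_mov, fs, config$rise_ms, config$fall_ms) * effort
  envelope <- c(rep(0, n_pre), env_mov, rep(0, n_post))

  set.seed(seed)
  samples <- matrix(0, length(ch_names), n, dimnames = list(ch_names, NULL))
  for (i in seq_along(config$channels)) {
    ch <- config$channels[[i]]
    gain <- ch$activation_gain[[movement]] * scale[[ch$name]]
    x <- if (ch$noise_floor_rms > 0) {
      ch$noise_floor_rms * .bandlimited_carrier(n, fs, config$band)
    } else numeric(n)
    if (gain > 0 && any(envelope > 0)) {
      x <- x + envelope * gain * .bandlimited_carrier(n, fs, config$band)
    }
    samples[i, ] <- x
  }
  labels <- rep("rest", n)
  labels[envelope > 0] <- movement
  # active span = the cued movement window (also defined for rest trials)
  trials <- data.frame(start = 0L, end = n, movement = movement,
                       active_start = n_pre, active_end = n_pre + n_mov,
                       stringsAsFactors = FALSE)
  emg_recording(samples, fs, labels, trials, config$channels)
}

#' Generate a calibration session
#'
#' Concatenates `reps` repetitions of each movement in pseudo-random order
#' (seeded by the session seed), with rest padding around each repetition —
#' mirroring a calibration block of five repetitions per movement mimicked
#' from a cued virtual hand.
#'
#' @param config an [emg_config].
#' @param reps repetitions per movement (>= 1).
#' @param session a [session_spec]; its `amplitude_scale` multiplies the
#'   activation gains and its seed drives trial order and noise.
#' @param movements movements to include (default: all in `config`).
#' @param trial_duration movement duration per repetition, seconds.
#' @param rest_pre,rest_post rest padding per repetition, seconds.
#' @return an [emg_recording] with one trial annotation per repetition.
#' @export
generate_calibration_session <- function(config, reps = 5,
                                         session = session_spec(0, NULL, 1),
                                         movements = config$movements,
                                         trial_duration = 2,
                                         rest_pre = 0.5, rest_post = 0.5) {
  check_that(length(movements) >= 1, "movement set must be nonempty")
  check_that(reps >= 1, "reps must be >= 1")
  ch_names <- vapply(config$channels, `[[`, "", "name")
  scale <- session$amplitude_scale
  if (is.null(scale)) scale <- stats::setNames(rep(1, length(ch_names)), ch_names)

  set.seed(session$seed)
  order <- sample(rep(movements, reps))
  parts <- vector("list", length(order))
  for (k in seq_along(order)) {
    parts[[k]] <- generate_trial(order[k], trial_duration, config, scale,
                                 seed = derive_seed(session$seed, k),
                                 rest_pre = rest_pre, rest_post = rest_post)
  }
  samples <- do.call(cbind, lapply(parts, `[[`, "samples"))
  labels <- unlist(lapply(parts, `[[`, "labels"), use.names = FALSE)
  lens <- vapply(parts, function(p) ncol(p$samples), integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  trials <- do.call(rbind, lapply(seq_along(parts), function(k) {
    tr <- parts[[k]]$trials
    tr$start <- tr$start + offs[k]; tr$end <- tr$end + offs[k]
    tr$active_start <- tr$active_start + offs[k]
    tr$active_end <- tr$active_end + offs[k]
    tr
  }))
  emg_recording(samples, config$sample_rate, labels, trials, config$channels)
}

#' Generate a longitudinal session series with amplitude drift
#'
#' Draws lognormal session amplitude factors (median 1, log-scale SD
#' `drift_sigma`) emulating the session-to-session EMG-amplitude
#' variability seen over months of implanted recording; the noise floor
#' stays fixed. Under the default `drift_mode = "common"` one factor per
#' session is shared by all channels, so amplitude drifts while the
#' relative activation pattern across channels is held stable — the regime
#' in which a decoder calibrated once can keep working across sessions.
#' `drift_mode = "per_channel"` instead draws i.i.d. factors per channel,
#' which also distorts the across-channel pattern (a harsher, electrode-
#' level drift model). Days default to an even spread over `span_days`
#' (604 d over 16 sessions).
#'
#' @param config an [emg_config].
#' @param n_sessions number of sessions (>= 1).
#' @param drift_sigma lognormal sigma of the session scale (>= 0).
#' @param drift_mode `"common"` (one factor per session, pattern-stable) or
#'   `"per_channel"` (i.i.d. factors per channel and session).
#' @param seed root seed; session seeds are derived deterministically.
#' @param days integer vector of session days (strictly increasing); default
#'   `round(seq(0, span_days, length.out = n_sessions))`.
#' @param span_days series span used for default days.
#' @param recordings if `TRUE`, generate a calibration recording per session.
#' @param reps,trial_duration,rest_pre,rest_post passed to
#'   [generate_calibration_session()].
#' @return a list with one element per session: `session` (a [session_spec])
#'   and `recording` (an [emg_recording] or `NULL`).
#' @export
generate_longitudinal_series <- function(config, n_sessions = 16,
                                         drift_sigma = 0.5,
                                         drift_mode = c("common", "per_channel"),
                                         seed = 1,
                                         days = NULL, span_days = 604,
                                         recordings = TRUE, reps = 5,
                                         trial_duration = 2,
                                         rest_pre = 0.5, rest_post = 0.5) {
  drift_mode <- match.arg(drift_mode)
  check_that(n_sessions >= 1, "n_sessions must be >= 1")
  check_that(drift_sigma >= 0, "drift_sigma must be >= 0")
  if (is.null(days)) {
    days <- if (n_sessions == 1) 0L else round(seq(0, span_days, length.out = n_sessions))
  }
  check_that(length(days) == n_sessions && all(diff(days) > 0) || n_sessions == 1,
             "days must be strictly increasing, one per session")
  ch_names <- vapply(config$channels, `[[`, "", "name")
  lapply(seq_len(n_sessions), function(i) {
    s_seed <- derive_seed(seed, i)
    set.seed(s_seed)
    scale <- stats::setNames(
      if (drift_sigma == 0) rep(1, length(ch_names))
      else if (drift_mode == "common")
        rep(stats::rlnorm(1, 0, drift_sigma), length(ch_names))
      else stats::rlnorm(length(ch_names), 0, drift_sigma), ch_names)
    sess <- session_spec(days[i], scale, s_seed)
    rec <- if (recordings) {
      generate_calibration_session(config, reps = reps, session = sess,
                                   trial_duration = trial_duration,
                                   rest_pre = rest_pre, rest_post = rest_post)
    }
    list(session = sess, recording = rec)
  })
}

#' Expected plateau MAV per channel for a movement
#'
#' Closed-form generator truth used as an oracle: at full envelope the
#' channel signal is zero-mean Gaussian with variance `gain^2 scale^2 +
#' noise^2`, whose mean absolute value is `sqrt(2/pi)` times its RMS.
#'
#' @param config an [emg_config].
#' @param movement movement label.
#' @param scale named per-channel amplitude factors (default 1).
#' @return named numeric vector of expected MAV (uV) per channel.
#' @export
expected_plateau_mav <- function(config, movement, scale = NULL) {
  ch_names <- vapply(config$channels, `[[`, "", "name")
  if (is.null(scale)) scale <- stats::setNames(rep(1, length(ch_names)), ch_names)
  out <- vapply(config$channels, function(ch) {
    g <- ch$activation_gain[[movement]] * scale[[ch$name]]
    sqrt(2 / pi) * sqrt(g^2 + ch$noise_floor_rms^2)
  }, numeric(1))
  stats::setNames(out, ch_names)
}

#' Regenerate recordings for an existing session series
#'
#' Produces a second, independent recording per session under identical
#' session conditions (day and amplitude scale) but fresh noise and trial
#' order — a held-out set for within-session train/test evaluation.
#'
#' @param series output of [generate_longitudinal_series()].
#' @param config the [emg_config] used to build the series.
#' @param seed_offset offset applied to each session seed.
#' @param reps,trial_duration,rest_pre,rest_post passed to
#'   [generate_calibration_session()].
#' @return a session series of the same shape with new recordings.
#' @export
regenerate_session_recordings <- function(series, config, seed_offset = 9901,
                                          reps = 5, trial_duration = 2,
                                          rest_pre = 0.5, rest_post = 0.5) {
  lapply(series, function(s) {
    sess <- session_spec(s$session$day, s$session$amplitude_scale,
                         derive_seed(s$session$seed, seed_offset))
    list(session = sess,
         recording = generate_calibration_session(
           config, reps = reps, session = sess,
           trial_duration = trial_duration,
           rest_pre = rest_pre, rest_post = rest_post))
  })
}
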