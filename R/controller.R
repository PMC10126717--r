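#' Prosthesis controller configuration
#'
#' The physical-hand control layer on top of the grip decoder: a
#' grip-selection filter that only actuates a newly decoded grip after it
#' has persisted continuously for `grip_threshold`, and a linear velocity
#' ramp that attenuates the proportional speed command for `ramp_duration`
#' after every grip change. Both are there to prevent the sudden movements a
#' purely discrete controller would produce.
#'
#' @param grip_threshold ms a new decoded grip must persist before actuation
#'   (default 250).
#' @param ramp_duration ms of linear speed ramp after a grip change
#'   (default 500).
#' @param bin_width controller timestep, ms (default 50).
#' @param rest_class decoded class meaning "no movement" (default
#'   `"rest"`). Rest never actuates as a grip: it stops motion while the
#'   hand keeps its posture, and it resets any pending grip candidate.
#' @return a `controller_config` list.
#' @export
controller_config <- function(grip_threshold = 250, ramp_duration = 500,
                              bin_width = 50, rest_class = "rest") {
  check_that(grip_threshold %% bin_width == 0 && ramp_duration %% bin_width == 0,
             "thresholds must be multiples of bin_width")
  structure(list(grip_threshold = grip_threshold,
                 ramp_duration = ramp_duration, bin_width = bin_width,
                 rest_class = rest_class),
            class = "controller_config")
}

#' Initial controller state
#'
#' @param active_grip initially actuated grip (default `"rest"`).
#' @return a `controller_state` list: `active_grip`, `candidate_grip`,
#'   `candidate_elapsed` (ms), `ramp_elapsed` (ms), `commanded_speed`,
#'   `actuated` (whether a grip change occurred on the last step).
#' @export
controller_init <- function(active_grip = "rest") {
  structure(list(active_grip = active_grip, candidate_grip = NA_character_,
                 candidate_elapsed = 0, ramp_elapsed = Inf,
                 commanded_speed = 0, actuated = FALSE),
            class = "controller_state")
}

#' Advance the controller by one timestep
#'
#' Grip-selection filter: while the decoded class differs from the active
#' grip, it accumulates as a candidate; a single timestep of any other class
#' (including the active grip) resets the accumulator. When the candidate
#' has persisted for `grip_threshold` the new grip actuates on that
#' timestep, and the velocity ramp restarts from zero. The commanded speed
#' is the proportional input attenuated by `min(1, ramp_elapsed /
#' ramp_duration)`, so speed is 0 on the actuation timestep and recovers the
#' raw input only after the full ramp. A decoded rest stops motion and
#' clears any pending candidate but never actuates as a grip itself.
#'
#' @param state a `controller_state`.
#' @param decoded decoded movement class for this timestep.
#' @param proportional proportional effort input in `[0, 1]`.
#' @param config a [controller_config].
#' @return the updated `controller_state`.
#' @export
controller_step <- function(state, decoded, proportional = 1,
                            config = controller_config()) {
  dt <- config$bin_width
  check_that(proportional >= 0 && proportional <= 1,
             "proportional input must be in [0, 1]")
  state$actuated <- FALSE
  if (decoded == (config$rest_class %||% "rest") &&
      decoded != state$active_grip) {
    # rest gates motion but is never actuated as a grip
    state$candidate_grip <- NA_character_
    state$candidate_elapsed <- 0
    state$ramp_elapsed <- state$ramp_elapsed + dt
    state$commanded_speed <- 0
    return(state)
  }
  if (decoded != state$active_grip) {
    if (!is.na(state$candidate_grip) && decoded == state$candidate_grip) {
      state$candidate_elapsed <- state$candidate_elapsed + dt
    } else {
      state$candidate_grip <- decoded
      state$candidate_elapsed <- dt
    }
    if (state$candidate_elapsed >= config$grip_threshold) {
      state$active_grip <- state$candidate_grip
      state$candidate_grip <- NA_character_
      state$candidate_elapsed <- 0
      state$ramp_elapsed <- 0
      state$actuated <- TRUE
    } else {
      state$ramp_elapsed <- state$ramp_elapsed + dt
    }
  } else {
    state$candidate_grip <- NA_character_
    state$candidate_elapsed <- 0
    state$ramp_elapsed <- state$ramp_elapsed + dt
  }
  ramp <- min(1, state$ramp_elapsed / config$ramp_duration)
  state$commanded_speed <- proportional * ramp
  state
}

#' Run the controller over a decoded class sequence
#'
#' @param decoded character vector of decoded classes, one per timestep.
#' @param proportional numeric vector (recycled) of proportional inputs.
#' @param config a [controller_config].
#' @param init initial `controller_state`.
#' @return data frame with one row per timestep: `time_ms`, `decoded`,
#'   `active_grip`, `speed`, `actuated`.
#' @export
run_controller <- function(decoded, proportional = 1,
                           config = controller_config(),
                           init = controller_init()) {
  n <- length(decoded)
  proportional <- rep_len(proportional, n)
  state <- init
  out <- data.frame(time_ms = seq_len(n) * config$bin_width,
                    decoded = decoded, active_grip = character(n),
                    speed = numeric(n), actuated = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    state <- controller_step(state, decoded[i], proportional[i], config)
    out$active_grip[i] <- state$active_grip
    out$speed[i] <- state$commanded_speed
    out$actuated[i] <- state$actuated
  }
  out
}

#' Segmented task plan
#'
#' An activity-of-daily-living protocol broken into grip-transition
#' segments (e.g. fist to pick up the cup, pinch for the coffee pod). Each
#' segment is attempted `repetitions` times in each of `trials` runs, so the
#' maximum possible number of transition errors is
#' `segments x repetitions x trials`.
#'
#' @param segments data frame with columns `grip` (required grip) and
#'   `description`, or a character vector of grips.
#' @param repetitions repetitions per segment within a trial (default 5).
#' @param trials number of trials (default 5).
#' @return a `task_plan` list with `segments`, `repetitions`, `trials`,
#'   `max_transitions`.
#' @export
task_plan <- function(segments, repetitions = 5, trials = 5) {
  if (is.character(segments)) {
    segments <- data.frame(grip = segments, description = segments,
                           stringsAsFactors = FALSE)
  }
  check_that(nrow(segments) >= 1, "plan needs at least one segment")
  structure(list(segments = segments, repetitions = repetitions,
                 trials = trials,
                 max_transitions = nrow(segments) * repetitions * trials),
            class = "task_plan")
}

#' Default coffee-task plan
#'
#' Five grip-transition segments of a simulated coffee-making activity,
#' five repetitions across five trials (125 attempted transitions).
#'
#' @return a `task_plan`.
#' @export
coffee_task_plan <- function() {
  task_plan(data.frame(
    grip = c("fist", "open", "pinch", "open", "point"),
    description = c("pick up the cup of water", "release the cup",
                    "place the coffee pod", "release the pod",
                    "press the brew button"),
    stringsAsFactors = FALSE))
}

#' Grip accuracy from transition counts
#'
#' The segmented-task accounting: accuracy is the percentage of attempted
#' transitions whose first actuated grip was the required one, reported
#' rounded to the nearest integer (the headline figure) alongside the
#' unrounded value.
#'
#' @param correct number of correct transitions.
#' @param total total attempted transitions.
#' @return list with `correct`, `incorrect`, `total`,
#'   `accuracy` (rounded percentage) and `accuracy_unrounded`.
#' @export
grip_accuracy <- function(correct, total) {
  check_that(total >= 1 && correct >= 0 && correct <= total,
             "need 0 <= correct <= total")
  acc <- 100 * correct / total
  list(correct = as.integer(correct), incorrect = as.integer(total - correct),
       total = as.integer(total), accuracy = round(acc),
       accuracy_unrounded = acc)
}

#' Run the segmented grip-transition task
#'
#' For every trial, segment and repetition, the decoder is presented with a
#' feature stream for the required grip, the controller consumes the decoded
#' classes, and the attempt is scored correct iff the first grip actuated
#' after the attempt starts equals the required grip. Each attempt starts
#' from a hand-open state (the participant opens the hand between
#' transitions). An attempt in which no grip actuates is scored incorrect.
#'
#' @param decoder an `hmm_nb` or `static_model`.
#' @param stream_source function `(cue, seed)` returning a
#'   `feature_sequence` (see [make_stream_source()]).
#' @param plan a [task_plan].
#' @param config a [controller_config].
#' @param start_grip controller state at the start of each attempt
#'   (default `"rest"`: the attempt begins from relaxed muscles, so the
#'   first actuated grip is the one scored).
#' @param seed integer seed.
#' @return list with `result` (see [grip_accuracy()]), `attempts` data frame
#'   (`trial`, `segment`, `repetition`, `required`, `first_actuated`,
#'   `correct`).
#' @export
run_segmented_task <- function(decoder, stream_source, plan = coffee_task_plan(),
                               config = controller_config(),
                               start_grip = "rest", seed = 1) {
  rows <- list()
  k <- 0L
  for (trial in seq_len(plan$trials)) {
    for (seg in seq_len(nrow(plan$segments))) {
      required <- plan$segments$grip[seg]
      for (rep in seq_len(plan$repetitions)) {
        k <- k + 1L
        stream <- stream_source(required, derive_seed(seed, k))
        decoded <- decode_bins(decoder, stream)
        ctrl <- run_controller(decoded, 1, config,
                               controller_init(active_grip = start_grip))
        first <- which(ctrl$actuated)
        first_grip <- if (length(first)) ctrl$active_grip[first[1]] else NA_character_
        rows[[k]] <- data.frame(trial = trial, segment = seg,
                                repetition = rep, required = required,
                                first_actuated = first_grip,
                                correct = isTRUE(first_grip == required),
                                stringsAsFactors = FALSE)
      }
    }
  }
  attempts <- do.call(rbind, rows)
  list(result = grip_accuracy(sum(attempts$correct), plan$max_transitions),
       attempts = attempts)
}
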