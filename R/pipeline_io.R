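#' Write a recording as a delimited table plus JSON sidecar
#'
#' Samples go to `<prefix>_samples.csv` (one column per channel, full
#' 17-digit precision so round trips are lossless) and metadata —
#' sample rate, units (uV), channel specs, run-length-encoded labels and
#' trial annotations — to `<prefix>_meta.json`.
#'
#' @param rec an [emg_recording].
#' @param prefix file path prefix.
#' @return invisibly, the two file paths.
#' @export
write_recording <- function(rec, prefix) {
  samples_path <- paste0(prefix, "_samples.csv")
  meta_path <- paste0(prefix, "_meta.json")
  m <- t(rec$samples)
  txt <- apply(m, 2, function(col) formatC(col, digits = 17, format = "g"))
  if (!is.matrix(txt)) txt <- matrix(txt, nrow = 1)
  colnames(txt) <- rownames(rec$samples)
  utils::write.table(txt, samples_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    format = "rpnidecode-recording",
    units = "uV",
    sample_rate = rec$sample_rate,
    n_samples = ncol(rec$samples),
    channels = lapply(rec$channel_specs %||% list(), function(ch) {
      list(name = ch$name, source_kind = ch$source_kind,
           noise_floor_rms = ch$noise_floor_rms,
           activation_gain = as.list(ch$activation_gain))
    }),
    labels_rle = if (!is.null(rec$labels)) {
      r <- rle(rec$labels)
      list(lengths = r$lengths, values = r$values)
    },
    trials = rec$trials)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(samples_path, meta_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording written by [write_recording()]
#'
#' @param prefix file path prefix.
#' @return an [emg_recording].
#' @export
read_recording <- function(prefix) {
  samples_path <- paste0(prefix, "_samples.csv")
  meta_path <- paste0(prefix, "_meta.json")
  check_that(file.exists(samples_path), paste("missing file:", samples_path))
  check_that(file.exists(meta_path), paste("missing file:", meta_path))
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) {
                     stop("malformed sidecar ", meta_path, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
  check_that(identical(meta$format, "rpnidecode-recording"),
             "not a recording sidecar (missing format tag)")
  df <- utils::read.csv(samples_path, check.names = FALSE)
  if (nrow(df) != meta$n_samples) {
    stop("truncated samples file: expected ", meta$n_samples, " samples, got ",
         nrow(df), call. = FALSE)
  }
  samples <- t(as.matrix(df))
  labels <- if (!is.null(meta$labels_rle)) {
    inverse.rle(structure(list(lengths = meta$labels_rle$lengths,
                               values = meta$labels_rle$values), class = "rle"))
  }
  specs <- NULL
  raw <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  if (length(raw$channels)) {
    specs <- lapply(raw$channels, function(ch) {
      channel_spec(ch$name, ch$source_kind, ch$noise_floor_rms,
                   unlist(ch$activation_gain))
    })
  }
  trials <- meta$trials
  emg_recording(samples, meta$sample_rate, labels, trials, specs)
}

#' Serialize a decoder model to JSON
#'
#' All parameters (class list, transition and emission parameters, floors)
#' are written at full precision, so a reloaded model makes identical
#' predictions.
#'
#' @param model an `hmm_nb` or `static_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  ser <- unclass(model)
  ser$.class <- class(model)[1]
  for (fld in c("transition", "emission_mean", "emission_var", "means",
                "vars", "cov", "cov_inv")) {
    if (!is.null(ser[[fld]])) {
      m <- ser[[fld]]
      ser[[fld]] <- list(values = as.numeric(m), dim = dim(m),
                         rownames = rownames(m), colnames = colnames(m))
    }
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a decoder model written by [write_model()]
#'
#' @param path JSON file path.
#' @return the restored model.
#' @export
read_model <- function(path) {
  ser <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed model file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  check_that(is.list(ser) && !is.null(ser$.class),
             "not a model file (missing class tag)")
  cls <- ser$.class
  ser$.class <- NULL
  for (fld in c("transition", "emission_mean", "emission_var", "means",
                "vars", "cov", "cov_inv")) {
    if (!is.null(ser[[fld]])) {
      m <- matrix(ser[[fld]]$values, ser[[fld]]$dim[1], ser[[fld]]$dim[2])
      rn <- ser[[fld]]$rownames; cn <- ser[[fld]]$colnames
      if (length(rn)) rownames(m) <- rn
      if (length(cn)) colnames(m) <- cn
      ser[[fld]] <- m
    }
  }
  structure(ser, class = cls)
}

#' Write virtual-task trial logs as newline-delimited JSON
#'
#' @param logs list of `trial_log` objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_trial_logs <- function(logs, path) {
  lines <- vapply(logs, function(log) {
    jsonlite::toJSON(list(
      cue = log$cue, outputs = log$outputs,
      onset_bin = log$onset_bin, success = log$success,
      success_bin = log$success_bin,
      analyzed_start = if (length(log$analyzed)) min(log$analyzed) else NA,
      analyzed_end = if (length(log$analyzed)) max(log$analyzed) else NA,
      bin_width = log$bin_width, arm_position = log$arm_position,
      latency_ms = compute_latency(log)),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read trial logs written by [write_trial_logs()]
#'
#' @param path NDJSON file.
#' @return list of `trial_log` objects.
#' @export
read_trial_logs <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    analyzed <- if (!is.null(x$analyzed_start) && !is.na(x$analyzed_start)) {
      x$analyzed_start:x$analyzed_end
    } else integer(0)
    structure(list(cue = x$cue, outputs = x$outputs,
                   onset_bin = if (is.null(x$onset_bin)) NA_integer_ else x$onset_bin,
                   success = x$success,
                   success_bin = if (is.null(x$success_bin)) NA_integer_ else x$success_bin,
                   analyzed = analyzed, bin_width = x$bin_width,
                   arm_position = x$arm_position), class = "trial_log")
  })
}

#' Experiment configuration
#'
#' Bundles every stage parameter of an end-to-end run: synthetic generation,
#' decoder training on session 1, the longitudinal virtual task, the
#' segmented coffee task and the session-level analysis.
#'
#' @param seed root seed recorded in all outputs.
#' @param out_dir output directory.
#' @param movement_set generator movement set (see [default_config()]).
#' @param n_sessions,drift_sigma,reps longitudinal series parameters.
#' @param n_trials virtual-task trials per session.
#' @param arm_position arm-position label for the virtual task.
#' @param sample_rate generator rate for the calibration recording (30000
#'   exercises the decimation path; 1000 is the fast path).
#' @param stages stages to run, in order, from `"simulate"`, `"train"`,
#'   `"task"`, `"coffee"`, `"analyze"`.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(seed = 1, out_dir = tempfile("rpnidecode_run_"),
                              movement_set = "grips_open", n_sessions = 4,
                              drift_sigma = 0.5, reps = 5, n_trials = 10,
                              arm_position = "side", sample_rate = 1000,
                              stages = c("simulate", "train", "task",
                                         "coffee", "analyze")) {
  known <- c("simulate", "train", "task", "coffee", "analyze")
  check_that(all(stages %in% known), "unknown stage")
  structure(list(seed = seed, out_dir = out_dir, movement_set = movement_set,
                 n_sessions = n_sessions, drift_sigma = drift_sigma,
                 reps = reps, n_trials = n_trials,
                 arm_position = arm_position, sample_rate = sample_rate,
                 stages = stages[order(match(stages, known))]),
            class = "experiment_config")
}

#' Run an end-to-end experiment
#'
#' Executes the configured stages in order — simulate (longitudinal
#' synthetic sessions), train (HMM-NB on session 1; the model is then fixed
#' and reused, never retrained), task (virtual posture task on every
#' session), coffee (segmented grip-transition task) and analyze (trend
#' test on per-session accuracy) — writing each stage's artifacts under
#' `config$out_dir` and returning a manifest with an MD5 content hash per
#' file. Reruns with the same config are bit-identical for the simulation
#' and training stages.
#'
#' @param config an [experiment_config].
#' @return list with `manifest` (data frame `file`, `md5`), `summary`
#'   (per-session data frame), and in-memory stage results.
#' @export
run_experiment <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- default_config(config$movement_set, sample_rate = config$sample_rate)
  produced <- character(0)
  model <- NULL; series <- NULL; task_summary <- NULL
  results <- list()

  emit <- function(path) produced <<- c(produced, path)

  for (stage in config$stages) {
    if (stage == "simulate") {
      series <- generate_longitudinal_series(
        gen, n_sessions = config$n_sessions, drift_sigma = config$drift_sigma,
        seed = config$seed, reps = config$reps)
      sess_df <- do.call(rbind, lapply(seq_along(series), function(i) {
        s <- series[[i]]$session
        data.frame(session = i, day = s$day, seed = s$seed,
                   channel = names(s$amplitude_scale),
                   amplitude_scale = as.numeric(s$amplitude_scale),
                   root_seed = config$seed, stringsAsFactors = FALSE)
      }))
      p <- file.path(config$out_dir, "sessions.csv")
      utils::write.csv(sess_df, p, row.names = FALSE); emit(p)
      results$series <- series
    } else if (stage == "train") {
      if (is.null(series)) stop("stage 'train' requires the simulate stage",
                                call. = FALSE)
      feats <- .session_features(series[[1]]$recording)
      model <- train_hmm_nb(feats)
      p <- file.path(config$out_dir, "model.json")
      write_model(model, p); emit(p)
      results$model <- model
      results$rest_stats <- rest_mav_stats(feats)
    } else if (stage == "task") {
      if (is.null(model)) stop("stage 'task' requires the train stage",
                               call. = FALSE)
      tcfg <- task_config(arm_position = config$arm_position,
                          n_trials = config$n_trials)
      rows <- list()
      for (i in seq_along(series)) {
        src <- make_stream_source(gen, tcfg,
                                  scale = series[[i]]$session$amplitude_scale)
        logs <- run_virtual_task(model, src, tcfg, results$rest_stats,
                                 seed = derive_seed(config$seed, 1000 + i))
        p <- file.path(config$out_dir, sprintf("task_logs_s%02d.ndjson", i))
        write_trial_logs(logs, p); emit(p)
        acc <- compute_accuracy(logs)
        lat <- vapply(logs, compute_latency, numeric(1))
        rows[[i]] <- data.frame(
          session = i, day = series[[i]]$session$day,
          arm_position = tcfg$arm_position,
          accuracy = acc$overall,
          transition_errors = acc$transition_error_count,
          success_rate = 100 * mean(vapply(logs, `[[`, TRUE, "success")),
          median_latency_ms = stats::median(lat, na.rm = TRUE),
          root_seed = config$seed, stringsAsFactors = FALSE)
      }
      task_summary <- do.call(rbind, rows)
      p <- file.path(config$out_dir, "task_summary.csv")
      utils::write.csv(task_summary, p, row.names = FALSE); emit(p)
      results$task_summary <- task_summary
    } else if (stage == "coffee") {
      if (is.null(model)) stop("stage 'coffee' requires the train stage",
                               call. = FALSE)
      check_that("open" %in% model$classes,
                 "the coffee stage needs a decoder with a hand-open class")
      src <- make_stream_source(gen, task_config(),
                                scale = series[[1]]$session$amplitude_scale)
      coffee <- run_segmented_task(model, src, coffee_task_plan(),
                                   seed = derive_seed(config$seed, 99))
      p <- file.path(config$out_dir, "coffee_attempts.csv")
      utils::write.csv(cbind(coffee$attempts, root_seed = config$seed), p,
                       row.names = FALSE); emit(p)
      p <- file.path(config$out_dir, "coffee_result.json")
      jsonlite::write_json(c(coffee$result, root_seed = config$seed), p,
                           auto_unbox = TRUE, digits = NA); emit(p)
      results$coffee <- coffee
    } else if (stage == "analyze") {
      if (is.null(task_summary)) stop("stage 'analyze' requires the task stage",
                                      call. = FALSE)
      payload <- list(mean_accuracy = mean(task_summary$accuracy),
                      min_accuracy = min(task_summary$accuracy),
                      root_seed = config$seed)
      if (nrow(task_summary) >= 3) {
        trend <- fit_trend(task_summary$day, task_summary$accuracy)
        payload <- c(unclass(trend), payload)
        results$trend <- trend
      }
      p <- file.path(config$out_dir, "trend.json")
      jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA)
      emit(p)
    }
  }
  manifest <- data.frame(file = basename(produced),
                         md5 = unname(tools::md5sum(produced)),
                         stringsAsFactors = FALSE)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(
    root_seed = config$seed,
    version = as.character(utils::packageVersion("rpnidecode")),
    stages = config$stages, files = manifest),
    mp, auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  results
}
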