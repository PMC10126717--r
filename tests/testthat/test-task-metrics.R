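test_that("task configuration enforces its timing invariants", {
  tc <- task_config()
  expect_equal(tc$hold_duration, 1000)
  expect_equal(tc$timeout, 5000)
  expect_error(task_config(hold_duration = 6000), "<= timeout")
  expect_error(task_config(hold_duration = 975), "multiples")
})

test_that("a perfect decoder succeeds on every trial with zero latency", {
  fx <- calib_fixture()
  tc <- task_config(n_trials = 8)
  src <- make_stream_source(fx$cfg, tc)
  oracle <- function(f) f$labels # reads the ground-truth labels
  logs <- run_virtual_task(oracle, src, tc, fx$rest_stats,
                           cues = c("fist", "pinch", "point"), seed = 3)
  expect_true(all(vapply(logs, `[[`, TRUE, "success")))
  lats <- vapply(logs, compute_latency, 0)
  expect_true(all(lats == 0)) # hold starts at EMG onset
  acc <- compute_accuracy(logs)
  expect_equal(acc$overall, 100)
  expect_equal(acc$transition_error_count, 0)
})

test_that("a decoder that never matches the cue times out every trial", {
  fx <- calib_fixture()
  tc <- task_config(n_trials = 5)
  src <- make_stream_source(fx$cfg, tc)
  never <- function(f) rep("rest", ncol(f$mav))
  logs <- run_virtual_task(never, src, tc, fx$rest_stats,
                           cues = c("fist", "pinch"), seed = 4)
  expect_false(any(vapply(logs, `[[`, TRUE, "success")))
  expect_true(all(is.na(vapply(logs, compute_latency, 0))))
  expect_true(all(vapply(logs, function(lg) length(lg$outputs), 0) ==
                    tc$timeout / tc$bin_width))
  expect_equal(compute_accuracy(logs)$overall, 0)
})

test_that("cues avoid immediate repetition and trials are reproducible", {
  fx <- calib_fixture()
  tc <- task_config(n_trials = 30)
  src <- make_stream_source(fx$cfg, tc)
  logs <- run_virtual_task(fx$model, src, tc, fx$rest_stats, seed = 6)
  cues <- vapply(logs, `[[`, "", "cue")
  expect_true(all(cues[-1] != cues[-30]))
  logs2 <- run_virtual_task(fx$model, src, tc, fx$rest_stats, seed = 6)
  expect_identical(cues, vapply(logs2, `[[`, "", "cue"))
  expect_identical(logs[[1]]$outputs, logs2[[1]]$outputs)
})

test_that("transition errors count off-cue timesteps after onset", {
  log <- make_log("fist", c("fist", "pinch", "fist", "pinch"), onset_bin = 1)
  expect_equal(as.integer(count_transition_errors(log)), 2)
  clean <- make_log("fist", rep("fist", 10), onset_bin = 1)
  expect_equal(as.integer(count_transition_errors(clean)), 0)
  blind <- make_log("fist", rep("rest", 10), onset_bin = NA_integer_)
  e <- count_transition_errors(blind)
  expect_equal(as.integer(e), 0)
  expect_true(attr(e, "no_onset"))
})

test_that("accuracy follows the correct-timestep percentage equation", {
  # 18 of 20 analyzed bins correct -> 90.0%
  log18 <- make_log("fist", c(rep("fist", 18), "pinch", "point"))
  expect_equal(compute_accuracy(list(log18))$overall, 90)
  # one erroneous 50 ms bin in a 1 s analyzed window -> 95.0%
  log19 <- make_log("fist", c(rep("fist", 10), "pinch", rep("fist", 9)))
  expect_equal(compute_accuracy(list(log19))$overall, 95)
  # overall pools timesteps rather than averaging per-class values
  a <- make_log("fist", rep("fist", 30))                 # 30/30
  b <- make_log("pinch", c(rep("pinch", 5), rep("fist", 5))) # 5/10
  acc <- compute_accuracy(list(a, b))
  expect_equal(acc$overall, 100 * 35 / 40)
  expect_equal(acc$per_class$accuracy[acc$per_class$class == "pinch"], 50)
  # a class with an empty analyzed window is NA, not zero
  c0 <- make_log("point", rep("rest", 10), onset_bin = NA_integer_)
  acc2 <- compute_accuracy(list(a, c0))
  expect_true(is.na(acc2$per_class$accuracy[acc2$per_class$class == "point"]))
  expect_equal(acc2$n_no_onset, 1)
})

test_that("accuracy and pooled transition errors are consistent", {
  fx <- calib_fixture()
  tc <- task_config(n_trials = 10)
  src <- make_stream_source(fx$cfg, tc)
  logs <- run_virtual_task(fx$model, src, tc, fx$rest_stats, seed = 9)
  acc <- compute_accuracy(logs)
  for (cl in acc$per_class$class) {
    sub <- Filter(function(lg) lg$cue == cl, logs)
    errs <- sum(vapply(sub, function(lg) as.integer(count_transition_errors(lg)), 0L))
    n <- sum(vapply(sub, function(lg) length(lg$analyzed), 0L))
    expect_equal(acc$per_class$accuracy[acc$per_class$class == cl],
                 100 * (1 - errs / n))
  }
})

test_that("latency is bin arithmetic from onset to hold start", {
  log <- make_log("fist", c(rep("rest", 5), rep("fist", 20)), onset_bin = 1,
                  success = TRUE, success_bin = 6)
  expect_equal(compute_latency(log), 250) # hold starts 5 bins after onset
  fail <- make_log("fist", rep("rest", 20), success = FALSE)
  expect_true(is.na(compute_latency(fail)))
})

test_that("latency of successful trials stays within the task window", {
  fx <- calib_fixture()
  tc <- task_config(n_trials = 15)
  src <- make_stream_source(fx$cfg, tc)
  logs <- run_virtual_task(fx$model, src, tc, fx$rest_stats, seed = 12)
  lats <- vapply(logs, compute_latency, 0)
  ok <- !is.na(lats)
  expect_true(all(lats[ok] >= 0))
  expect_true(all(lats[ok] <= tc$timeout - tc$hold_duration))
})

test_that("hold-truncated trials end with the completed hold", {
  fx <- calib_fixture()
  tc <- task_config(n_trials = 6, trial_end = "hold")
  src <- make_stream_source(fx$cfg, tc)
  logs <- run_virtual_task(fx$model, src, tc, fx$rest_stats, seed = 14)
  hold_bins <- tc$hold_duration / tc$bin_width
  for (lg in logs) {
    if (lg$success) {
      expect_length(lg$outputs, lg$success_bin + hold_bins - 1)
      expect_true(all(lg$outputs[lg$success_bin + seq_len(hold_bins) - 1] ==
                        lg$cue))
    }
  }
})

test_that("confusion matrix rows are normalized per-cue distributions", {
  a <- make_log("fist", rep("fist", 10))
  b <- make_log("pinch", c(rep("pinch", 6), rep("fist", 4)))
  cm <- confusion_matrix(list(a, b))
  expect_equal(unname(rowSums(cm)), rep(100, 2), tolerance = 1e-9)
  expect_equal(cm["fist", "fist"], 100)
  expect_equal(cm["pinch", "pinch"], 60)
  expect_equal(cm["pinch", "fist"], 40)
  # diagonal equals the per-class accuracy
  acc <- compute_accuracy(list(a, b))
  for (cl in rownames(cm)) {
    expect_equal(cm[cl, cl],
                 acc$per_class$accuracy[acc$per_class$class == cl])
  }
})
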