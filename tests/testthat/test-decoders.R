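test_that("HMM-NB training recovers degenerate and smoothed structure", {
  # one class, constant features: mean = c, self-transition exactly 1
  f <- make_features(matrix(4, 1, 30), labels = rep("fist", 30))
  m <- train_hmm_nb(f)
  expect_equal(unname(m$emission_mean[1, 1]), 4)
  expect_equal(unname(m$transition[1, 1]), 1)
  # alternating blocks: add-one smoothing guarantees off-diagonal mass
  labs <- rep(rep(c("a", "b"), each = 10), 3)
  f2 <- make_features(matrix(rep(c(1, 5), each = 10, times = 3), 1),
                      labels = labs)
  m2 <- train_hmm_nb(f2)
  expect_true(all(m2$transition > 0))
  expect_equal(rowSums(m2$transition), c(a = 1, b = 1), tolerance = 1e-9)
  # a requested class with no data errors by name
  expect_error(train_hmm_nb(f, classes = c("fist", "pinch")), "pinch")
})

test_that("emission means recover generator plateau MAV within 10%", {
  cfg <- grips_config()
  rec <- generate_calibration_session(cfg, reps = 5,
                                      session = session_spec(0, NULL, 21),
                                      trial_duration = 4)
  m <- train_hmm_nb(compute_mav(rec))
  for (mv in cfg$movements) {
    truth <- expected_plateau_mav(cfg, mv)
    est <- m$emission_mean[mv, names(truth)]
    expect_true(all(abs(est - truth) / truth < 0.1),
                label = paste("plateau recovery for", mv))
  }
})

test_that("forward filtering equals exhaustive path enumeration", {
  for (n_states in 1:3) {
    for (n_bins in 1:4) {
      model <- random_hmm(n_states, n_channels = 2,
                          seed = 100 * n_states + n_bins)
      mav <- matrix(stats::runif(2 * n_bins, 0, 5), 2, n_bins)
      got <- forward_filter(model, mav)$posterior
      want <- brute_force_posterior(model, mav)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("posteriors are normalized and symmetric cases stay uniform", {
  model <- random_hmm(3, seed = 7)
  mav <- matrix(stats::runif(2 * 30, 0, 5), 2, 30)
  dec <- forward_filter(model, mav)
  expect_equal(unname(rowSums(dec$posterior)), rep(1, 30), tolerance = 1e-9)
  expect_equal(dec$argmax,
               model$classes[apply(dec$posterior, 1, which.max)])
  # identical emissions and uniform transitions leave the posterior uniform
  sym <- random_hmm(3, seed = 8)
  sym$transition <- matrix(1 / 3, 3, 3)
  sym$initial <- rep(1 / 3, 3)
  sym$emission_mean <- matrix(2, 3, 2)
  sym$emission_var <- matrix(1, 3, 2)
  post <- forward_filter(sym, mav)$posterior
  expect_equal(unname(post), matrix(1 / 3, 30, 3), tolerance = 1e-12)
})

test_that("predictions are invariant under consistent channel permutation", {
  fx <- calib_fixture()
  perm <- c(4, 1, 6, 3, 2, 5)
  m <- fx$model
  mp <- m
  mp$emission_mean <- m$emission_mean[, perm]
  mp$emission_var <- m$emission_var[, perm]
  mp$channels <- m$channels[perm]
  stream <- compute_mav(generate_trial("point", 2, fx$cfg, seed = 31,
                                       rest_pre = 0.3))
  expect_identical(forward_filter(m, stream)$argmax,
                   forward_filter(mp, stream$mav[perm, ])$argmax)
})

test_that("static baselines fit separable and degenerate data sensibly", {
  mav <- matrix(c(rep(1, 20), rep(8, 20)), 1)
  labs <- rep(c("a", "b"), each = 20)
  for (kind in c("nb", "lda")) {
    m <- train_static(mav, labs, kind = kind)
    expect_equal(predict_bins(m, mav), labs)
  }
  # identical features for every class: prediction falls back to the prior
  same <- matrix(2, 1, 30)
  labs2 <- c(rep("a", 20), rep("b", 10))
  m2 <- train_static(same, labs2, kind = "nb")
  expect_equal(predict_bins(m2, matrix(2, 1, 3)), rep("a", 3))
  expect_error(train_static(same, rep("a", 30), kind = "nb"), "2 classes")
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 2), 30),
             matrix(rnorm(60, c(0, 4)), 30, byrow = TRUE))
  labs <- rep(c("a", "b", "c"), each = 30)
  ours <- train_static(t(x), labs, kind = "lda")
  ref <- MASS::lda(x, grouping = labs)
  test <- rbind(matrix(rnorm(30, 0), 15), matrix(rnorm(30, 2), 15))
  expect_equal(predict_bins(ours, t(test)),
               as.character(stats::predict(ref, test)$class))
})

test_that("trial prediction uses trial averages (static) and the mode (HMM)", {
  mav <- matrix(c(rep(0, 20), rep(10, 20)), 1)
  labs <- rep(c("lo", "hi"), each = 20)
  nb <- train_static(mav, labs, kind = "nb")
  expect_equal(predict_trial(nb, matrix(4, 1, 1)), "lo") # single bin rule
  # bin-wise predictions split 2/1 for "lo" but the average lands in "hi":
  # bins 0, 0, 30 -> average 10
  trial <- matrix(c(0, 0, 30), 1)
  binwise <- predict_bins(nb, trial)
  expect_equal(sum(binwise == "lo"), 2) # bin-majority oracle says "lo"
  expect_equal(predict_trial(nb, trial), "hi") # trial-average rule decides
  # HMM mode with earliest-achieved tie break
  fx <- calib_fixture()
  s_fist <- compute_mav(generate_trial("fist", 2, fx$cfg, seed = 41))
  expect_equal(predict_trial(fx$model, s_fist), "fist")
})

test_that("leave-one-out runs one fold per trial and scores separable data", {
  fx <- calib_fixture()
  cv <- loo_cross_validate(fx$feats, fx$rec$trials, kind = "lda")
  expect_equal(cv$n_folds, nrow(fx$rec$trials))
  expect_equal(nrow(cv$predictions), nrow(fx$rec$trials))
  expect_equal(cv$accuracy, 1.0)
  cv_hmm <- loo_cross_validate(fx$feats, fx$rec$trials, kind = "hmm")
  expect_equal(cv_hmm$accuracy, 1.0)
})

test_that("shuffled labels drop LOO accuracy to chance", {
  cfg <- grips_config()
  rec <- generate_calibration_session(cfg, reps = 15,
                                      session = session_spec(0, NULL, 77),
                                      trial_duration = 1,
                                      rest_pre = 0.2, rest_post = 0.2)
  trials <- rec$trials
  set.seed(13)
  trials$movement <- sample(trials$movement)
  cv <- loo_cross_validate(compute_mav(rec), trials, kind = "nb")
  p <- 1 / 4
  expect_lt(abs(cv$accuracy - p), 3 * sqrt(p * (1 - p) / nrow(trials)) + 0.02)
})

test_that("nine-movement offline decoding is accurate when separable", {
  cfg <- default_config("nine", sample_rate = 1000)
  rec <- generate_calibration_session(cfg, reps = 3,
                                      session = session_spec(0, NULL, 55),
                                      trial_duration = 1.5,
                                      rest_pre = 0.3, rest_post = 0.3)
  f <- compute_mav(rec)
  for (kind in c("nb", "lda")) {
    cv <- loo_cross_validate(f, rec$trials, kind = kind)
    expect_gt(cv$accuracy, 0.9)
  }
})

test_that("decoding accuracy degrades monotonically as separation collapses", {
  base <- grips_config()
  gains <- sapply(base$channels, function(ch) ch$activation_gain)
  # per-channel mean gain over the non-rest grips: the collapse target
  center <- colMeans(gains[setdiff(base$movements, "rest"), , drop = FALSE])
  accs <- vapply(c(1, 0.6, 0.3, 0.1, 0), function(alpha) {
    channels <- lapply(seq_along(base$channels), function(i) {
      ch <- base$channels[[i]]
      g <- ch$activation_gain
      g[names(g) != "rest"] <- alpha * g[names(g) != "rest"] +
        (1 - alpha) * center[i]
      ch$activation_gain <- g
      ch
    })
    cfg <- emg_config(channels, base$movements, sample_rate = 1000)
    rec <- generate_calibration_session(cfg, reps = 3,
                                        session = session_spec(0, NULL, 61))
    f <- compute_mav(rec)
    m <- train_hmm_nb(f)
    test <- generate_calibration_session(cfg, reps = 3,
                                         session = session_spec(0, NULL, 62))
    ft <- compute_mav(test)
    mean(forward_filter(m, ft)$argmax == ft$labels)
  }, 0)
  expect_true(all(diff(accs) <= 0.005),
              label = paste("separation grid accuracies:",
                            paste(round(accs, 3), collapse = " ")))
  expect_lt(accs[5], 0.75) # near-collapsed separation is poor
})
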