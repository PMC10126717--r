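# shared fixtures and independent oracles, built in code

# memoize expensive fixtures across test files within one run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# default four-grip generator at the 1 kSps fast path
grips_config <- function() default_config("grips", sample_rate = 1000)

# one cached calibration recording + features + decoder + rest stats
calib_fixture <- function() {
  fixture("calib", {
    cfg <- grips_config()
    rec <- generate_calibration_session(cfg, reps = 5,
                                        session = session_spec(0, NULL, 42))
    feats <- compute_mav(rec)
    list(cfg = cfg, rec = rec, feats = feats,
         model = train_hmm_nb(feats),
         rest_stats = rest_mav_stats(feats))
  })
}

# wrap a bare MAV matrix as a feature sequence (1 kSps, 50 ms bins)
make_features <- function(mav, labels = NULL, bin_width = 50) {
  if (!is.matrix(mav)) mav <- matrix(mav, nrow = 1)
  structure(list(mav = mav, bin_width = bin_width, origin = 0L,
                 labels = labels, sample_rate = 1000,
                 samples_per_bin = bin_width),
            class = "feature_sequence")
}

# wrap a channels x time matrix as a recording
make_recording <- function(samples, sample_rate, labels = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  emg_recording(samples, sample_rate, labels)
}

# random small HMM-NB model for property tests
random_hmm <- function(n_states, n_channels = 2, seed) {
  set.seed(seed)
  trans <- matrix(stats::rexp(n_states^2), n_states)
  trans <- trans / rowSums(trans)
  init <- stats::rexp(n_states); init <- init / sum(init)
  classes <- paste0("c", seq_len(n_states))
  structure(list(classes = classes, states_per_class = 1,
                 initial = init, transition = trans,
                 emission_mean = matrix(stats::runif(n_states * n_channels, 0, 5),
                                        n_states, n_channels),
                 emission_var = matrix(stats::runif(n_states * n_channels, 0.2, 2),
                                       n_states, n_channels),
                 state_to_class = classes,
                 channels = paste0("ch", seq_len(n_channels)),
                 var_floor = 1e-4),
            class = "hmm_nb")
}

# brute-force filtered state posteriors by exhaustive path enumeration:
# at each time t, sum the joint over every state path ending in each state
brute_force_posterior <- function(model, mav) {
  n_bins <- ncol(mav)
  n_states <- length(model$state_to_class)
  emis <- function(st, b) {
    prod(stats::dnorm(mav[, b], model$emission_mean[st, ],
                      sqrt(model$emission_var[st, ])))
  }
  post <- matrix(0, n_bins, n_states)
  for (t in seq_len(n_bins)) {
    paths <- as.matrix(expand.grid(rep(list(seq_len(n_states)), t)))
    w <- apply(paths, 1, function(p) {
      v <- model$initial[p[1]] * emis(p[1], 1)
      if (t > 1) for (b in 2:t) {
        v <- v * model$transition[p[b - 1], p[b]] * emis(p[b], b)
      }
      v
    })
    for (st in seq_len(n_states)) post[t, st] <- sum(w[paths[, t] == st])
    post[t, ] <- post[t, ] / sum(post[t, ])
  }
  # collapse states to classes
  cls <- matrix(0, n_bins, length(model$classes),
                dimnames = list(NULL, model$classes))
  for (st in seq_len(n_states)) {
    cl <- model$state_to_class[st]
    cls[, cl] <- cls[, cl] + post[, st]
  }
  cls
}

# exhaustive two-sided rank-sum p-value by enumerating all group assignments
rank_sum_enumerate <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  ws <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- m * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# hand-built trial log
make_log <- function(cue, outputs, onset_bin = 1L, success = FALSE,
                     success_bin = NA_integer_, analyzed = NULL,
                     bin_width = 50) {
  if (is.null(analyzed)) {
    analyzed <- if (is.na(onset_bin)) integer(0) else onset_bin:length(outputs)
  }
  structure(list(cue = cue, outputs = outputs, onset_bin = onset_bin,
                 success = success, success_bin = success_bin,
                 analyzed = analyzed, bin_width = bin_width,
                 arm_position = "side"),
            class = "trial_log")
}

# generator config whose non-rest activation lives only on RPNI channels
# (intrinsic hand movements: no extrinsic residual-muscle representation)
rpni_only_config <- function(sample_rate = 1000) {
  base <- default_config("intrinsic", sample_rate = sample_rate)
  channels <- lapply(base$channels, function(ch) {
    if (ch$source_kind == "residual_muscle") {
      ch$activation_gain[] <- 0
    }
    ch
  })
  suppressWarnings(emg_config(channels, base$movements,
                              sample_rate = sample_rate))
}

channel_names <- function(cfg) vapply(cfg$channels, `[[`, "", "name")
rpni_channels <- function(cfg) {
  channel_names(cfg)[vapply(cfg$channels, `[[`, "", "source_kind") == "rpni"]
}
residual_channels <- function(cfg) {
  channel_names(cfg)[vapply(cfg$channels, `[[`, "", "source_kind") == "residual_muscle"]
}
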