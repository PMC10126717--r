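# rpnidecode

Simulation and analysis pipeline for **longitudinal intramuscular EMG
decoding** in upper-limb neuroprosthetic control.

Regenerative peripheral nerve interfaces (RPNIs — free muscle grafts
reinnervated by a transected nerve, acting as bioamplifiers of efferent
motor commands) and implanted electrodes in residual forearm muscles
provide high-amplitude, chronically stable EMG after limb loss. The
question this package is built around: **does a grip decoder calibrated
once keep working for months to years without recalibration**, given that
absolute EMG amplitude drifts substantially from session to session while
the resting noise floor (~1.43 µV RMS) stays put?

Because no participant recordings are publicly deposited, everything here
runs on a statistically matched synthetic generator, and the package is a
testbed for the *machinery*: estimators, real-time metrics, controller
semantics, and statistical calibration.

## What's inside

* **Synthetic EMG** (`default_config`, `generate_trial`,
  `generate_calibration_session`, `generate_longitudinal_series`) —
  six channels (3 RPNIs + 3 residual muscles), band-limited (100–500 Hz)
  Gaussian carriers under trapezoidal activation envelopes on a 1.43 µV
  noise floor, with lognormal session-to-session amplitude drift.
* **Signal processing** (`preprocess`, `compute_mav`, `compute_rms`,
  `compute_snr`, `detect_onset`) — Butterworth 100–500 Hz band-pass,
  30 kSps → 1 kSps decimation, mean-absolute-value (MAV) features in 50 ms
  non-overlapping bins, SNR as movement RMS over resting noise-floor RMS.
* **Decoders** (`train_hmm_nb`, `forward_filter`, `train_static`,
  `predict_trial`, `loo_cross_validate`) — the streaming hidden Markov
  model with Naive Bayes emissions over channel MAVs,

  `P(x_t | state) = ∏_c N(x_tc; μ_sc, σ²_sc)`,

  decoded causally by the log-space forward recursion every 50 ms, plus
  single-state NB and ridge-regularized LDA baselines with
  trial-averaged/mode per-trial prediction and leave-one-out CV.
* **Virtual posture-matching task** (`run_virtual_task`,
  `compute_accuracy`, `count_transition_errors`, `compute_latency`,
  `confusion_matrix`) — 1 s continuous hold within a 5 s timeout; per-class
  timestep accuracy `A_c = 100 · Σ_{i∈T_c}[x_i = c] / n(T_c)` over the
  analyzed window from EMG onset to trial end; decoder latency from onset
  to hold start.
* **Prosthesis controller** (`controller_step`, `run_controller`,
  `run_segmented_task`, `coffee_task_plan`) — 250 ms grip-selection filter,
  500 ms linear velocity ramp, and the segmented coffee-making task
  accounting (5 segments × 5 repetitions × 5 trials = 125 possible
  transition errors).
* **Longitudinal statistics** (`fit_trend`, `compare_positions`,
  `rank_sum_compare`, `ablate_channels`, `icapca_2d`) — slope F-tests,
  one-way ANOVA with Bonferroni pairwise comparisons, Wilcoxon rank sum,
  per-session channel-ablation analysis, and 2D extended-infomax ICA-PCA
  feature visualization.
* **Pipeline IO** (`run_experiment`, `write_recording`, `write_model`,
  `write_trial_logs`, …) — lossless text serialization and a staged,
  MD5-manifested, seed-reproducible experiment runner.

## Worked example

Calibrate a four-grip decoder on synthetic session 1, then reuse it —
never recalibrated — across 16 drifted sessions spanning 604 days:

```r
library(rpnidecode)

cfg    <- default_config("grips", sample_rate = 1000)
series <- generate_longitudinal_series(cfg, n_sessions = 16,
                                       drift_sigma = 0.5, seed = 1)

feats      <- compute_mav(series[[1]]$recording)
decoder    <- train_hmm_nb(feats)          # trained once
rest_stats <- rest_mav_stats(feats)
decoder
#> HMM-NB decoder: 4 classes (rest, pinch, point, fist), 4 states, 6 channels

tc  <- task_config(n_trials = 20)
src <- make_stream_source(cfg, tc, scale = series[[16]]$session$amplitude_scale)
logs <- run_virtual_task(decoder, src, tc, rest_stats,
                         seed = derive_seed(1, 116))
compute_accuracy(logs)                      # session 16, day 604
#> Timestep decoding accuracy: overall 99.8% (3 transition errors)
#>   fist        100.0%  (644 bins)
#>   point       100.0%  (460 bins)
#>   pinch        99.6%  (736 bins)
```

The overall figure is the percentage of correctly classified 50 ms
timesteps from EMG onset to each trial's end, pooled over trials — so it
penalizes both the occurrence and the duration of transition errors. Doing
this for every session and regressing accuracy on days post-implant:

```r
accs <- vapply(seq_along(series), function(i) {
  src <- make_stream_source(cfg, tc, scale = series[[i]]$session$amplitude_scale)
  compute_accuracy(run_virtual_task(decoder, src, tc, rest_stats,
                                    seed = derive_seed(1, 100 + i)))$overall
}, numeric(1))
range(accs)
#> 97.7 99.9
fit_trend(vapply(series, function(s) s$session$day, numeric(1)), accs)
#> Linear trend: slope 0.0008416/day, F = 1.08, p = 0.316 -> no-trend
```

Per-session accuracy stays between 97.7% and 99.9% with no significant
trend: amplitude drift that preserves the relative channel pattern does
not erode a fixed HMM-NB. The segmented coffee-task accounting prints its
two standard figures directly:

```r
grip_accuracy(correct = 124, total = 125)
#> $accuracy: 99        (rounded headline)
#> $accuracy_unrounded: 99.2
```

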