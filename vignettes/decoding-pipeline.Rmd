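---
title: "Simulating and decoding longitudinal intramuscular EMG for prosthetic grip control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding longitudinal intramuscular EMG for prosthetic grip control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpnidecode)
```

## The problem

Implanted bipolar electrodes in regenerative peripheral nerve interfaces
(RPNIs — free muscle grafts reinnervated by a transected nerve, acting as
bioamplifiers of efferent motor commands) and in residual innervated forearm
muscles provide high-amplitude, chronically stable electromyography (EMG)
after limb loss. The engineering question for prosthetic control is whether
a grip decoder calibrated once keeps working for months to years without
recalibration, even though the absolute EMG amplitude varies substantially
from day to day.

`rpnidecode` implements the complete analysis chain for that question as
tested, reproducible code operating on synthetic data: a multichannel EMG
generator with session-to-session amplitude drift, the signal-processing
front end, a streaming hidden-Markov-model classifier with Naive Bayes
emissions (HMM-NB) plus single-state Naive Bayes (NB) and linear
discriminant (LDA) baselines, a real-time virtual posture-matching task
with transition-error and latency metrics, a physical-prosthesis control
layer (grip-selection filter and proportional velocity ramp), and the
session-level statistics (SNR tracking, trend F-tests, arm-position ANOVA,
rank-sum decoder comparisons, channel ablation, 2D ICA-PCA visualization).

No participant recordings ship with the package; every analysis runs on the
generator, so the tests verify the *machinery* — estimators, metrics,
controller semantics, statistical calibration — not any clinical claim.

## The synthetic EMG generator

### Signal model

Each channel is modeled as

$$x(t) = n(t) + e(t)\, g_{cm}\, s_c\, w(t),$$

where $n(t)$ is the noise floor, a band-limited (100–500 Hz) Gaussian
process with RMS $\sigma_c$ (default 1.43 µV — the median noise floor
reported for chronically implanted intramuscular electrodes, stable across
years); $w(t)$ is an independent unit-RMS Gaussian carrier in the same
band; $g_{cm}$ is channel $c$'s activation gain for movement $m$ (µV RMS
at full effort); $s_c$ is the session amplitude factor; and $e(t)$ is a
trapezoidal activation envelope with 200 ms rise and fall. Both processes
are synthesized with hard spectral edges in the frequency domain, so
out-of-band energy is at the numerical floor and — importantly — the
configured noise RMS is what the 100–500 Hz acquisition front end sees:
it survives preprocessing, as a measured noise floor would.

Because noise and carrier are independent, the plateau RMS is
$\sqrt{g^2 s^2 + \sigma^2}$ and the plateau mean absolute value (MAV) is
$\sqrt{2/\pi}$ times that; `expected_plateau_mav()` exposes this closed
form as the oracle the tests check parameter recovery against.

The default configuration mirrors a six-channel implant: three RPNIs
(median RPNI, ulnar RPNI 1 and 2) and three residual muscles (FDL, FDP
index, EDC), with distinct activation-gain vectors for the four functional
grips (rest, fist, two-finger pinch, index point), plus gain tables for a
hand-open class, a nine-movement set (individual finger flexions, wrist
flexion, finger abduction/adduction), and an intrinsic-movement set. Gain
magnitudes (tens of µV) sit around the reported median movement EMG RMS of
a few tens of µV. The grips are well separated by construction because the
online four-grip controller they feed is reported to operate at 94–96%
accuracy; the nine-movement table deliberately contains closer patterns
(adjacent-finger sharing), which is where offline decoders actually lose
accuracy.

### Session drift

`generate_longitudinal_series()` draws lognormal amplitude factors
(median 1, log-SD `drift_sigma`, default 0.5 — which reproduces an
EMG-RMS interquartile spread comparable to the reported tens of µV) for a
default of 16 sessions spread over 604 days. Two drift modes exist:

* `"common"` (default): one factor per session shared by all channels.
  Amplitude drifts while the relative activation pattern across channels is
  held stable. This is the regime consistent with the central longitudinal
  observation being modeled — a decoder calibrated once keeps working for
  hundreds of days despite large amplitude variability — and with the
  physiological reading that day-to-day variability is dominated by global
  factors (effort level, limb state, interface impedance).
* `"per_channel"`: i.i.d. factors per channel and session. This harsher
  model also distorts the across-channel pattern. We keep it available
  because electrode-level drift exists in practice, but it is not the
  default: simulations show that independent per-channel scaling of 0.3–3×
  makes one grip's scaled pattern more likely under another grip's emission
  model for entire trials, which contradicts the no-recalibration stability
  the pipeline is built to measure.

The noise floor is *not* scaled by drift (measured noise floors are
reported stable), so session drift moves SNR through its numerator only.

### What the generator does not emulate

Motor-unit spike trains and recruitment (the analysis consumes only
MAV/RMS, which amplitude-modulated band-limited noise reproduces),
electrode shift or impedance transients, afferent stimulation artifacts,
within-session fatigue, and — most importantly — *closed-loop effort
adaptation*: effort is fixed at full, so the simulated user never pushes
harder on a weak day. Passing tests therefore demonstrate correct machinery
and stability under the stated drift model, not robustness of a fixed
Gaussian decoder to arbitrary real-world drift (see Limitations).

## Signal processing

The front end mirrors a 30 kSps acquisition chain: 4th-order Butterworth
band-pass (100–500 Hz), zero-phase (forward–backward) for offline analysis
or causal for streaming, followed by stride decimation to 1 kSps (the
500 Hz cutoff already satisfies Nyquist at the target rate). MAV features
are means of rectified samples in 50 ms non-overlapping bins; a trailing
partial bin is discarded, never padded. SNR per channel is the RMS during
volitional movement divided by the RMS of the resting noise floor; segment
selection is caller-provided since no window standard exists.

EMG onset — the anchor of the analyzed window of every trial — is the
first bin in which any channel's MAV exceeds its rest mean plus $k$ rest
standard deviations (default $k = 3$) for two consecutive bins. The rule
and both constants are pipeline conventions (no published definition
exists); they are configurable and logged. On synthetic rest the MAV SD is
small, so this detector fires within the first 50 ms of the activation
rise — earlier than any amplitude-based classifier can identify *which*
movement is starting, which is the dominant source of transition errors in
the simulated task.

## Decoders

`train_hmm_nb()` fits the streaming classifier: latent states with
diagonal-Gaussian emissions over the channel MAVs (the Naive Bayes
factorization), transition probabilities from labelled bin-to-bin counts
with add-one smoothing (keeping the chain ergodic), uniform initial
distribution, and a variance floor of $10^{-4}\,\mu V^2$ against
degenerate likelihoods. `forward_filter()` is the causal forward recursion
in log space; per-bin class posteriors sum the state posteriors, and ties
break deterministically by class-list order. The default is one state per
movement; multi-state left-to-right sub-chains (contiguous labelled runs
split into equal temporal segments) are available via `states_per_class`
and shorten onset latency slightly, but every property in the test suite
holds at the single-state default, so the simpler model stays the default.

The offline baselines are re-implemented to keep their numerical contract
explicit: NB as per-class diagonal Gaussian maximum likelihood, LDA with a
pooled within-class covariance ridge-regularized by
$\varepsilon\,\mathrm{tr}(\Sigma)/d$ ($\varepsilon = 10^{-6}$), priors from
bin frequencies. The test suite cross-checks LDA predictions against an
independent reference implementation. Per-trial predictions use the rules
appropriate to each family: NB/LDA classify the trial-averaged MAV, the
HMM-NB takes the mode of its per-bin output (ties to the earliest-achieved
class); both deliberately ignore transient errors for open-loop evaluation,
and leave-one-out cross-validation holds out whole trials.

## The virtual posture-matching task

A cue (drawn pseudo-randomly without immediate repetition) starts a trial;
the simulated participant reacts after a rest lead-in and sustains the
movement. The trial succeeds when the decoder holds the cued class
uninterrupted for 1 s within a 5 s timeout, decoding every 50 ms.

Two windowing conventions are implemented. Under the default
(`trial_end = "timeout"`) the cue period always runs its full course and
the posture is held until the next cue, so the analyzed window $T_c$ spans
EMG onset to the end of the period — accuracy then reflects both the
occurrence and the duration of transition errors. The alternative
(`trial_end = "hold"`) truncates the trial at the completion of the first
successful hold. The default was chosen on arithmetic grounds: per-trial
accuracy under hold-truncation is $h/(h+L)$ for a hold of $h$ bins and
latency of $L$ bins, so a 250 ms latency alone caps a trial at 80% — a
windowing under which the jointly reported ~95% timestep accuracies and
100–250 ms latencies of real online use could not coexist. Only the
full-period window makes those figures mutually consistent.

Metrics follow the standard definitions: per movement $c$,
$A_c = 100 \sum_{i \in T_c} [x_i = c] / n(T_c)$ pooled over trials (the
overall figure pools timesteps, it is not a mean of per-class values; a
class with an empty pooled window is `NA`, not 0); a transition error is
any analyzed timestep predicting off-cue; latency is the time from EMG
onset to the *start* of the completed hold (the completion-end alternative
differs by exactly 1 s and the start convention keeps a perfect decoder at
0 ms); trials without detected onset are flagged, contribute no errors,
and are excluded from latency. Confusion matrices are row-normalized
per-cue distributions whose diagonal equals $A_c$ by construction.

## The prosthesis controller

The physical-hand layer prevents the sudden movements of a purely discrete
controller: a newly decoded grip must persist for 250 ms of continuous
50 ms timesteps before it actuates (a single off-candidate bin resets the
counter — strict continuity, matching the "continuous hold" semantics of
the virtual task), and after every grip change the proportional speed
command ramps linearly from 0 to its raw value over 500 ms, so commanded
speed is continuous across a change. Decoded rest gates motion (speed 0,
candidate cleared) but never actuates as a grip; hand open is an ordinary
class to the decoder and only the controller treats it as the
aperture-opening action.

The segmented activity-of-daily-living protocol (five grip-transition
segments — fist, open, pinch, open, point — five repetitions, five trials)
scores each attempt correct iff the first actuated grip equals the required
one, giving at most $5 \times 5 \times 5 = 125$ transition errors; grip
accuracy is reported rounded (the headline figure) alongside the unrounded
percentage. Each attempt starts from relaxed muscles so exactly one
transition is scored. Object-drop task errors are human events outside the
computational scope; only grip-transition accuracy is computed.

## Longitudinal statistics

Session trends use OLS with the regression F-test at $\alpha = 0.05$
(a constant series returns $F = 0$, no-trend, rather than 0/0); the
`trend_test_type1_error_rate` quantity in the acceptance output verifies
nominal calibration under a stable-decoder null. Arm-position comparisons
use one-way ANOVA with Bonferroni-corrected pairwise tests on transition
errors per trial; decoder comparisons use the two-sided Wilcoxon rank sum
test (exact for $m + n \le 12$ without ties, normal approximation with tie
correction otherwise — the tests check it against exhaustive enumeration).

Channel ablation retrains the classifier per session on each channel
subset and averages per-trial accuracy unweighted across sessions.
Evaluation uses a held-out recording generated under identical session
conditions (same day and amplitude scale, fresh noise) in preference to
within-session leave-one-out: with an ablated, uninformative channel set,
LOO's exclusion of the held-out trial from its own class mean biases
chance-level classes *below* $1/k$, while held-out evaluation is unbiased
at chance. The intrinsic movement set is the designed showcase: intrinsic
hand movements (thumb opposition, finger abduction/adduction) have no
extrinsic forearm-muscle representation, so with residual-muscle channels
only, every movement collapses to chance — the construction the ablation
acceptance check exercises.

The 2D feature-space visualization centers per-trial MAV vectors, projects
onto the top two principal components, whitens, and applies *extended*
(kurtosis-sign-adaptive) infomax ICA. Plain logistic infomax assumes
super-Gaussian sources and demonstrably mixes the sub-Gaussian
(multimodal) cluster structure this plot exists to display. Determinism
comes from identity initialization and full-batch natural-gradient updates;
component sign follows a fixed convention (dominant channel loading
positive) and components are ordered by projected variance, since ICA sign
and order are inherently arbitrary. Coordinates are projections onto
unit-norm independent directions — feature-space scale — because whitened
scale would equalize signal and noise components and hide cluster
separation. Channel contribution vectors are the rows of the 2D mixing
matrix (pseudo-inverse of the projection).

## Numerical and reproducibility choices

0-based half-open sample intervals everywhere; µV and ms units fixed in
all files; one root seed with Lehmer-style splitting (`derive_seed()`,
always below $2^{31}$) so every session and trial is independently
reproducible; recordings persist as CSV samples (17 significant digits —
lossless round trip) with a JSON sidecar for channel metadata,
run-length-encoded labels, and trial annotations; models serialize to JSON
at full precision so a reloaded model predicts identically; trial logs are
newline-delimited JSON; `run_experiment()` writes an MD5-hashed manifest
and reruns of the simulation and training stages are bit-identical. The
exported functions and `run_experiment()` are the orchestration surface;
there is no shell CLI because every consumer of this package works in R.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run calibrations of five
repetitions per movement (2–4 s per repetition), virtual-task runs of
20–30 trials per session, 16-session drifted series, 1000-replicate null
calibrations, and 6-session ablation series with held-out recordings —
sizes chosen to match the modeled experimental protocol at the small end
of its reported ranges while keeping any single experiment in the tens of
seconds. Most simulation runs use the 1 kSps generator fast path; the
30 kSps decimation path is exercised explicitly by the signal-processing
tests.

## A compact end-to-end run

```{r, eval = FALSE}
library(rpnidecode)

cfg <- default_config("grips", sample_rate = 1000)
series <- generate_longitudinal_series(cfg, n_sessions = 16,
                                       drift_sigma = 0.5, seed = 1)

feats <- compute_mav(series[[1]]$recording)
decoder <- train_hmm_nb(feats)      # calibrated once, reused for all sessions
rest_stats <- rest_mav_stats(feats)

tc <- task_config(n_trials = 20)
accuracy <- vapply(seq_along(series), function(i) {
  src <- make_stream_source(cfg, tc,
                            scale = series[[i]]$session$amplitude_scale)
  logs <- run_virtual_task(decoder, src, tc, rest_stats,
                           seed = derive_seed(1, 100 + i))
  compute_accuracy(logs)$overall
}, numeric(1))

days <- vapply(series, function(s) s$session$day, numeric(1))
fit_trend(days, accuracy)           # no-recalibration stability test
```

## Known limitations

* A fixed Gaussian-emission decoder tolerates roughly a 4× relative
  amplitude change between the calibration day and a later session; beyond
  that, entire grips are systematically misassigned. Real users adapt
  effort in closed loop and real calibration data contain effort
  variability that widens emission distributions; the fixed-effort,
  open-loop simulation therefore *understates* achievable robustness at
  extreme drift while being honest about the decoder mathematics.
* The onset detector's 3-SD threshold on near-ideal synthetic rest fires
  at a few percent of plateau amplitude, earlier than movement identity is
  decodable; simulated latencies (median ~50 ms) are consequently faster
  than real reported latencies, and simulated accuracies correspondingly
  benign. Structure, not participant-specific values, is what the
  synthetic experiments reproduce.
* Arm position is carried as a categorical label only; there is no
  biomechanical model, so position effects exist in the simulation only if
  mapped to distinct drift factors.
* Effort is fixed at full per the generator default; within-session effort
  variability is configurable but off by default.
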