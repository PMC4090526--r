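---
title: "Decoding hand trajectories: models, design choices and limitations"
author: "reachDecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hand trajectories: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the three decoding models, the evaluation metrics, the synthetic
center-out world they are benchmarked in, and the numerical and design
choices a maintainer would want spelled out. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The decoding problem

The input is a multichannel neural time series — in the motivating
setting, 68 MEG gradiometer channels over bilateral sensorimotor cortex,
band-passed to 0.5–8 Hz and downsampled to 50 Hz — recorded while a
participant makes center-out point-to-point reaches to four corner
targets, roughly 0.93 s per movement, with 4 s between trials. The task
is to reconstruct the 2-D hand velocity (and from it position, speed and
direction) from the neural signals alone, and to understand how the
choice of decoding model interacts with two properties of natural
reaching:

* **speed is nonlinear** — a unimodal, bell-shaped profile per reach, and
* **speed is largely independent of direction**.

## Models

**Linear filter.** Each velocity coordinate is a linear function of a
200 ms history window (the current sample plus $m = 10$ preceding ones
at 50 Hz) of every channel, plus an intercept. Fitting is ordinary least
squares; when the lagged design is rank deficient the minimum-norm
solution is returned with a warning (68 × 11 lagged copies of band-limited
channels are strongly collinear). Rows with incomplete history are
excluded from fitting and withheld from prediction rather than
zero-padded, avoiding edge bias. Lag $j$ means strictly earlier samples
($t-j$), so prediction is causal.

**Kalman filter.** A time-invariant linear-Gaussian state-space model
over the 2-D velocity state. $A$ and $H$ are least-squares estimates;
$W$ and $Q$ are residual covariances with the $1/(\text{rows}-1)$
normalization. Decoding is the textbook predict/update recursion; the
innovation covariance is symmetrized every step and, should its Cholesky
factorization fail, a diagonal jitter of `1e-9 * (1 + mean(diag))` is
added and the event counted in the returned `StateSequence`.

**Hybrid Kalman filter.** The state is extended to
$[r(t), r(t-1), r(t-2), d_x(t), d_y(t)]$: the current speed, two lagged
copies of it (together encoding the local change and curvature of the
bell-shaped profile — three temporal terms are the minimum that can
describe a bell), and the unit direction. The Kalman machinery is
unchanged; two independent read-outs sit on the posterior:

* **direction** — the posterior $(d_x, d_y)$ normalized to unit length;
  if its norm is at or below the speed floor the previous direction is
  carried forward (first-sample fallback $(1, 0)$);
* **speed** — a multilayer perceptron (3 inputs, 18 tanh hidden units,
  1 logistic-sigmoid output) applied to the posterior
  $(r(t), r(t-1), r(t-2))$. Inputs and training targets are divided by
  `speedScale` (the maximum training speed), so the rescaled output is
  confined to $(0, \mathrm{speedScale})$ — speed estimates can never be
  negative and never explode. Inputs above the training maximum simply
  saturate.

Decoded velocity is the product of the two read-outs. The network output
never feeds back into the recursion: the filter stays linear-Gaussian,
and the full model and its ablation (speed read directly from the
posterior $r(t)$) share identical posteriors, differing only in the
read-out. The network's input width is fixed at 3, which structurally
enforces the speed–direction independence assumption: no direction
information can leak into the speed estimate.

### Why the network trains on posterior states

What the speed network sees at decode time is never the true speed
state — it is the Kalman posterior, a smoothed, biased, noisy version of
it. `fitHybrid()` therefore decodes the training observations with the
fitted filter and trains the network on those posterior speed states
against the true current speed (`trainOn = "posterior"`, the default).
This matches the training and decoding input distributions and lets the
network correct systematic distortion in the posterior, at the cost of
one extra decoding pass over the training data. Teacher forcing on the
true states (`trainOn = "true"`) is retained as an option; with it the
network can only learn the (nearly identity) map from clean speed states
to speed, which is the right setting for asking whether nonlinearity
per se is what the network contributes (the test suite uses it for
exactly that question).

### Scaled conjugate gradient training

The network is trained by Møller's scaled conjugate gradient on the
full-batch mean squared error. Hyperparameters (all overridable):
$\sigma_0 = 10^{-4}$, $\lambda_0 = 10^{-6}$, at most 500 iterations,
stop when the gradient norm falls below $10^{-6}$; conjugacy is restarted
every `#parameters` accepted steps. Weights initialize uniformly on
$(-0.5, 0.5)/\sqrt{\text{fan-in}}$ under a recorded seed, so identical
calls give bit-identical networks. The loss trace over accepted steps is
stored in the model and is non-increasing by construction.

### Re-initialization of the recursion

Offline decoding is trial-wise: the recursion restarts at every decoded
segment. The initial state is the mean training state. The initial
covariance is the **covariance of the training states** — the marginal
state prior, i.e. the correct statement of ignorance about the state at
an epoch boundary. An earlier draft used the per-step system noise $W$
instead; that prior is far too confident for short segments (on
reach-only runs of ~1 s the direction states never moved off their
initialization, leaving decoded paths straight and wrong), and the
change to the marginal prior fixed exactly that failure mode.

## Signal conditioning

* **Band-pass**: 4th-order Butterworth, applied forward–backward
  (`signal::filtfilt`), i.e. zero phase — appropriate offline, where no
  causality constraint exists and phase distortion would misalign
  kinematics and neural features. Passband gain is within ~1% of unity
  mid-band; DC and out-of-band tones are attenuated by more than 99%.
  Because a realizable Butterworth has finite passband ripple, filtering
  an already band-limited signal is the identity only to about 1%, and
  the test suite checks the filter–downsample commutation property at
  that fidelity.
* **Downsampling** slices every $k$-th sample for integer rate ratios
  (the 0.5–8 Hz band-pass already rules out aliasing at 50 Hz) and falls
  back to polyphase resampling (`signal::resample`) with a rational
  approximation of the ratio otherwise.
* **Epoching** cuts $[t_{\min}, t_{\max}]$ windows around target onsets
  (default $-1$ to $2$ s, 151 samples at 50 Hz); onsets whose window
  leaves the recording are dropped with a warning and counted.
* **Reach/rest labeling** thresholds speed at 5% of the session peak;
  only below-threshold runs of at least 0.1 s become rest, which acts as
  hysteresis against fragmenting a movement at brief dips. An
  event-table-based labeler is provided as an alternative. All values
  are configurable.

## Evaluation metrics

RMSE is computed over the per-sample Euclidean error (position,
velocity) or absolute difference (speed), after intersecting validity
masks. The pointing metrics project the decoded path onto the task axis
(start → target line; the perpendicular sign follows the +90°
rotation of the axis direction) and report:

* **ODC** — sign changes of the increments of the along-axis coordinate
  (reversals of progress toward the target; consistency),
* **MDC** — sign changes of the increments of the perpendicular
  coordinate (reversals across the axis; smoothness),
* **ME** — mean absolute perpendicular deviation,
* **MV** — sample standard deviation (n−1) of the perpendicular
  deviation.

Zero increments inherit the previous nonzero sign, so flat segments
never create spurious counts, and leading zeros are skipped. The mapping
of "orthogonal" to along-axis reversals and "movement" to perpendicular
reversals follows the functional descriptions of the measures
(consistency toward the target vs. smoothness about the axis); anyone
comparing against another implementation should check which convention
it uses, since the two counts are easily swapped. All four metrics are
invariant under rigid motions of the scene, which the suite verifies.
Metrics are computed on the outbound segment of each trial by default
(the task has no dwell criterion, so no target-acquisition truncation is
applied).

## The synthetic center-out world

No public dataset accompanies the setting this package targets, so the
generator is a first-class, tested module rather than a fixture. It
emulates:

* 120 trials per session, 30 per corner target, in seeded pseudorandom
  balanced order; 4 s trial spacing; target onset 1 s into each trial
  (so a $(-1, 2)$ s epoch always fits); 0.25 s reaction time;
* minimum-jerk out-and-back movements (the canonical bell-shaped
  profile, with closed-form position, velocity and peak speed
  $1.875\,L/T$ for oracle tests), nominal duration 0.93 s with Gaussian
  jitter (SD 0.1 s, truncated at ±0.3 s);
* a ground-truth reach mask marking samples above 5% of the movement's
  peak speed — the standard movement onset/offset convention, and the
  definition the speed-threshold labeler estimates;
* 68 surrogate channels
  $z_i(t) = g_i \cdot v(t-\ell_i) + h_i\,\sigma((s(t-\ell_i)-\theta)/\kappa) + n_i(t)$:
  a lagged linear velocity code, plus on half the channels a sigmoidal
  speed tuning (threshold $\theta = 1.5$, width $\kappa = 0.4$ units/s
  against a ~2.9 units/s peak speed, so the tuning is genuinely
  nonlinear across the speed range), in band-limited Gaussian noise.

### Calibration of the default gains and noise

The defaults are chosen to put the decoders in the accuracy regime
reported for noninvasive kinematic decoding, not in a sterile high-SNR
regime:

* `linearGainSD = 0.5` vs `nonlinearGainSD = 2.5`: speed coding is
  deliberately stronger than velocity coding, reflecting the
  noninvasive-decoding literature in which hand speed is robustly
  decodable from low-frequency fields while direction information is
  scarcer.
* `noiseSD = 5` with a **1/f ("pink") in-band spectrum**: MEG sensor and
  brain noise is strongly 1/f at low frequencies; per-channel SNR is
  low, and decoding accuracy comes from pooling 68 channels. Under these
  defaults the linear filter's cross-validated velocity correlation is
  ≈ 0.65 — the upper-middle of published noninvasive ranges.

A flat ("white") in-band spectrum remains available
(`noiseSpectrum = "white"`).

### What the generator does not emulate

Real MEG has nonstationary artifacts, cross-channel correlated
interference, sensor geometry, and an unknown, certainly richer neural
code. Two consequences matter when reading benchmark results:

* The surrogate code is *additively* linear in velocity. A regression
  filter is therefore never structurally mis-specified here, and its
  velocity errors are only weakly autocorrelated — they largely cancel
  when integrated to position. The hybrid's direction errors, by
  contrast, come from a smoothed posterior and persist over a reach, so
  they integrate coherently. On these sessions the regression filter
  attains the lowest *position* RMSE even while the hybrid attains the
  lowest *speed* RMSE and beats the standard Kalman filter on both;
  on real recordings, with structured nonstationary noise and a code
  that is not additively linear in velocity, the position ranking need
  not transfer, and results obtained on this surrogate should not be
  read as a statement about real MEG.
* Passing tests demonstrate correctness of the algorithms and the
  qualitative orderings the generator is designed to probe (nonlinear
  speed structure rewards the nonlinear read-out), not decoding
  performance on any particular real dataset.

## Benchmark protocol

`runBenchmark()` uses trial-wise stratified 5-fold cross-validation
(every trial decoded exactly once, as test data), under two regimes:
`reach_rest` fits and scores on all samples; `reach_only` excludes rest
samples from fitting *and* scoring and restarts decoding at every
contiguous reach run. Decoded velocity is integrated to position per
trial (per run in `reach_only`), starting from the true position at the
segment start — position must be scored somehow from velocity decoders,
and anchoring each segment at its true start point is the choice made
here (documented, since no standard exists). Decoders are compared by
paired t-tests on per-trial RMSE; raw P values are reported without
multiplicity correction, and each input dataset is treated as one
independent session. The train/test protocol is a package choice — users
comparing against other work should treat the fold structure, not just
the metric definitions, as part of the comparison.

Problem sizes: the default benchmark (120 trials × 200 samples, 68
channels, 5 folds, 2 regimes) runs in a few minutes on one CPU; the test
suite exercises reduced sessions (20 trials, 12 channels) for module
tests and ten full-size single-split sessions for the paired decoder
comparisons.

## Known limitations

* Only the x–y plane is modelled; a z-axis on input is dropped with a
  warning.
* The observation model of the hybrid filter treats direction as
  linearly observed, but in a velocity-coding channel the direction's
  observation gain scales with speed; during rest the direction
  posterior is therefore noise, and the unit-normalization contract
  means the decoder always emits *some* direction. Its speed read-out,
  bounded below by 0 but strictly positive, multiplies this into a
  small, slowly wandering rest velocity — visible as position drift over
  long rest periods.
* The ablation read-out ($r(t)$ directly) is not range-restricted and
  can go (slightly) negative at rest; it is reported as-is rather than
  clamped, since clamping would silently hand it part of the network's
  advantage.
* `trainSpeedMLP()` rejects constant targets unless an explicit
  `speedScale` is supplied: with the default scale (max target) a
  constant target rescales to exactly 1, which a sigmoid can only reach
  asymptotically.
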