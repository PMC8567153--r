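---
title: "Methods: dual-IMU wrist angle estimation and movement classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-IMU wrist angle estimation and movement classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imuwrist)
```

## The measurement problem

Active wrist range of motion (ROM) is a core clinical outcome in cerebral
palsy (CP), conventionally measured with a goniometer — slow, contact-based
and hard to use with young children. `imuwrist` implements an alternative:
two 9-axis inertial measurement units (IMUs), one on the back of the hand and
one just above the wrist, mounted with parallel Y and Z axes. Because the
sensors share a frame, the wrist joint angle is simply the *difference* of the
two sensors' orientations about the shared Y axis. This two-sensor relative
formulation reduces a 3-D orientation problem to a 2-D one: no reference
plane, no Euler angles, no quaternions.

On top of the angle estimator the package builds a movement classifier:
trials are converted into frequency-domain feature vectors and a suite of
standard classifiers is benchmarked, under cross-validation, at telling
CP-like (reduced, slower, tremulous) wrist movement from typical movement.

## Per-sensor orientation

### Accelerometer tilt

When a sensor is quasi-static the accelerometer measures gravity. The tilt on
the X–Z plane is the four-quadrant arctangent

$$\beta = \operatorname{atan2}(a_x, a_z)\ \text{(degrees)},$$

so the neutral posture (gravity along +Z) reads 0° and a quarter rotation
about Y reads 90°. The projections on the Y–Z and Z–Y planes are computed and
exposed for inspection (`tilt_angles()`), but only the X–Z angle drives the
joint measurement: the mounting geometry confines wrist flexion/extension to
a rotation about the shared Y axis. The tilt observation is exact in a static
posture but noisy and biased by motion acceleration during movement — hence
sensor fusion.

### Gyroscope drift correction

Rate gyros carry a constant bias ("static drift") plus a slowly varying
component. The static drift is estimated as the mean rate over $m$ windows of
100 samples, window $j$ starting at sample $n + jr$ with defaults $n = 0$,
$m = 5$, $r = 100$; the series must be longer than $n + (m-1)r + 100m$
samples, and the windows are expected to fall in the stationary lead-in of a
trial. The per-sample rate is then calibrated with a Savitzky–Golay filter
(local least-squares polynomial smoothing, default window 51 samples, order
3):

$$\omega_{gf}(i) = \mathrm{SG}[\omega_{\text{raw}}](i) - \bar\omega_{\text{static}}.$$

Two readings of the Savitzky–Golay step were possible: smooth the *residual
drift* and subtract it, or use the filter as the calibrated (denoised) rate
itself. The first reading is self-defeating for this filter length — an SG
filter of window 0.51 s reproduces any movement-band waveform almost exactly,
so subtracting the smoothed residual would cancel the motion signal along
with the drift. The package therefore implements the second reading: the SG
filter denoises the rate, and the window-mean bias is subtracted. The
consequence to keep in mind is that the SG smoother attenuates sharp rate
transients (it is least accurate at the corners of a velocity plateau); for
slower, bandlimited movement it is transparent.

### Complementary filter

The filtered angle about the Y axis (equivalently, on the X–Z plane) is the
first-order complementary blend

$$\sigma(i+1) = h\,\bigl(\sigma(i) + \omega_{gf}(i+1)\,\Delta t\bigr) + l\,\beta(i+1),
\qquad h + l = 1,$$

with defaults $h = 0.98$, $l = 0.02$ and $\Delta t = 1/f_s$. The gyro path is
effectively high-passed (accurate over transients, drifting over minutes) and
the accelerometer tilt low-passed (noisy instant-by-instant, unbiased on
average); the blend has a time constant of roughly $\Delta t / l = 0.5$ s at
100 Hz, which bounds the residual effect of any uncorrected gyro drift at
about $\omega_{\text{drift}} \cdot \Delta t / l$ degrees. $h + l = 1$ is
enforced at construction of `fusion_config()`, so violating configurations
cannot exist. The filter is initialised from the first accelerometer tilt
observation. The wrist angle is then
`hand$sigma - forearm$sigma` per sample, summarised by its maximum and its
range (`joint_angle()`).

The sampling interval is taken from the trial's explicit sampling rate
(default 100 Hz, i.e. $\Delta t = 0.01$ s); `fs` is carried as per-trial
metadata end to end.

## The synthetic motion simulator

No public recordings exist for this task, so the package ships a simulator
that defines the study conditions under which the pipeline is validated.

**Trajectory.** The stop-sign task is modelled as rest → smooth ramp to the
peak angle → hold → smooth ramp back → rest. The angular-velocity profile is
a cosine-blended trapezoid: `speed` is the *peak* angular velocity (reached
exactly on the plateau), the blend time is 0.3 s (shortened for very quick
ramps), and the swept angle has the closed form `speed * (T_r - T_b)`, so the
commanded peak angle is hit exactly. A minimum-jerk ramp was considered and
rejected: its peak velocity is 1.875× the average, which would make "movement
at 30°/s" ambiguous. Within a trial of duration $D$ the layout is: leading
rest (up to 6 s, sized so that the static-drift windows fall entirely in it
at the default drift configuration even after a 1 s startup trim), ramp, hold
(up to 1.5 s), ramp down, trailing rest. An optional tremor sinusoid
(amplitude in degrees, frequency in Hz) is superposed on the whole
trajectory.

**Sensors.** The forearm sensor stays level; the hand sensor rotates about
the shared Y axis by the true angle (in the both-moving validation mode the
forearm counter-rotates by half the amplitude and the hand carries the rest,
preserving the commanded relative peak). Accelerometers report the gravity
vector projected through the sensor orientation, in g (1 g = 9.80665 m/s²);
gyroscopes report the true rate plus per-axis static bias, a slow linear
drift ramp and white noise; magnetometers report a fixed ambient field
rotated into the sensor frame plus noise. Default imperfections
(`sensor_noise_model()`): accelerometer noise 0.01 g, gyro noise 0.2 °/s,
gyro bias (0.5, −0.3, 0.4) °/s, drift ramp 0.005 °/s², magnetometer noise
0.5 µT — representative of a consumer MEMS part.

What the simulator deliberately does **not** model: motion (tangential or
centripetal) acceleration on the accelerometer — every noise-free sample has
magnitude exactly 1 g, which makes the tilt observation unrealistically
trustworthy during movement; cross-axis motion; magnetometer disturbance;
soft-tissue artefact; sensor detachment. Passing the validation envelopes on
this simulator therefore demonstrates that the estimator chain is correct and
well-conditioned under drift, bias and noise, not that it achieves clinical
accuracy on real limbs — the simulator is a stand-in for a robotic
validation rig, not for patients.

**Cohort contrast.** The two-class cohort (`cohort_spec()`) encodes the
clinical contrast the classifier must detect as reduced movement: CP-like
trials default to a 40° mean peak at 20 °/s with a 2°, 5 Hz tremor; typical
trials to 70° at 40 °/s with no tremor; per-trial jitter is 5° (sd) on the
peak and 10% (sd) on the speed; trials are 15 s at 100 Hz. These effect sizes
are package choices of a plausible, clearly separated contrast — no
quantitative kinematic difference is published for the clinical cohorts, so
classification accuracy on the synthetic cohort says nothing about accuracy
on clinical data; it verifies the pipeline end to end.

## Frequency-domain features

Each of the 18 channels (2 sensors × 9 axes) of a trimmed trial is
mean-removed and Fourier-transformed (no taper; the fundamental frequency is
$f_0 = 1/t_{\text{total}}$, the reciprocal of the record length). The five
largest-amplitude non-DC peaks — "the first five harmonics" in order of
energy, ties to the lower frequency — contribute their amplitude $A$ (channel
units, one-sided normalisation so a pure sinusoid of amplitude $a$ peaks at
$a$), phase $P$ (radians, from the complex coefficient) and peak frequency
$F$ (Hz). The alternative reading — bins at exact multiples $k f_0$,
$k = 1..5$, under which $F$ would be degenerate — is available via
`extract_harmonics(mode = "fundamental")`; the dominant-peak reading is the
default precisely because it makes $F$ informative.

The canonical vector is block-major: amplitudes at 1–90, phases at 91–180,
frequencies at 181–270; within a block, channels run hand ax…mz then forearm
ax…mz, five harmonics each (`feature_index()`); so 270 = 2 × 9 × 5 × 3, which
is also the only channel reading under which the documented count holds —
the magnetometer channels are included. Position 91 is the phase of the
first (dominant) harmonic of the hand accelerometer X channel. Feature
matrices export to CSV and to plain-text ARFF.

## The classification benchmark

`run_cv()` evaluates each classifier under stratified $k$-fold
cross-validation (default 10-fold, i.e. 90% training / 10% testing, repeated
over the folds). Folds are dealt by one continuous round-robin across the
shuffled classes, so fold sizes differ by at most one *and* per-fold class
counts differ by at most one. Out-of-fold predictions are pooled into a
single accuracy, a pooled ROC curve (standard orientation: false-positive
rate on x) and a class-weighted AUC — per-class one-vs-rest AUCs averaged by
prevalence, which for a binary problem coincides with the plain AUC; the
weighted form is computed regardless. `summarize_benchmark()` appends the
unweighted mean accuracy (2 decimals) and AUC (3 decimals) over the
non-baseline rows.

ZeroR (training-majority class, ties to label 0; its constant score makes the
ROC the chance diagonal) and OneR (equal-frequency discretisation with a
minimum bucket of 6, per-bin majority labels, minimum-training-error feature,
ties to the lowest index, degenerate features skipped with a majority-class
fallback) are implemented natively — the benchmark's interpretive value
rests on these baselines. The remaining classifiers delegate to standard
implementations behind a common fit/score interface: naive Bayes and SVM
(RBF, probability outputs) from `e1071`, ridge-penalised logistic regression
from `glmnet` (the ridge makes the 270-feature, $p \gtrsim n$ problem
well-posed), an information-gain `rpart` tree with pruning as the C4.5-style
learner, `randomForest` with 100 trees, a single-hidden-layer softmax `nnet`
(10 units, decay 0.01) on standardised inputs as the MLP, and 1-nearest
neighbour from `class` on standardised inputs. "BayesNet" degrades to naive
Bayes with a one-time warning, as no Bayesian-network backend is configured.
Fitting seeds are derived from the CV seed, so a benchmark re-run with the
same data and seed is identical.

## Validation experiments and problem sizes

`peak_angle_error_experiment()` replays the robotic-rig style validation on
the simulator: 20 trials (default) to predetermined peaks of 30/50/70/90°,
full pipeline, mean signed error between detected and true peak. Under the
default noise model the package holds the mean absolute error under 0.95°
with one sensor static, under 2.90° with both moving at 30 °/s and under
2.63° at 90 °/s; noise-free, the per-trial error is below 0.1°. Trials are
20 s at 100 Hz — long enough that the five 100-sample drift windows fall in
the stationary lead-in after the 1 s startup trim.

The test suite exercises the classifier sanity check on a 100/100 default
cohort (random forest above 90% accuracy while ZeroR sits at 50%), and the
reference pipeline run uses the same sizes. These sizes were chosen as the
smallest at which the estimates are stable.

## Numerical choices and edge cases

- Angles are kept in degrees throughout; tilt output lies in (−180°, 180°].
  No unwrapping is needed for the wrist task (|angle| < 120°).
- `estimate_static_drift` rejects series at or below the documented
  sample-count bound, naming it.
- `trim_startup` (default 1 s; the stated "small section" is not quantified)
  drops `round(trim * fs)` samples from both streams, never desynchronising
  them.
- Zero accelerometer vectors make the tilt undefined and raise an error
  rather than returning an arbitrary angle.
- CSV round trips are lossless at the written 6-decimal precision; a second
  round trip is bitwise exact.
- Equal-frequency OneR bins merge until each holds ≥ 6 training instances;
  empty test-time bins fall back to the majority class.
- All stochastic components (simulator noise, cohort jitter, fold shuffles,
  forest/MLP fits) run on seeds derived from the caller's seed through an
  isolated RNG stream, so no package function perturbs the caller's
  `.Random.seed`.

## Known limitations

- The accelerometer model omits motion acceleration; real tilt observations
  degrade during fast movement, so real-world fusion error will be larger
  than the simulated envelopes.
- The SG-based rate calibration attenuates sharp velocity transients at the
  default window; shorten `sg_window` for brisk tasks.
- Single-axis kinematics only: out-of-plane wrist motion (radial/ulnar
  deviation) is not modelled and would alias into the X–Z tilt.
- The synthetic class contrast is an artifact parameter, not an estimate of
  clinical effect sizes; benchmark numbers on synthetic cohorts do not
  transfer to clinical recordings.
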