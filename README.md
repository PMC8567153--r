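# imuwrist

Wrist joint-angle estimation from two body-worn inertial measurement units
(IMUs), and classification of reduced, cerebral-palsy-like wrist movement —
with a built-in synthetic motion simulator so the whole pipeline can be
exercised and validated end to end.

## Who this is for

Clinical movement scientists and biomedical engineers who want to replace (or
complement) goniometric measurement of active wrist range of motion with two
small 9-axis IMUs — one on the back of the hand, one just above the wrist,
mounted with parallel Y/Z axes — and who want a reproducible benchmark of how
well standard machine-learning classifiers separate atypical from typical
movement using frequency-domain features of the raw signals.

## The method

**Joint angle.** Each sensor's orientation about the shared Y axis is tracked
by a first-order complementary filter blending two observations:

- accelerometer tilt on the X–Z plane, `β = atan2(a_x, a_z)` (degrees);
- the gyroscope rate, drift-corrected by subtracting the average static
  drift `ω̄` (the mean over *m* windows of 100 samples, window *j* starting
  at sample *n + j·r*; the series must exceed `n + (m−1)r + 100m` samples)
  and calibrated with a Savitzky–Golay smoother.

The update is

```
σ(i+1) = h · (σ(i) + ω_gf(i+1)·Δt) + l · β(i+1),   h + l = 1
```

with defaults `h = 0.98`, `l = 0.02`, `Δt = 1/100 s`. The wrist angle is the
difference of the two sensors' filtered orientations; its maximum and range
summarise active range of motion.

**Features & benchmark.** Every channel (2 sensors × 9 axes) of a trimmed
trial is Fourier-transformed (fundamental frequency `1/t_total`); the
amplitude, phase and frequency of the five dominant harmonics per channel
form a canonical 1×270 feature vector. A classifier suite (native ZeroR and
OneR baselines; naive Bayes, ridge logistic regression, C4.5-style tree,
random forest, SVM, MLP, 1-NN via standard R implementations) is evaluated
under stratified 10-fold cross-validation with pooled accuracy, ROC curves
and class-weighted AUC.

**Simulator.** `generate_stop_sign_profile()` builds rest–ramp–hold–ramp–rest
"stop sign" trajectories (cosine-blended trapezoidal velocity, exact peak
angle and peak speed); `synthesize_recording()` turns them into two 9-axis
streams with gravity projection, gyro bias + slow drift, and sensor noise;
`generate_cohort()` produces labelled CP-like vs typical cohorts with a
configurable kinematic contrast.

## Worked example

```r
library(imuwrist)

# one synthetic stop-sign trial: 70° peak at 35°/s, default sensor noise
pr <- generate_stop_sign_profile(duration = 20, peak_angle = 70, speed = 35)
tr <- synthesize_recording(pr, sensor_noise_model(), seed = 42, label = 0L)
tr <- trim_startup(tr, 1)

trial_joint_angle(tr)
#> <joint_angle_series> 1901 samples  max=70.07 deg  range=70.32 deg

round(build_feature_vector(tr)[c(1, 91, 181)], 3)
#> A_hand_ax_h1 P_hand_ax_h1 F_hand_ax_h1
#>        0.368       -2.662        0.053

# a small labelled cohort and the classifier benchmark
trials <- generate_cohort(cohort_spec(n_cp = 30, n_typical = 30, seed = 1))
d <- build_dataset(lapply(trials, trim_startup, 1))
run_cv(d, c("ZeroR", "OneR", "RandomForest", "KNN"), cv_config(k = 10, seed = 1))
#> <benchmark_table>
#>    classifier accuracy   auc
#>         ZeroR    50.00 0.500
#>          OneR    96.67 0.957
#>  RandomForest   100.00 1.000
#>           KNN   100.00 1.000
#>       Average    98.89 0.986
```

The fused series recovers the commanded 70° peak to within a tenth of a
degree despite gyro bias, drift and noise. The feature values shown are the
dominant-harmonic amplitude (g), phase (radians) and frequency (Hz) of the
hand accelerometer X channel. On the default synthetic contrast the baseline
ZeroR sits at the majority fraction (50% here) while feature-based
classifiers separate the classes nearly perfectly — a pipeline sanity check,
not a clinical claim.

A full run directory (per-trial joint-angle CSVs, ROM table, 270-column
feature matrix, ARFF export, benchmark and ROC CSVs, run manifest) comes from
`run_pipeline(pipeline_config())`, or from the thin CLI in
`inst/cli/imuwrist.R` (`simulate`, `angle`, `featurize`, `bench`, `run-all`
subcommands).

## Documentation

See the methods vignette (`vignettes/imuwrist-methods.Rmd`) for the model,
the simulator's assumptions and limits, the feature-layout conventions, and
every numerical default with its rationale.
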