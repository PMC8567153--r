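# Complementary-filter sensor fusion for the two-sensor wrist-angle method:
# accelerometer tilt observations, gyroscope static-drift estimation and
# Savitzky-Golay calibration, per-sensor orientation tracking, and the
# inter-sensor joint angle with range-of-motion summaries.

#' Accelerometer tilt angle on the X-Z plane
#'
#' Four-quadrant arctangent of the gravity vector's projection on the sensor
#' X-Z plane: `atan2(a_x, a_z)` in degrees. At the neutral posture (gravity
#' along +Z) the tilt is 0; a quarter rotation about Y gives 90.
#'
#' @param a_x,a_z accelerometer X and Z readings, g (vectorised).
#' @return Tilt angle(s) in degrees, in (-180, 180].
#' @examples
#' accel_tilt(0.5, sqrt(3) / 2) # 30
#' @export
accel_tilt <- function(a_x, a_z) {
  if (any(a_x == 0 & a_z == 0))
    stop("tilt undefined for zero acceleration vector", call. = FALSE)
  ang <- atan2(a_x, a_z) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)
}

#' Projected tilt angles on all three planes
#'
#' The X-Z plane angle `beta` (the primary tilt that drives the joint
#' measurement) together with the Y-Z and Z-Y plane projections, computed from
#' one accelerometer sample or vectors of samples.
#'
#' @param a_x,a_y,a_z accelerometer readings, g.
#' @return A list with components `beta` (= `theta_zx`), `theta_yz`, `theta_zy`
#'   in degrees.
#' @export
tilt_angles <- function(a_x, a_y, a_z) {
  list(beta = accel_tilt(a_x, a_z),
       theta_zx = accel_tilt(a_x, a_z),
       theta_yz = atan2(a_y, a_z) * 180 / pi,
       theta_zy = atan2(a_z, a_y) * 180 / pi)
}

#' Gyroscope drift-estimation configuration
#'
#' Static drift is estimated as the mean gyro reading over `m` windows of
#' `window_len` (fixed at 100) samples, window `j` starting at sample
#' `n + j*r` (0-based). The series must be longer than
#' `n + (m - 1) * r + 100 * m` samples. Residual slow drift and measurement
#' noise are calibrated with a Savitzky-Golay filter of length `sg_window`
#' and polynomial order `sg_order`.
#'
#' @param n start offset of the first static window, samples (>= 0).
#' @param m number of static windows (> 3).
#' @param r stride between window starts, samples.
#' @param sg_window Savitzky-Golay window length, samples (odd).
#' @param sg_order Savitzky-Golay polynomial order (< `sg_window`).
#' @return An object of class `drift_config`.
#' @export
drift_config <- function(n = 0L, m = 5L, r = 100L,
                         sg_window = 51L, sg_order = 3L) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (m <= 3) stop("m must be larger than 3", call. = FALSE)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  if (sg_window < 3 || sg_window %% 2 == 0)
    stop("sg_window must be an odd integer >= 3", call. = FALSE)
  if (sg_order >= sg_window)
    stop("sg_order must be smaller than sg_window", call. = FALSE)
  structure(list(n = as.integer(n), m = as.integer(m), r = as.integer(r),
                 window_len = 100L, sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order)),
            class = "drift_config")
}

#' Minimum series length required by a drift configuration
#' @param cfg a [drift_config()].
#' @return The sample-count bound `n + (m - 1) * r + 100 * m`; series must be
#'   strictly longer.
#' @export
drift_sample_bound <- function(cfg) {
  cfg$n + (cfg$m - 1L) * cfg$r + cfg$window_len * cfg$m
}

#' Estimate the average static gyroscope drift (bias)
#'
#' Mean of the gyro readings over `m` windows of 100 samples taken from the
#' stationary early portion of the series, window `j` starting at sample
#' `n + j*r` (0-based).
#'
#' @param gyro angular-velocity series for one axis, degrees/second.
#' @param cfg a [drift_config()].
#' @return The average static drift, degrees/second (scalar).
#' @export
estimate_static_drift <- function(gyro, cfg = drift_config()) {
  bound <- drift_sample_bound(cfg)
  if (length(gyro) <= bound)
    stop(sprintf(
      "series of %d samples too short: must exceed n + (m-1)r + 100m = %d",
      length(gyro), bound), call. = FALSE)
  acc <- 0
  for (j in seq_len(cfg$m) - 1L) {
    start <- cfg$n + j * cfg$r + 1L # 1-based
    acc <- acc + sum(gyro[start:(start + cfg$window_len - 1L)])
  }
  acc / (cfg$m * cfg$window_len)
}

#' Drift-correct and calibrate a gyroscope series
#'
#' Subtracts the average static drift and applies a Savitzky-Golay filter to
#' calibrate the moving angular-velocity estimate (local least-squares
#' polynomial smoothing that suppresses measurement noise and jitter while
#' preserving the motion waveform):
#' `omega_gf = SG(omega_raw) - omega_bar_static`.
#'
#' @param gyro raw angular-velocity series, degrees/second.
#' @param drift average static drift (from [estimate_static_drift()]), or
#'   `NULL` to estimate it from `gyro` with `cfg`.
#' @param cfg a [drift_config()].
#' @return Corrected angular-velocity series `omega_gf`, same length as input.
#' @export
correct_gyro <- function(gyro, drift = NULL, cfg = drift_config()) {
  if (cfg$sg_window > length(gyro))
    stop("sg_window exceeds the series length", call. = FALSE)
  if (is.null(drift)) drift <- estimate_static_drift(gyro, cfg)
  smoothed <- signal::sgolayfilt(gyro, p = cfg$sg_order, n = cfg$sg_window)
  smoothed - drift
}

#' Complementary-filter configuration
#'
#' First-order fusion weights: high-pass factor `h` on the gyro-integrated
#' path and low-pass factor `l = 1 - h` on the accelerometer tilt observation.
#' The constraint `h + l = 1` is enforced at construction, so violating
#' configurations cannot be built.
#'
#' @param h high-pass factor in `[0, 1]`.
#' @param l low-pass factor; must equal `1 - h` (supplied for explicitness,
#'   defaults to `1 - h`).
#' @param dt sampling interval, seconds.
#' @param init_angle initial filtered angle, degrees; `NA` means initialise
#'   from the first accelerometer tilt observation.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(h = 0.98, l = 1 - h, dt = 0.01, init_angle = NA) {
  if (h < 0 || h > 1) stop("h must lie in [0, 1]", call. = FALSE)
  if (abs(h + l - 1) > .Machine$double.eps * 4)
    stop("high-pass and low-pass factors must satisfy h + l = 1", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(h = h, l = 1 - h, dt = dt, init_angle = init_angle),
            class = "fusion_config")
}

#' One complementary-filter update
#'
#' `sigma_next = h * (sigma_prev + omega_gfc * dt) + l * theta_ab`: the
#' previous filtered angle advanced by the drift-corrected gyro rate, blended
#' with the current accelerometer-plane angle.
#'
#' @param sigma_prev previous filtered angle, degrees.
#' @param omega_gfc drift-corrected angular rate about the filter axis,
#'   degrees/second.
#' @param theta_ab current accelerometer angle on the a-b plane, degrees.
#' @param cfg a [fusion_config()].
#' @return The updated filtered angle, degrees.
#' @export
complementary_step <- function(sigma_prev, omega_gfc, theta_ab, cfg) {
  stopifnot(inherits(cfg, "fusion_config"))
  cfg$h * (sigma_prev + omega_gfc * cfg$dt) + cfg$l * theta_ab
}

#' Track the orientation of one sensor
#'
#' Runs the full per-sensor chain: accelerometer tilt observations on the X-Z
#' plane, static-drift estimation and Savitzky-Golay calibration of the Y-axis
#' gyro (rotation about Y moves the X-Z plane angle), then the complementary
#' filter iterated over all samples. The Y-Z and Z-Y projected angles are
#' returned alongside for inspection; only the X-Z angle is filtered.
#'
#' @param sensor a 9-channel data frame (one sensor of a `raw_trial`).
#' @param fs sampling rate, Hz.
#' @param cfg a [fusion_config()]; its `dt` is overridden by `1/fs`.
#' @param drift_cfg a [drift_config()].
#' @return An object of class `orientation_state`: list with `sigma` (filtered
#'   X-Z angle per sample, degrees), `theta_acc` (raw accelerometer tilt),
#'   `omega_gf` (corrected gyro rate), `theta_yz`, `theta_zy`.
#' @export
track_orientation <- function(sensor, fs, cfg = fusion_config(),
                              drift_cfg = drift_config()) {
  cfg$dt <- 1 / fs
  tilts <- tilt_angles(sensor$ax, sensor$ay, sensor$az)
  omega <- correct_gyro(sensor$gy, drift = NULL, cfg = drift_cfg)
  n <- length(omega)
  sigma <- numeric(n)
  sigma[1] <- if (is.na(cfg$init_angle)) tilts$beta[1] else cfg$init_angle
  h <- cfg$h; l <- cfg$l; dt <- cfg$dt
  theta <- tilts$beta
  for (i in seq_len(n - 1L))
    sigma[i + 1L] <- h * (sigma[i] + omega[i + 1L] * dt) + l * theta[i + 1L]
  structure(list(sigma = sigma, theta_acc = theta, omega_gf = omega,
                 theta_yz = tilts$theta_yz, theta_zy = tilts$theta_zy),
            class = "orientation_state")
}

#' Joint angle as the inter-sensor orientation difference
#'
#' The wrist joint angle is the hand sensor's filtered orientation minus the
#' forearm sensor's, per sample, with range-of-motion summaries.
#'
#' @param hand,forearm `orientation_state` objects of equal length.
#' @param t optional time vector, seconds (default: sample index / implied).
#' @param fs sampling rate used to build `t` when `t` is missing, Hz.
#' @return An object of class `joint_angle_series`: `t`, `angle` (degrees),
#'   `max_angle`, `range`.
#' @export
joint_angle <- function(hand, forearm, t = NULL, fs = 100) {
  if (length(hand$sigma) != length(forearm$sigma))
    stop("orientation series lengths differ; streams not aligned", call. = FALSE)
  ang <- hand$sigma - forearm$sigma
  if (is.null(t)) t <- (seq_along(ang) - 1) / fs
  structure(list(t = t, angle = ang,
                 max_angle = max(ang), range = max(ang) - min(ang)),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d samples  max=%.2f deg  range=%.2f deg\n",
              length(x$angle), x$max_angle, x$range))
  invisible(x)
}

#' Full fusion pipeline for one trial
#'
#' Convenience wrapper: tracks both sensors of a (trimmed) trial and returns
#' the joint-angle series.
#'
#' @param trial a `raw_trial`.
#' @param cfg a [fusion_config()].
#' @param drift_cfg a [drift_config()].
#' @return A `joint_angle_series`.
#' @export
trial_joint_angle <- function(trial, cfg = fusion_config(),
                              drift_cfg = drift_config()) {
  stopifnot(inherits(trial, "raw_trial"))
  hand <- track_orientation(trial$hand, trial$fs, cfg, drift_cfg)
  fore <- track_orientation(trial$forearm, trial$fs, cfg, drift_cfg)
  joint_angle(hand, fore, fs = trial$fs)
}

#' Peak-angle error experiment (robotic-rig style validation on the simulator)
#'
#' Simulates repeated stop-sign movements to predetermined peak angles, runs
#' the full fusion pipeline on each synthetic recording, and returns the mean
#' signed error between the detected and true peak joint angle. In
#' `"one-static"` mode the forearm sensor is stationary; in `"both-moving"`
#' mode both sensors rotate (the forearm sweeps a half-amplitude counter
#' rotation at the same speed) while the relative angle still reaches the
#' commanded peak.
#'
#' @param speeds peak angular velocities to test, degrees/second.
#' @param peak_angles predetermined peak angles, degrees.
#' @param mode `"one-static"` or `"both-moving"`.
#' @param n_trials number of simulated trials (peaks and speeds are cycled).
#' @param noise a `sensor_noise_model`.
#' @param seed integer seed.
#' @param duration trial length, seconds.
#' @param trim_seconds startup trim applied before fusion, seconds.
#' @param cfg,drift_cfg fusion and drift configurations.
#' @return A list: `mean_error` (mean detected - true, degrees), `errors`
#'   (per-trial signed errors), `n_trials`.
#' @export
peak_angle_error_experiment <- function(speeds = 30,
                                        peak_angles = c(30, 50, 70, 90),
                                        mode = c("one-static", "both-moving"),
                                        n_trials = 20,
                                        noise = sensor_noise_model(),
                                        seed = 1L,
                                        duration = 20,
                                        trim_seconds = 1,
                                        cfg = fusion_config(),
                                        drift_cfg = drift_config()) {
  mode <- match.arg(mode)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  rng <- .seeded_rng(seed)
  trial_seeds <- rng$int(n_trials, .Machine$integer.max)
  errors <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    peak <- peak_angles[((i - 1L) %% length(peak_angles)) + 1L]
    speed <- speeds[((i - 1L) %% length(speeds)) + 1L]
    pr <- generate_stop_sign_profile(duration = duration, peak_angle = peak,
                                     speed = speed, tremor_amplitude = 0)
    forearm_motion <- if (mode == "both-moving") -pr$theta_true / 2 else NULL
    # relative hand - forearm angle must still reach `peak`
    tr <- synthesize_recording(pr, noise, seed = trial_seeds[i],
                               forearm_motion = forearm_motion)
    tr <- trim_startup(tr, trim_seconds)
    ja <- trial_joint_angle(tr, cfg, drift_cfg)
    errors[i] <- ja$max_angle - peak
  }
  list(mean_error = mean(errors), errors = errors, n_trials = n_trials)
}
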