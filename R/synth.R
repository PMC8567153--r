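# Synthetic two-sensor motion simulator: stop-sign wrist trajectories,
# 9-axis sensor synthesis (gravity projection, gyro bias/drift, noise),
# and labelled cohorts with a configurable CP-like vs typical contrast.

GRAVITY_G <- 9.80665 # m/s^2 per g; channels are reported in g units

#' Sensor imperfection model
#'
#' Describes the additive imperfections applied when synthesising a 9-axis
#' recording from a ground-truth motion profile: white measurement noise on
#' each modality, a constant per-axis gyroscope bias ("static drift") and a
#' slow linear gyroscope drift ramp. The defaults are representative of a
#' consumer MEMS IMU and are the conditions under which the fusion pipeline's
#' error envelopes are assessed.
#'
#' @param accel_noise_sd accelerometer noise standard deviation, g.
#' @param gyro_noise_sd gyroscope noise standard deviation, degrees/second.
#' @param gyro_static_bias constant gyro bias per axis (length-3, x/y/z),
#'   degrees/second.
#' @param gyro_drift_rate slope of the slow linear gyro drift, degrees/second^2
#'   (the same ramp is applied to all three axes).
#' @param mag_field ambient magnetic field in the world frame (length-3), uT.
#' @param mag_noise_sd magnetometer noise standard deviation, uT.
#' @return An object of class `sensor_noise_model`.
#' @export
sensor_noise_model <- function(accel_noise_sd = 0.01,
                               gyro_noise_sd = 0.2,
                               gyro_static_bias = c(0.5, -0.3, 0.4),
                               gyro_drift_rate = 0.005,
                               mag_field = c(22, 5, -42),
                               mag_noise_sd = 0.5) {
  if (accel_noise_sd < 0 || gyro_noise_sd < 0 || mag_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (length(gyro_static_bias) == 1L) gyro_static_bias <- rep(gyro_static_bias, 3L)
  if (length(mag_field) != 3L || length(gyro_static_bias) != 3L)
    stop("gyro_static_bias and mag_field must have length 3", call. = FALSE)
  structure(list(accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd,
                 gyro_static_bias = gyro_static_bias,
                 gyro_drift_rate = gyro_drift_rate,
                 mag_field = mag_field,
                 mag_noise_sd = mag_noise_sd),
            class = "sensor_noise_model")
}

#' Noise-free sensor model
#'
#' Convenience constructor: all noise standard deviations, biases and drift
#' rates set to zero. Used for ground-truth consistency checks.
#' @return A `sensor_noise_model` with every imperfection zeroed.
#' @export
noise_free <- function() {
  sensor_noise_model(accel_noise_sd = 0, gyro_noise_sd = 0,
                     gyro_static_bias = c(0, 0, 0), gyro_drift_rate = 0,
                     mag_noise_sd = 0)
}

#' Generate a stop-sign wrist motion profile
#'
#' Ground-truth joint-angle trajectory for the stop-sign task: the wrist starts
#' at rest (0 degrees), extends smoothly to `peak_angle`, holds, and returns to
#' rest. The angular-velocity profile is a cosine-blended trapezoid, so the
#' peak angular velocity equals `speed` exactly and the peak angle is reached
#' in closed form. A rest period precedes the movement (used downstream for
#' static gyro-drift estimation) and follows it. An optional tremor sinusoid
#' of amplitude `tremor_amplitude` at `tremor_frequency` is superposed on the
#' whole trajectory.
#'
#' Timing layout within `duration`: ramp time is
#' `T_r = peak_angle / speed + T_b` where `T_b` is the cosine blend time
#' (0.3 s, shortened for very quick ramps). The remainder of the trial is
#' split into a hold at the peak (at most 1.5 s), a leading rest (at most 6 s)
#' and a trailing rest.
#'
#' @param duration total trial length, seconds.
#' @param peak_angle target peak joint angle, degrees.
#' @param speed peak angular velocity of the ramp, degrees/second.
#' @param tremor_amplitude tremor sinusoid amplitude, degrees (0 disables).
#' @param tremor_frequency tremor frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return An object of class `motion_profile` with fields `t` (seconds),
#'   `theta_true` (degrees), `omega_true` (degrees/second), `fs`, `task_name`
#'   and the realised `peak_angle`.
#' @examples
#' pr <- generate_stop_sign_profile(duration = 5, peak_angle = 70, speed = 35)
#' max(pr$theta_true) # 70
#' @export
generate_stop_sign_profile <- function(duration,
                                       peak_angle,
                                       speed,
                                       tremor_amplitude = 0,
                                       tremor_frequency = 5,
                                       fs = 100) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (speed <= 0) stop("speed must be > 0", call. = FALSE)
  if (peak_angle <= 0 || peak_angle > 120)
    stop("peak_angle must lie in (0, 120] degrees", call. = FALSE)
  if (tremor_frequency >= fs / 2)
    stop("tremor_frequency must be below the Nyquist rate fs/2", call. = FALSE)

  t_b <- min(0.3, 0.25 * peak_angle / speed)
  t_r <- peak_angle / speed + t_b
  avail <- duration - 2 * t_r
  if (avail < 0)
    stop(sprintf(
      "duration %.3g s too short for ramps of %.3g s at %.3g deg/s to %.3g deg",
      duration, t_r, speed, peak_angle), call. = FALSE)
  hold <- min(1.5, 0.3 * avail)
  rest <- avail - hold
  lead <- min(6, 0.75 * rest)

  t <- seq(0, duration, by = 1 / fs)
  # phase boundaries: [rest | up-ramp | hold | down-ramp | rest]
  t1 <- lead
  t2 <- t1 + t_r
  t3 <- t2 + hold
  t4 <- t3 + t_r

  ramp <- function(tau) .blended_ramp(tau, t_r, t_b, speed, peak_angle)
  theta <- numeric(length(t))
  omega <- numeric(length(t))
  up <- t > t1 & t <= t2
  hd <- t > t2 & t <= t3
  dn <- t > t3 & t <= t4
  r_up <- ramp(t[up] - t1)
  theta[up] <- r_up$theta; omega[up] <- r_up$omega
  theta[hd] <- peak_angle
  r_dn <- ramp(t4 - t[dn])
  theta[dn] <- r_dn$theta; omega[dn] <- -r_dn$omega

  if (tremor_amplitude > 0) {
    theta <- theta + tremor_amplitude * sin(2 * pi * tremor_frequency * t)
    omega <- omega + tremor_amplitude * 2 * pi * tremor_frequency *
      cos(2 * pi * tremor_frequency * t)
  }

  structure(list(t = t, theta_true = theta, omega_true = omega, fs = fs,
                 task_name = "stop_sign", peak_angle = peak_angle,
                 speed = speed),
            class = "motion_profile")
}

# Closed-form cosine-blended trapezoidal velocity ramp evaluated at tau in
# [0, t_r]: velocity rises over t_b, plateaus at `speed`, falls over t_b;
# the swept angle at t_r equals `peak` = speed * (t_r - t_b) exactly.
.blended_ramp <- function(tau, t_r, t_b, speed, peak) {
  theta <- numeric(length(tau))
  omega <- numeric(length(tau))
  a <- tau <= t_b
  b <- tau > t_b & tau <= t_r - t_b
  c_ <- tau > t_r - t_b
  omega[a] <- speed * 0.5 * (1 - cos(pi * tau[a] / t_b))
  theta[a] <- speed * (tau[a] / 2 - (t_b / (2 * pi)) * sin(pi * tau[a] / t_b))
  omega[b] <- speed
  theta[b] <- speed * t_b / 2 + speed * (tau[b] - t_b)
  rem <- t_r - tau[c_]
  omega[c_] <- speed * 0.5 * (1 - cos(pi * rem / t_b))
  theta[c_] <- peak - speed * (rem / 2 - (t_b / (2 * pi)) * sin(pi * rem / t_b))
  list(theta = theta, omega = omega)
}

#' @export
print.motion_profile <- function(x, ...) {
  cat(sprintf("<motion_profile> task=%s  %.1f s @ %g Hz  peak=%.1f deg\n",
              x$task_name, max(x$t), x$fs, max(x$theta_true)))
  invisible(x)
}

#' Synthesise a two-sensor 9-axis recording from a motion profile
#'
#' Emulates the paper-style geometry: both sensors share parallel Y and Z axes;
#' the forearm sensor stays level while the hand sensor rotates about the
#' shared Y axis by the true joint angle. Accelerometers report the gravity
#' vector projected through each sensor's orientation (in g); gyroscopes
#' report the true angular rate about Y (hand) or zero (forearm) plus static
#' bias, a slow linear drift ramp and white noise; magnetometers report the
#' fixed ambient field rotated into the sensor frame plus noise.
#'
#' @param profile a `motion_profile`.
#' @param noise a `sensor_noise_model`.
#' @param seed integer seed for the measurement-noise generator.
#' @param label optional class label (0 typical, 1 CP-like) carried on the trial.
#' @param forearm_motion optional vector of forearm rotation angles (degrees)
#'   about the shared Y axis, same length as the profile; used by the
#'   both-sensors-moving validation mode. Default: forearm stationary.
#' @return A `raw_trial` (see [raw_trial()]).
#' @export
synthesize_recording <- function(profile, noise = sensor_noise_model(),
                                 seed = 1L, label = NULL,
                                 forearm_motion = NULL) {
  if (!inherits(profile, "motion_profile")) stop("profile must be a motion_profile",
                                                 call. = FALSE)
  n <- length(profile$t)
  if (n == 0L) stop("empty profile", call. = FALSE)
  if (is.null(forearm_motion)) forearm_motion <- numeric(n)
  if (length(forearm_motion) != n)
    stop("forearm_motion must match the profile length", call. = FALSE)

  hand_theta <- profile$theta_true + forearm_motion
  hand_omega <- profile$omega_true + .fd_deriv(forearm_motion, profile$fs)
  fore_theta <- forearm_motion
  fore_omega <- .fd_deriv(forearm_motion, profile$fs)

  rng <- .seeded_rng(seed)
  hand <- .sensor_stream(hand_theta, hand_omega, profile$t, noise, rng)
  fore <- .sensor_stream(fore_theta, fore_omega, profile$t, noise, rng)

  raw_trial(fs = profile$fs, hand = hand, forearm = fore, label = label,
            meta = list(task = profile$task_name,
                        true_peak = max(profile$theta_true)))
}

# One 9-axis stream for a sensor rotated by theta (degrees) about the shared
# Y axis. Gravity convention: at theta = 0 the accelerometer reads (0, 0, 1) g,
# and atan2(a_x, a_z) recovers theta. No motion (tangential/centripetal)
# acceleration is modelled: the accelerometer sees gravity only.
.sensor_stream <- function(theta_deg, omega_deg_s, t, noise, rng) {
  th <- theta_deg * pi / 180
  n <- length(t)
  ax <- sin(th); ay <- numeric(n); az <- cos(th)
  gx <- numeric(n); gy <- omega_deg_s; gz <- numeric(n)
  # world field rotated into the sensor frame (rotation about Y by -theta)
  mf <- noise$mag_field
  mx <- mf[1] * cos(th) - mf[3] * sin(th)
  my <- rep(mf[2], n)
  mz <- mf[1] * sin(th) + mf[3] * cos(th)

  drift <- noise$gyro_drift_rate * t
  b <- noise$gyro_static_bias
  data.frame(
    ax = ax + rng$norm(n, noise$accel_noise_sd),
    ay = ay + rng$norm(n, noise$accel_noise_sd),
    az = az + rng$norm(n, noise$accel_noise_sd),
    gx = gx + b[1] + drift + rng$norm(n, noise$gyro_noise_sd),
    gy = gy + b[2] + drift + rng$norm(n, noise$gyro_noise_sd),
    gz = gz + b[3] + drift + rng$norm(n, noise$gyro_noise_sd),
    mx = mx + rng$norm(n, noise$mag_noise_sd),
    my = my + rng$norm(n, noise$mag_noise_sd),
    mz = mz + rng$norm(n, noise$mag_noise_sd)
  )
}

# central finite difference, degrees/s
.fd_deriv <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# Local RNG stream isolated from the global .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  list(
    norm = function(n, sd) {
      if (sd == 0) return(numeric(n))
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      x <- stats::rnorm(n, 0, sd)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
      x
    },
    runif = function(n, min = 0, max = 1) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      x <- stats::runif(n, min, max)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
      x
    },
    int = function(n, max) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      x <- sample.int(max, n, replace = TRUE)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
      x
    }
  )
}

#' Cohort specification for the synthetic classification benchmark
#'
#' Defines a two-class cohort of stop-sign trials: a CP-like class with reduced
#' peak angle, slower movement and a tremor component, and a typical class.
#' Per-trial kinematic jitter (peak angle sd 5 degrees, speed sd 10% of the
#' class mean) is drawn from a generator seeded by `seed`, so identical specs
#' produce identical cohorts.
#'
#' @param n_cp number of CP-like trials (label 1).
#' @param n_typical number of typical trials (label 0).
#' @param cp_peak_angle,typical_peak_angle class mean peak angles, degrees.
#' @param cp_speed,typical_speed class mean peak angular velocities, deg/s.
#' @param tremor_amplitude tremor amplitude for the CP-like class, degrees.
#' @param tremor_frequency tremor frequency, Hz.
#' @param duration trial length, seconds.
#' @param fs sampling rate, Hz.
#' @param noise a `sensor_noise_model` shared by all trials.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cp = 100, n_typical = 100,
                        cp_peak_angle = 40, typical_peak_angle = 70,
                        cp_speed = 20, typical_speed = 40,
                        tremor_amplitude = 2, tremor_frequency = 5,
                        duration = 15, fs = 100,
                        noise = sensor_noise_model(), seed = 1L) {
  if (n_cp < 0 || n_typical < 0) stop("counts must be >= 0", call. = FALSE)
  if (n_cp + n_typical == 0) stop("cohort must contain at least one trial", call. = FALSE)
  for (p in c(cp_peak_angle, typical_peak_angle))
    if (p <= 0 || p > 120) stop("peak angles must lie in (0, 120] degrees", call. = FALSE)
  if (tremor_frequency >= fs / 2)
    stop("tremor_frequency must be below fs/2", call. = FALSE)
  structure(list(n_cp = n_cp, n_typical = n_typical,
                 cp_peak_angle = cp_peak_angle,
                 typical_peak_angle = typical_peak_angle,
                 cp_speed = cp_speed, typical_speed = typical_speed,
                 tremor_amplitude = tremor_amplitude,
                 tremor_frequency = tremor_frequency,
                 duration = duration, fs = fs, noise = noise,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labelled cohort of synthetic trials
#'
#' Produces exactly `n_cp` trials labelled 1 and `n_typical` labelled 0 (in
#' that order), each a stop-sign trial with class-specific kinematics plus
#' seeded trial-to-trial jitter. Identical specs (including seed) generate
#' identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return A list of `raw_trial` objects with labels attached.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rng <- .seeded_rng(spec$seed)
  n_tot <- spec$n_cp + spec$n_typical
  labels <- c(rep(1L, spec$n_cp), rep(0L, spec$n_typical))
  seeds <- rng$int(n_tot, .Machine$integer.max)
  trials <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    cp <- labels[i] == 1L
    mean_peak <- if (cp) spec$cp_peak_angle else spec$typical_peak_angle
    mean_speed <- if (cp) spec$cp_speed else spec$typical_speed
    peak <- min(120, max(5, mean_peak + rng$norm(1, 5)))
    speed <- max(2, mean_speed * (1 + rng$norm(1, 0.1)))
    trem <- if (cp) spec$tremor_amplitude else 0
    pr <- generate_stop_sign_profile(duration = spec$duration,
                                     peak_angle = peak, speed = speed,
                                     tremor_amplitude = trem,
                                     tremor_frequency = spec$tremor_frequency,
                                     fs = spec$fs)
    trials[[i]] <- synthesize_recording(pr, spec$noise, seed = seeds[i],
                                        label = labels[i])
    trials[[i]]$meta$trial_id <- sprintf("trial_%03d", i)
  }
  trials
}
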