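# Sensor fusion: tilt, drift estimation and correction, complementary filter,
# joint angle, and the peak-angle validation experiment.

test_that("accelerometer tilt is the four-quadrant X-Z arctangent", {
  expect_equal(accel_tilt(0, 1), 0)
  expect_equal(accel_tilt(1, 0), 90)
  # independent arctangent oracle
  expect_equal(accel_tilt(0.5, 0.8660254), atan(0.5 / 0.8660254) * 180 / pi,
               tolerance = 1e-7)
  expect_equal(accel_tilt(0.5, 0.8660254), 30, tolerance = 1e-5)
  expect_equal(accel_tilt(0, -1), 180) # angles live in (-180, 180]
  expect_equal(accel_tilt(-1, 0), -90)
  expect_error(accel_tilt(0, 0), "undefined")
})

test_that("static drift estimation averages the configured windows", {
  cfg <- drift_config(n = 0, m = 5, r = 100)
  expect_equal(estimate_static_drift(rep(0.7, 1000), cfg), 0.7)

  set.seed(42)
  g <- 0.5 + rnorm(1000, sd = 0.1)
  est <- estimate_static_drift(g, cfg)
  # brute-force mean oracle over the identical windows
  expect_equal(est, window_mean_oracle(g, 0, 5, 100))
  expect_lt(abs(est - 0.5), 3 * 0.1 / sqrt(500))

  # overlapping-window layout (r < 100) still follows the window formula
  cfg2 <- drift_config(n = 10, m = 4, r = 50)
  set.seed(7)
  g2 <- rnorm(1200)
  expect_equal(estimate_static_drift(g2, cfg2), window_mean_oracle(g2, 10, 4, 50))
})

test_that("series at exactly the sample-count bound is rejected", {
  cfg <- drift_config(n = 0, m = 5, r = 100)
  bound <- drift_sample_bound(cfg) # n + (m-1) r + 100 m = 900
  expect_identical(bound, 900L)
  expect_error(estimate_static_drift(rep(0, bound), cfg), "900")
  expect_silent(estimate_static_drift(rep(0, bound + 1L), cfg))
})

test_that("drift configuration invariants are enforced at construction", {
  expect_error(drift_config(m = 3), "larger than 3")
  expect_error(drift_config(n = -1), ">= 0")
  expect_error(drift_config(sg_window = 50), "odd")
  expect_error(drift_config(sg_window = 0), "odd")
  expect_error(drift_config(sg_window = 5, sg_order = 5), "smaller")
})

test_that("gyro correction removes bias and preserves the motion waveform", {
  cfg <- drift_config()
  bias_only <- rep(0.8, 2000)
  out <- correct_gyro(bias_only, cfg = cfg)
  expect_lt(max(abs(out)), 1e-9)

  # bandlimited motion: the SG smoother passes the waveform through
  t <- seq(0, 20, by = 0.01)
  signal_true <- 30 * sin(2 * pi * 0.3 * t)
  out2 <- correct_gyro(signal_true + 0.8, drift = 0.8, cfg = cfg)
  expect_lt(max(abs(out2 - signal_true)), 0.2) # within SG filter tolerance
  expect_length(out2, length(signal_true))

  expect_error(correct_gyro(rep(0, 10), drift = 0, cfg = cfg), "sg_window")
})

test_that("complementary step blends gyro integration with accel tilt", {
  cfg <- fusion_config(h = 0.98, dt = 0.01)
  expect_equal(complementary_step(10, 0, 10, cfg), 10) # fixed point
  expect_equal(complementary_step(0, 5, 0, fusion_config(h = 1, dt = 0.01)), 0.05)
  expect_equal(complementary_step(0, 999, 42, fusion_config(h = 0, dt = 0.01)), 42)
})

test_that("violating h + l = 1 is unconstructible", {
  expect_error(fusion_config(h = 0.9, l = 0.2), "h \\+ l = 1")
  expect_error(fusion_config(h = 1.2), "\\[0, 1\\]")
  expect_error(fusion_config(h = 0.98, dt = 0), "dt")
  cfg <- fusion_config(h = 0.95)
  expect_equal(cfg$h + cfg$l, 1)
})

test_that("fixed point: agreeing gyro and accel observations pass through", {
  # if the tilt observation stays at sigma and the gyro rate is zero, the
  # filter output equals both exactly, for any h
  for (h in c(0, 0.5, 0.98, 1)) {
    cfg <- fusion_config(h = h, dt = 0.01)
    sigma <- 25
    for (i in 1:50) sigma <- complementary_step(sigma, 0, 25, cfg)
    expect_equal(sigma, 25)
  }
})

test_that("a static noise-free sensor tracks zero orientation", {
  pr <- generate_stop_sign_profile(15, 70, 35)
  pr$theta_true[] <- 0; pr$omega_true[] <- 0
  tr <- synthesize_recording(pr, noise_free(), seed = 1)
  st <- track_orientation(tr$hand, tr$fs)
  expect_lt(max(abs(st$sigma)), 1e-6)
})

test_that("orientation converges to a held tilt within half a degree", {
  pr <- generate_stop_sign_profile(20, 30, 30)
  tr <- synthesize_recording(pr, noise_free(), seed = 1)
  st <- track_orientation(tr$hand, tr$fs)
  # during the hold the filter must sit on the true 30-degree angle
  hold <- which(abs(pr$theta_true - 30) < 1e-9)
  expect_lt(abs(st$sigma[max(hold)] - 30), 0.5)
})

test_that("uncorrected gyro bias grows linearly; the pipeline removes it", {
  # pure-gyro filter (h = 1) fed the biased rate without drift correction:
  # terminal error is bias * t
  bias <- 0.5; fs <- 100; dur <- 10
  cfg <- fusion_config(h = 1, dt = 1 / fs)
  sigma <- 0
  for (i in seq_len(dur * fs)) sigma <- complementary_step(sigma, bias, 0, cfg)
  expect_equal(sigma, bias * dur, tolerance = 1e-9)

  # the full chain (drift estimation + complementary blending) stays near zero
  pr <- generate_stop_sign_profile(15, 70, 35)
  pr$theta_true[] <- 0; pr$omega_true[] <- 0
  nm <- sensor_noise_model(accel_noise_sd = 0, gyro_noise_sd = 0,
                           gyro_static_bias = c(0.5, 0.5, 0.5),
                           gyro_drift_rate = 0, mag_noise_sd = 0)
  tr <- synthesize_recording(pr, nm, seed = 1)
  st <- track_orientation(tr$hand, tr$fs)
  expect_lt(max(abs(st$sigma)), 0.1)
})

test_that("joint angle is the inter-sensor difference and is antisymmetric", {
  pr <- generate_stop_sign_profile(20, 70, 35)
  tr <- synthesize_recording(pr, noise_free(), seed = 1)
  hand <- track_orientation(tr$hand, tr$fs)
  fore <- track_orientation(tr$forearm, tr$fs)

  same <- joint_angle(hand, hand, fs = tr$fs)
  expect_true(all(same$angle == 0))
  expect_equal(same$range, 0)

  ab <- joint_angle(hand, fore, fs = tr$fs)
  ba <- joint_angle(fore, hand, fs = tr$fs)
  expect_equal(ab$angle, -ba$angle)
  expect_equal(ab$range, ba$range)
  expect_equal(ab$max_angle, max(ab$angle))
  expect_equal(ab$range, max(ab$angle) - min(ab$angle))

  short <- fore; short$sigma <- short$sigma[-1]
  expect_error(joint_angle(hand, short), "aligned")
})

test_that("noise-free stop-sign trial recovers its peak within a degree", {
  pr <- generate_stop_sign_profile(20, 70, 35)
  tr <- trim_startup(synthesize_recording(pr, noise_free(), seed = 1), 1)
  ja <- trial_joint_angle(tr)
  expect_lt(abs(ja$max_angle - 70), 1)
})

test_that("end-to-end noise-free peak recovery is sub-degree at all peaks", {
  res <- peak_angle_error_experiment(speeds = c(30, 90),
                                     peak_angles = c(30, 50, 70, 90),
                                     mode = "one-static", n_trials = 20,
                                     noise = noise_free(), seed = 11)
  expect_lt(max(abs(res$errors)), 1)
  res2 <- peak_angle_error_experiment(speeds = 30, mode = "both-moving",
                                      n_trials = 8, noise = noise_free(),
                                      seed = 12)
  expect_lt(abs(res2$mean_error), 0.1)
})
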