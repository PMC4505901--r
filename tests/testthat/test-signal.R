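test_that("envelope extraction passes DC, kills zero, and is homogeneous", {
  fs <- 1000
  expect_equal(rectify_and_envelope(rep(3, 600), fs), rep(3, 600),
               tolerance = 1e-3)
  expect_equal(rectify_and_envelope(rep(0, 600), fs), rep(0, 600))
  set.seed(1)
  x <- rnorm(800)
  e1 <- rectify_and_envelope(x, fs)
  e5 <- rectify_and_envelope(5 * x, fs)
  expect_equal(e5, 5 * e1, tolerance = 1e-10)
})

test_that("envelope of a fast sine matches the rectified moving-average oracle", {
  fs <- 2000
  A <- 1.7
  t <- seq(0, 4, by = 1 / fs)
  x <- A * sin(2 * pi * 150 * t)
  env <- rectify_and_envelope(x, fs)
  interior <- env[(fs + 1):(3 * fs)]
  # oracle: moving average of the rectified signal over 1 s windows
  ma <- stats::filter(abs(x), rep(1 / fs, fs), sides = 2)
  ma <- ma[!is.na(ma)]
  expect_lt(abs(mean(interior) - mean(ma)) / mean(ma), 0.05)
  expect_lt(abs(mean(interior) - 2 * A / pi) / (2 * A / pi), 0.05)
  ripple <- max(interior) - min(interior)
  expect_lt(ripple, 0.10 * mean(interior))
})

test_that("envelope extraction rejects bad inputs", {
  expect_error(rectify_and_envelope(c(1, NA, 2), 100), "finite")
  expect_error(rectify_and_envelope(rnorm(100), 100, cutoff = 60), "Nyquist")
})

test_that("tension normalization scales, baselines, and ignores amplifier gain", {
  env <- rep(2.5, 100)
  expect_equal(normalize_tension(env, calib = 2.5), rep(1, 100))
  # envelope at the baseline level maps to zero tension
  env2 <- rep(0.8, 100)
  out <- normalize_tension(env2, calib = 2.5, central_hold = 1:20)
  expect_equal(out, rep(0, 100))
  # linearity: 2x calibration amplitude minus a 0.5 baseline
  out3 <- normalize_tension(rep(5, 100), calib = 2.5) - 0.5
  expect_equal(out3, rep(1.5, 100))
  # amplifier gain cancels when raw EMG and calibration scale together
  set.seed(2)
  e <- abs(rnorm(200)) + 0.1
  t1 <- normalize_tension(e, calib = 1.3, central_hold = 1:50)
  t2 <- normalize_tension(7 * e, calib = 7 * 1.3, central_hold = 1:50)
  expect_equal(t1, t2, tolerance = 1e-12)
  # sub-noise-floor calibration is rejected with a diagnostic
  expect_error(
    normalize_tension(e, calib = list(level = 0.1, noise_floor = 0.2)),
    "noise floor")
  # non-reference calibration torque rescales the gain
  expect_equal(normalize_tension(rep(2, 10), calib = list(level = 2,
                                                          torque_nm = 1.56)),
               rep(2, 10))
})

test_that("kinematic differentiation matches analytic derivatives", {
  fs <- 2000
  n <- 4000
  k <- differentiate_kinematics(rep(10, n), fs)
  expect_equal(k$theta, rep(10 * pi / 180, n), tolerance = 1e-12)
  expect_equal(k$vel, rep(0, n))
  expect_equal(k$acc, rep(0, n))
  # ramp: constant velocity on interior samples
  omega_deg <- 25
  t <- seq(0, 2, by = 1 / fs)
  k2 <- differentiate_kinematics(omega_deg * t, fs)
  expect_equal(k2$vel[2:(length(t) - 1)],
               rep(omega_deg * pi / 180, length(t) - 2), tolerance = 1e-9)
  expect_equal(max(abs(k2$acc[3:(length(t) - 2)])), 0, tolerance = 1e-8)
  # sine: < 1% of the analytic velocity amplitude (interior)
  f0 <- 0.5
  t <- seq(0, 6, by = 1 / fs)
  k3 <- differentiate_kinematics(180 / pi * sin(2 * pi * f0 * t), fs)
  vtrue <- 2 * pi * f0 * cos(2 * pi * f0 * t)
  i <- (fs / 2):(length(t) - fs / 2)
  expect_lt(max(abs(k3$vel[i] - vtrue[i])), 0.01 * 2 * pi * f0)
  expect_error(differentiate_kinematics(1:4, 100), "5 samples")
})

test_that("differentiate then integrate recovers the angle", {
  fs <- 500
  t <- seq(0, 5, by = 1 / fs)
  ang <- 12 * sin(2 * pi * 0.7 * t) + 4 * cos(2 * pi * 1.3 * t)
  k <- differentiate_kinematics(ang, fs)
  rebuilt <- k$theta[1] + pracma::cumtrapz(t, k$vel)
  rms_err <- sqrt(mean((rebuilt - k$theta)^2))
  expect_lt(rms_err, 0.001 * sqrt(mean(k$theta^2)))
})

test_that("movement onset is detected at the sustained threshold crossing", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  vel <- ifelse(t >= 1, pmin((t - 1) * 4, 1), 0)
  on <- detect_movement_onset(vel, fs)
  expect_gte(on, 1.0)
  expect_lte(on, 1.05)
  expect_error(detect_movement_onset(rep(0, 100), fs), "no movement")
  # noisy bell-shaped velocity with known onset at 0.8 s (SNR ~ 20 dB)
  set.seed(77)
  u <- pmin(pmax((t - 0.8) / 0.4, 0), 1)
  bell <- 30 * u^2 - 60 * u^3 + 30 * u^4
  noisy <- bell + rnorm(length(t), 0, 0.1 * stats::sd(bell))
  smoothed <- wristdecon:::zerophase_lowpass(noisy, fs, 10)
  on2 <- detect_movement_onset(smoothed, fs)
  expect_lt(abs(on2 - 0.8), 0.03)
})

test_that("trial processing zeroes the central hold and rejects bad clocks", {
  ptr <- make_step_subject(reps = 1L, seed = 11L)[[1]]
  expect_true(all(abs(colMeans(ptr$tension[ptr$hold_idx, ])) < 0.05))
  expect_true(all(is.finite(ptr$theta)) && all(is.finite(ptr$acc)))
  tr <- simulate_trial("step", list(M = REF_HAND$inertia, B = 0.02, K = 0.09),
                       direction = "RT", seed = 3L)
  tr$time <- rev(tr$time)
  expect_error(process_trial(tr), "increasing")
  tr2 <- simulate_trial("step", list(M = REF_HAND$inertia, B = 0.02, K = 0.09),
                        direction = "RT", seed = 3L)
  tr2$time <- tr2$time^1.01
  expect_error(process_trial(tr2), "non-uniform|increasing")
})

test_that("raw-EMG path reproduces the tension-envelope path", {
  # build a pseudo-raw EMG whose rectified mean equals a known envelope
  pars <- list(M = REF_HAND$inertia, B = 0.17 * 0.09, K = 0.09)
  tr <- simulate_trial("step", pars, direction = "UR", fs = 100,
                       snr_db = Inf, co_contraction = 0.05,
                       angle_noise_sd_deg = 0, hold_pre = 1.5)
  set.seed(9)
  n <- length(tr$time)
  gain <- 4.2e-4  # volts per unit tension
  carrier <- matrix(sample(c(-1, 1), n * 4, TRUE), n, 4)  # |carrier| = 1
  raw <- (tr$tension * pi / 2) * carrier * gain  # rectified mean = tension
  tr_raw <- tr
  tr_raw$tension <- NULL
  tr_raw$emg <- raw
  calib <- replicate(4, list(level = gain * pi / 2, torque_nm = 0.78),
                     simplify = FALSE)
  p_raw <- process_trial(tr_raw, calib = calib)
  p_env <- process_trial(tr)
  # same working-rate tensions up to envelope-estimation error
  expect_gt(stats::cor(p_raw$tension[, 1], p_env$tension[, 1]), 0.98)
  expect_lt(mean(abs(p_raw$tension - p_env$tension)),
            0.05 * max(abs(p_env$tension)))
})
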