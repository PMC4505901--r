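test_that("minimum-jerk steps have exact amplitude and boundary conditions", {
  for (d in c("RT", "UP", "DL")) {
    kin <- make_step_kinematics(d, amplitude_deg = 18)
    disp <- kin$angle_deg[nrow(kin$angle_deg), ] - kin$angle_deg[1, ]
    expect_equal(sqrt(sum(disp^2)), 18, tolerance = 1e-9)
    expect_equal(unname(kin$vel_deg[1, ]), c(0, 0))
    expect_equal(unname(kin$vel_deg[nrow(kin$vel_deg), ]), c(0, 0))
    expect_equal(unname(kin$acc_deg[nrow(kin$acc_deg), ]), c(0, 0))
  }
  # peak tangential speed of a minimum-jerk reach: 1.875 * amplitude/duration
  kin <- make_step_kinematics("UR", amplitude_deg = 18, move_duration = 0.4,
                              fs = 1000)
  peak <- max(sqrt(rowSums(kin$vel_deg^2)))
  expect_equal(peak, 1.875 * 18 / 0.4, tolerance = 1e-3)
})

test_that("pursuit kinematics traverse a closed path at constant speed", {
  kin <- make_pursuit_kinematics()
  n <- nrow(kin$angle_deg)
  lap_idx <- (2.8 * 100 + 30):(n - 30)  # steady tracking portion
  speed <- sqrt(rowSums(kin$vel_deg[lap_idx, ]^2))
  expect_equal(mean(speed), 6.2, tolerance = 0.01)
  expect_lt(stats::sd(speed) / mean(speed), 0.01)
  # closed: final angle returns to the path start
  expect_equal(unname(kin$angle_deg[n, ]), kin$path_start, tolerance = 1e-2)
  # traversal time equals path length / speed
  expect_equal(kin$lap_duration_s, kin$path_length_deg / 6.2,
               tolerance = 1e-6)
  # spans the advertised extents
  expect_equal(max(abs(kin$angle_deg[, 1])), 10, tolerance = 0.05)
  expect_equal(max(abs(kin$angle_deg[, 2])), 8, tolerance = 0.05)
  expect_error(make_pursuit_kinematics(x_amp = 0), "degenerate")
})

test_that("torque decomposition round-trips through muscle_torque", {
  a <- wristdecon:::default_true_weights()
  n <- 400
  set.seed(123)
  tau <- cbind(0.05 * sin(seq_len(n) / 20), 0.04 * cos(seq_len(n) / 31))
  tens <- tensions_from_torque(tau, a, co_contraction = 0, snr_db = Inf)
  expect_true(all(tens >= 0))
  expect_equal(unname(muscle_torque(tens, a)), unname(tau),
               tolerance = 1e-9)
  # zero torque: zero tensions without co-contraction, constant c with it
  z <- tensions_from_torque(matrix(0, 10, 2), a)
  expect_equal(unname(z), matrix(0, 10, 4))
  zc <- tensions_from_torque(matrix(0, 10, 2), a, co_contraction = 0.3)
  expect_equal(unname(zc), matrix(0.3, 10, 4), tolerance = 1e-9)
  expect_equal(unname(muscle_torque(zc, a)), matrix(0, 10, 2),
               tolerance = 1e-12)
  # co-contraction cancels even superposed on a torque profile
  tc <- tensions_from_torque(tau, a, co_contraction = 0.2, snr_db = Inf)
  expect_equal(unname(muscle_torque(tc, a)), unname(tau), tolerance = 1e-9)
  bad <- a; bad[2, 1] <- -bad[2, 1]  # two flexor-side x weights
  expect_error(tensions_from_torque(tau, bad), "infeasible")
})

test_that("trial simulation is deterministic under a fixed seed", {
  pars <- list(M = 0.0017, B = 0.05, K = 0.09)
  t1 <- simulate_trial("step", pars, direction = "UP", seed = 99L)
  t2 <- simulate_trial("step", pars, direction = "UP", seed = 99L)
  expect_identical(t1, t2)
  c1 <- generate_cohort(n_controls = 2, n_patients = 1, step_reps = 1L,
                        pursuit_reps = 1L, seed = 7L)
  c2 <- generate_cohort(n_controls = 2, n_patients = 1, step_reps = 1L,
                        pursuit_reps = 1L, seed = 7L)
  expect_identical(c1, c2)
  c3 <- generate_cohort(n_controls = 2, n_patients = 1, step_reps = 1L,
                        pursuit_reps = 1L, seed = 8L)
  expect_false(identical(c1$ground_truth$ratio, c3$ground_truth$ratio))
})

test_that("empty cohorts are valid and invalid distributions are rejected", {
  empty <- generate_cohort(n_controls = 0, n_patients = 0, seed = 1L)
  expect_length(empty$subjects, 0)
  expect_equal(nrow(empty$ground_truth), 0)
  expect_error(
    generate_cohort(ratio_spec = list(control = list(step = c(NA, 1),
                                                     pursuit = c(1, 1)),
                                      patient = list(step = c(1, 1),
                                                     pursuit = c(1, 1))),
                    seed = 1),
    "invalid ratio distribution")
})

test_that("cohort ratio draws match the prescribed group moments", {
  coh <- generate_cohort(n_controls = 10, n_patients = 0, step_reps = 0L,
                         pursuit_reps = 0L, tasks = "step",
                         seed = 17L)
  draws <- coh$ground_truth$ratio[coh$ground_truth$task == "step"]
  se <- 0.06 / sqrt(10)
  expect_lt(abs(mean(draws) - 0.17), 3 * se)
})
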