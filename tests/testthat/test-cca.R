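test_that("design matrices have the stacked block structure", {
  ptr <- make_step_subject(reps = 1L, seed = 21L)
  one <- ptr[1]
  n <- nrow(one[[1]]$tension)
  d <- build_design_matrices(one, include_acceleration = TRUE, axis = "both")
  expect_equal(dim(d$Y), c(2 * n, 3))
  expect_equal(dim(d$X), c(2 * n, 8))
  # block structure: y-axis rows have zero x-muscle columns
  expect_true(all(d$X[(n + 1):(2 * n), 1:4] == 0))
  expect_true(all(d$X[1:n, 5:8] == 0))
  d2 <- build_design_matrices(one, include_acceleration = FALSE,
                              axis = "both")
  expect_equal(ncol(d2$Y), 2)
  d3 <- build_design_matrices(one, axis = "x")
  expect_equal(dim(d3$X), c(n, 4))
  expect_error(build_design_matrices(list()), "no trials")
})

test_that("degenerate (no-movement) trials are excluded from the design", {
  ptr <- make_step_subject(reps = 1L, seed = 22L)
  still <- ptr[[1]]
  still$theta <- still$theta * 0
  still$vel <- still$vel * 0
  still$acc <- still$acc * 0
  d <- build_design_matrices(c(ptr[1], list(still)))
  expect_equal(d$n_trials, 1L)
  expect_error(build_design_matrices(list(still)), "degenerate")
})

test_that("uncentered CCA finds exact and null relationships", {
  set.seed(31)
  X <- matrix(abs(rnorm(120)), 40, 3)
  w <- c(0.5, 1, 2)
  Y <- matrix(X %*% w, ncol = 1)
  colnames(Y) <- "theta"
  expect_equal(cca_uncentered(X, Y)$cc, 1, tolerance = 1e-10)
  # uncentered-orthogonal column spaces give cc = 0
  X0 <- cbind(rep(c(1, 1, -1, -1), 10))
  Y0 <- cbind(rep(c(1, -1, 1, -1), 10), rep(c(1, -1, -1, 1), 10))
  expect_equal(cca_uncentered(X0, Y0)$cc, 0, tolerance = 1e-10)
  expect_error(cca_uncentered(cbind(0 * X0), Y0), "all-zero")
})

test_that("uncentered CCA agrees with the unit-sphere grid oracle and cancor", {
  set.seed(50)
  X <- matrix(rnorm(150), 50, 3)
  Y <- matrix(rnorm(100), 50, 2)
  ours <- cca_uncentered(X, Y)
  oracle <- cca_sphere_oracle(X, Y)
  expect_lt(abs(ours$cc - oracle), 1e-3)
  expect_gte(ours$cc + 1e-12, oracle)  # oracle cannot beat the SVD optimum
  ref <- stats::cancor(X, Y, xcenter = FALSE, ycenter = FALSE)
  expect_equal(ours$cc_all, ref$cor, tolerance = 1e-8)
})

test_that("canonical correlation is invariant to positive column rescaling", {
  set.seed(51)
  X <- matrix(abs(rnorm(150)), 50, 3)
  Y <- matrix(abs(rnorm(100)), 50, 2)
  base <- cca_uncentered(X, Y)
  scaled <- cca_uncentered(X %*% diag(c(3, 0.1, 7)), Y %*% diag(c(0.5, 20)))
  expect_equal(base$cc_all, scaled$cc_all, tolerance = 1e-10)
  expect_equal(base$eigen_proportion_first, scaled$eigen_proportion_first,
               tolerance = 1e-10)
  rows <- cca_uncentered(2.7 * X, 2.7 * Y)  # unit rescaling of all rows
  expect_equal(base$cc_all, rows$cc_all, tolerance = 1e-10)
})

test_that("rank-deficient designs are ridge-regularized with a warning", {
  set.seed(52)
  X <- matrix(rnorm(60), 20, 3)
  X[, 3] <- X[, 1] + X[, 2]
  Y <- matrix(rnorm(40), 20, 2)
  expect_warning(fit <- cca_uncentered(X, Y), "rank-deficient")
  expect_true(is.finite(fit$cc) && fit$cc >= 0 && fit$cc <= 1)
})

test_that("task identification recovers ground-truth weight ratios", {
  fit <- identify_task(make_step_subject(ratio = 0.17, seed = 61L, reps = 2L))
  expect_lt(abs(fit$ratio - 0.17) / 0.17, 0.10)
  expect_gt(fit$cc, 0.9)
  expect_length(fit$sign_violations, 0)
  pfit <- identify_task(make_pursuit_subject(ratio = 1.30, seed = 62L))
  expect_lt(abs(pfit$ratio - 1.30) / 1.30, 0.10)
  expect_gt(pfit$cc, 0.9)
  # per-axis mode reports both axes and a comparable pooled ratio
  pa <- identify_task(make_step_subject(ratio = 0.17, seed = 61L, reps = 2L),
                      axis_mode = "per_axis")
  expect_length(pa$per_axis, 2)
  expect_lt(abs(pa$ratio - 0.17) / 0.17, 0.15)
})

test_that("acceleration term is negligible for realistic inertia", {
  ptr <- make_pursuit_subject(ratio = 1.30, seed = 63L)
  with_acc <- identify_task(ptr, include_acceleration = TRUE)
  without <- identify_task(ptr, include_acceleration = FALSE)
  expect_lt(abs(with_acc$ratio - without$ratio) / with_acc$ratio, 0.05)
  expect_lt(abs(with_acc$cc - without$cc), 0.02)
  # recovered inertial share stays small (M/K of order 1e-2 or below)
  expect_lt(abs(with_acc$mk_ratio), 0.05)
})

test_that("first canonical pair dominates on model-generated step data", {
  fit <- identify_task(make_step_subject(ratio = 0.17, seed = 64L))
  expect_gt(fit$eigen_proportion_first, 0.9)
})
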