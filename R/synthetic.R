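# ---- synthetic trial generation -------------------------------------------
# Model-consistent virtual subjects: kinematics are built analytically, the
# joint model turns them into torque, and the torque is decomposed into four
# nonnegative muscle tensions that reproduce it exactly before noise.

canonical_directions <- c(RT = 0, UR = 45, UP = 90, UL = 135,
                          LF = 180, DL = 225, DN = 270, DR = 315)

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# minimum-jerk position profile s(u) and its derivatives, u in [0, 1]
min_jerk_profile <- function(u) {
  list(s = 10 * u^3 - 15 * u^4 + 6 * u^5,
       ds = 30 * u^2 - 60 * u^3 + 30 * u^4,
       d2s = 60 * u - 180 * u^2 + 120 * u^3)
}

#' Minimum-jerk step-tracking kinematics
#'
#' Point-to-point angular trajectory of the step-tracking task: a central
#' hold, a minimum-jerk movement of the stated amplitude toward one of the
#' eight canonical targets, and a target hold. Velocity and acceleration
#' are analytic (bell-shaped velocity, exactly zero at the endpoints).
#'
#' @param direction Direction label (`"UP"`, `"UR"`, `"RT"`, `"DR"`,
#'   `"DN"`, `"DL"`, `"LF"`, `"UL"`) or an angle in cursor-space degrees.
#' @param amplitude_deg Movement amplitude in degrees (default 18).
#' @param fs Sampling rate in Hz (default 100).
#' @param move_duration Movement time in s (default 0.4).
#' @param hold_pre,hold_post Hold durations in s (central and target hold).
#' @return List with `time`, `angle_deg` (n x 2), `vel_deg` (n x 2, deg/s),
#'   `acc_deg` (n x 2, deg/s^2), `hold_idx` (central-hold samples),
#'   `direction_deg`.
#' @export
make_step_kinematics <- function(direction, amplitude_deg = 18, fs = 100,
                                 move_duration = 0.4, hold_pre = 1.5,
                                 hold_post = 1.5) {
  dir_deg <- if (is.character(direction)) {
    if (!direction %in% names(canonical_directions))
      stop("unknown direction label: ", direction)
    canonical_directions[[direction]]
  } else as.numeric(direction)
  n_pre <- as.integer(round(hold_pre * fs))
  n_mov <- as.integer(round(move_duration * fs))
  n_post <- as.integer(round(hold_post * fs))
  time <- seq(0, by = 1 / fs, length.out = n_pre + n_mov + n_post + 1L)
  u <- c(rep(0, n_pre), seq(0, 1, length.out = n_mov + 1L), rep(1, n_post))
  prof <- min_jerk_profile(u)
  gate <- u > 0 & u < 1
  uvec <- c(cos(dir_deg * pi / 180), sin(dir_deg * pi / 180))
  s <- amplitude_deg * prof$s
  ds <- ifelse(gate, amplitude_deg * prof$ds / move_duration, 0)
  d2s <- ifelse(gate, amplitude_deg * prof$d2s / move_duration^2, 0)
  list(time = time,
       angle_deg = cbind(x = s * uvec[1], y = s * uvec[2]),
       vel_deg = cbind(x = ds * uvec[1], y = ds * uvec[2]),
       acc_deg = cbind(x = d2s * uvec[1], y = d2s * uvec[2]),
       hold_idx = seq_len(n_pre), direction_deg = dir_deg)
}

# figure-eight (2:1 Lissajous): x = xa*sin(2*psi), y = -ya*cos(psi).
# Traversal starts at psi = 3*pi/4, the upper-left extreme (-xa, ya/sqrt(2)).
pursuit_path <- function(psi, x_amp, y_amp) {
  list(x = x_amp * sin(2 * psi), y = -y_amp * cos(psi),
       dx = 2 * x_amp * cos(2 * psi), dy = y_amp * sin(psi))
}

#' Constant-speed pursuit kinematics
#'
#' The pursuit task: after a central hold, the wrist moves (minimum jerk)
#' to the path start at the upper left, holds, then traverses one lap of a
#' smooth closed figure-eight (2:1 Lissajous spanning +/- x_amp by
#' +/- y_amp degrees) at constant tangential speed. The traversal is
#' arc-length parameterized, so the speed is constant to well within 1%.
#'
#' @param fs Sampling rate in Hz (default 100).
#' @param speed_deg_s Tangential speed in deg/s (default 6.2).
#' @param x_amp,y_amp Path half-spans in degrees (default 10 and 8; the
#'   path starts at (-x_amp, y_amp)).
#' @param hold_center,transit,hold_start Durations (s) of the central hold,
#'   the transit to the path start, and the start hold.
#' @param laps Number of laps (default 1).
#' @return Same structure as [make_step_kinematics()], plus `path_start`.
#' @export
make_pursuit_kinematics <- function(fs = 100, speed_deg_s = 6.2,
                                    x_amp = 10, y_amp = 8,
                                    hold_center = 0.8, transit = 1.0,
                                    hold_start = 1.0, laps = 1L) {
  if (x_amp <= 0 || y_amp <= 0 || speed_deg_s <= 0)
    stop("degenerate path or speed")
  # arc-length table on a dense parameter grid
  npsi <- 20000L
  psi <- seq(3 * pi / 4, 3 * pi / 4 + 2 * pi * laps,
             length.out = npsi + 1L)
  p <- pursuit_path(psi, x_amp, y_amp)
  spd <- sqrt(p$dx^2 + p$dy^2)           # |dr/dpsi|
  dpsi <- diff(psi)
  arclen <- c(0, cumsum((spd[-1] + spd[-length(spd)]) / 2 * dpsi))
  L <- arclen[length(arclen)]
  T_lap <- L / speed_deg_s
  t_lap <- seq(0, T_lap, by = 1 / fs)
  psi_t <- stats::approx(arclen, psi, xout = pmin(t_lap * speed_deg_s, L),
                         rule = 2)$y
  lap <- pursuit_path(psi_t, x_amp, y_amp)
  lap_spd <- sqrt(lap$dx^2 + lap$dy^2)
  vx <- speed_deg_s * lap$dx / lap_spd   # unit tangent times constant speed
  vy <- speed_deg_s * lap$dy / lap_spd

  # central hold, min-jerk transit to the path start, start hold
  start <- c(lap$x[1], lap$y[1])
  n_hold <- as.integer(round(hold_center * fs))
  n_tr <- as.integer(round(transit * fs))
  n_sh <- as.integer(round(hold_start * fs))
  u <- seq(0, 1, length.out = n_tr + 1L)
  prof <- min_jerk_profile(u)
  gate <- u > 0 & u < 1
  amp <- sqrt(sum(start^2))
  uvec <- start / amp
  tr_s <- amp * prof$s
  tr_v <- ifelse(gate, amp * prof$ds / transit, 0)
  tr_a <- ifelse(gate, amp * prof$d2s / transit^2, 0)

  x <- c(rep(0, n_hold), tr_s * uvec[1], rep(start[1], n_sh), lap$x[-1])
  y <- c(rep(0, n_hold), tr_s * uvec[2], rep(start[2], n_sh), lap$y[-1])
  vxf <- c(rep(0, n_hold), tr_v * uvec[1], rep(0, n_sh), vx[-1])
  vyf <- c(rep(0, n_hold), tr_v * uvec[2], rep(0, n_sh), vy[-1])
  axf <- c(rep(0, n_hold), tr_a * uvec[1], rep(0, n_sh),
           finite_gradient(vx, fs)[-1])
  ayf <- c(rep(0, n_hold), tr_a * uvec[2], rep(0, n_sh),
           finite_gradient(vy, fs)[-1])
  n <- length(x)
  list(time = seq(0, by = 1 / fs, length.out = n),
       angle_deg = cbind(x = x, y = y),
       vel_deg = cbind(x = vxf, y = vyf),
       acc_deg = cbind(x = axf, y = ayf),
       hold_idx = seq_len(n_hold),
       direction_deg = NULL, path_start = start,
       path_length_deg = L / laps, lap_duration_s = T_lap / laps)
}

#' Decompose joint torque into nonnegative muscle tensions
#'
#' Inverts the muscle side of the joint model: produces four nonnegative
#' tension series whose weighted sum reproduces a given two-axis torque
#' exactly (before noise). The positive and negative torque on each axis is
#' carried by the antagonist pair pulling that way, with the pair's shares
#' chosen so their off-axis torque components cancel; a co-contraction term
#' along a nonnegative null vector of the weight matrix adds activity with
#' zero net torque; multiplicative log-normal noise (EMG-envelope-like,
#' signal-dependent) is applied last.
#'
#' @param tau n x 2 torque matrix (Nm; columns x, y).
#' @param a_star 4 x 2 matrix of true muscle weights (rows ECR, ECU, FCU,
#'   FCR), with one muscle pulling into each quadrant.
#' @param co_contraction Baseline co-contraction tension level (default 0).
#' @param snr_db Envelope signal-to-noise ratio in dB (`Inf` = noise-free).
#' @param seed Optional RNG seed for the noise draw.
#' @return n x 4 matrix of nonnegative (pre-noise) tensions.
#' @export
tensions_from_torque <- function(tau, a_star, co_contraction = 0,
                                 snr_db = Inf, seed = NULL) {
  tau <- as.matrix(tau)
  if (ncol(tau) != 2L) stop("tau must have two axis columns")
  a_star <- as.matrix(a_star)
  if (!identical(dim(a_star), c(4L, 2L))) stop("a_star must be 4 x 2")
  for (ax in 1:2)
    if (sum(a_star[, ax] > 0) != 2L || sum(a_star[, ax] < 0) != 2L)
      stop("infeasible sign pattern: each axis needs two agonists and two antagonists")

  n <- nrow(tau)
  tension <- matrix(0, n, 4L,
                    dimnames = list(NULL, c("ECR", "ECU", "FCU", "FCR")))
  # share coefficients: pair carrying each signed torque direction, with the
  # off-axis components cancelling within the pair
  add_pair <- function(axis, positive) {
    idx <- if (positive) which(a_star[, axis] > 0) else
      which(a_star[, axis] < 0)
    Mp <- rbind(a_star[idx, axis], a_star[idx, 3 - axis])
    coef <- solve(Mp, c(1, 0))
    part <- if (positive) pmax(tau[, axis], 0) else pmin(tau[, axis], 0)
    contrib <- outer(part, coef)
    if (any(contrib < -1e-9))
      stop("infeasible sign pattern: pair decomposition yields negative tension")
    tension[, idx] <<- tension[, idx] + pmax(contrib, 0)
  }
  for (axis in 1:2) for (positive in c(TRUE, FALSE)) add_pair(axis, positive)

  if (co_contraction > 0) {
    nv <- positive_null_vector(a_star)
    if (is.null(nv))
      stop("infeasible sign pattern: no nonnegative co-contraction null vector")
    tension <- tension + matrix(co_contraction * nv, n, 4L, byrow = TRUE)
  }
  if (is.finite(snr_db)) {
    sigma <- 10^(-snr_db / 20)
    tension <- with_seed(seed,
      tension * exp(matrix(stats::rnorm(n * 4L, 0, sigma), n, 4L)))
  }
  tension
}

# nonnegative unit-mean vector in the null space of t(a_star) (zero net
# torque on both axes), or NULL when none exists
positive_null_vector <- function(a_star) {
  N <- MASS::Null(a_star)  # basis of {n : t(a_star) %*% n = 0}
  if (NCOL(N) == 0L) return(NULL)
  if (NCOL(N) == 1L) {
    n <- drop(N)
    if (all(n >= 0) || all(n <= 0)) n <- abs(n) else return(NULL)
    return(n / mean(n))
  }
  # prefer the projection of the uniform vector (exact equal co-contraction
  # for balanced antagonist weights), fall back to a maximin search
  proj <- N %*% crossprod(N, rep(1, nrow(N)))
  if (all(proj > 1e-9)) return(drop(proj) / mean(proj))
  ang <- seq(0, 2 * pi, length.out = 721L)[-721L]
  cand <- N %*% rbind(cos(ang), sin(ang))
  worst <- apply(cand, 2, min)
  if (max(worst) <= 1e-9) return(NULL)
  n <- cand[, which.max(worst)]
  n / mean(n)
}

# default true weights: unit pulling vectors into the four quadrants,
# scaled to a physiological torque-per-tension gain
default_true_weights <- function(gain = 0.4) {
  d <- gain / sqrt(2)
  matrix(c(d, d,   d, -d,   -d, -d,   -d, d), 4L, 2L, byrow = TRUE,
         dimnames = list(c("ECR", "ECU", "FCU", "FCR"), c("x", "y")))
}

#' Simulate one model-consistent trial
#'
#' Builds task kinematics, evaluates the joint model to obtain the torque,
#' decomposes it into muscle tensions, and packages the result as a
#' `wrist_trial` carrying measurement noise on the recorded angles and
#' envelope noise on the tensions. The ground-truth parameters are attached
#' as the `truth` element.
#'
#' @param task `"step"` or `"pursuit"`.
#' @param params List with `M`, `B`, `K` (joint parameters) and optionally
#'   `a` (4 x 2 true weights; default [default_true_weights()]).
#' @param direction Step direction label or angle (step task only).
#' @param fs Sampling rate in Hz.
#' @param snr_db Tension envelope SNR in dB.
#' @param co_contraction Co-contraction tension level.
#' @param angle_noise_sd_deg SD of additive white angle noise (degrees).
#' @param hold_pre Central hold duration (s); `NULL` draws from the task's
#'   1-2 s variable hold.
#' @param seed Optional RNG seed.
#' @param ... Passed to the kinematics generator.
#' @return A `wrist_trial` object (see [process_trial()]).
#' @export
simulate_trial <- function(task = c("step", "pursuit"), params,
                           direction = "RT", fs = 100, snr_db = 20,
                           co_contraction = 0.05, angle_noise_sd_deg = 0.02,
                           hold_pre = NULL, seed = NULL, ...) {
  task <- match.arg(task)
  a_star <- if (is.null(params$a)) default_true_weights() else params$a
  with_seed(seed, {
    kin <- if (task == "step") {
      hp <- if (is.null(hold_pre)) stats::runif(1, 1, 2) else hold_pre
      make_step_kinematics(direction, fs = fs, hold_pre = hp, ...)
    } else {
      make_pursuit_kinematics(fs = fs, ...)
    }
    d2r <- pi / 180
    tau <- kinematic_torque(kin$angle_deg * d2r, kin$vel_deg * d2r,
                            kin$acc_deg * d2r,
                            params$M, params$B, params$K)
    tension <- tensions_from_torque(tau, a_star, co_contraction, snr_db)
    angle <- kin$angle_deg
    if (angle_noise_sd_deg > 0)
      angle <- angle + matrix(stats::rnorm(length(angle), 0,
                                           angle_noise_sd_deg),
                              nrow(angle), ncol(angle))
    structure(list(time = kin$time, fs = fs, angle_deg = angle,
                   tension = tension, task = task,
                   direction = if (task == "step")
                     names(which(canonical_directions ==
                                   kin$direction_deg))[1] else NULL,
                   hold_idx = kin$hold_idx,
                   truth = list(M = params$M, B = params$B, K = params$K,
                                ratio = params$B / params$K, a = a_star)),
              class = "wrist_trial")
  })
}

#' Generate a synthetic cohort of virtual subjects
#'
#' Draws per-subject, per-task ground-truth (B, K) pairs from group-level
#' ratio distributions, generates the full trial sets of the study design
#' (step-tracking: 3 repetitions of 8 directions; pursuit: 5 repetitions),
#' and returns the trials together with a ground-truth table for recovery
#' scoring. Hand inertia is drawn per subject from the spherical-hand model
#' at density 1.0 g/ml.
#'
#' @param n_controls,n_patients Number of virtual subjects per group
#'   (defaults 10 and 19, the study design).
#' @param ratio_spec Named list `group$task = c(mean, sd)` of the B/K ratio
#'   distributions (truncated normal, lower bound 0.02). Defaults to the
#'   reported group moments: controls 0.17/1.30 (step/pursuit, SD
#'   0.06/0.27), patients 0.24/0.54 (SD 0.10/0.28).
#' @param tasks Tasks to generate (default both).
#' @param step_reps Step repetitions per direction (default 3).
#' @param pursuit_reps Pursuit repetitions (default 5).
#' @param K_scale Named elastic-weight scale per task in Nm/rad (defaults
#'   step 0.090, pursuit 0.085); B = ratio * K.
#' @param snr_db,co_contraction,angle_noise_sd_deg,fs Noise and sampling
#'   settings passed to [simulate_trial()].
#' @param seed RNG seed (mandatory for reproducibility).
#' @return An object of class `wrist_cohort`: list with `subjects` (each a
#'   list with `id`, `group`, `M`, `trials` by task), `ground_truth`
#'   (data.frame), `config`.
#' @export
generate_cohort <- function(n_controls = 10L, n_patients = 19L,
                            ratio_spec = list(
                              control = list(step = c(0.17, 0.06),
                                             pursuit = c(1.30, 0.27)),
                              patient = list(step = c(0.24, 0.10),
                                             pursuit = c(0.54, 0.28))),
                            tasks = c("step", "pursuit"),
                            step_reps = 3L, pursuit_reps = 5L,
                            K_scale = c(step = 0.090, pursuit = 0.085),
                            snr_db = 20, co_contraction = 0.05,
                            angle_noise_sd_deg = 0.02, fs = 100,
                            seed = 1L) {
  for (g in names(ratio_spec)) for (tk in names(ratio_spec[[g]])) {
    p <- ratio_spec[[g]][[tk]]
    if (length(p) != 2L || !all(is.finite(p)) || p[2] < 0)
      stop("invalid ratio distribution for ", g, "/", tk)
  }
  groups <- c(rep("control", n_controls), rep("patient", n_patients))
  with_seed(seed, {
    subjects <- vector("list", length(groups))
    gt <- list()
    for (si in seq_along(groups)) {
      g <- groups[si]
      id <- sprintf("S%02d_%s", si, g)
      radius <- max(0.035, stats::rnorm(1, 0.049, 0.002))
      hand <- spherical_hand(radius = radius)
      trials <- list()
      for (tk in tasks) {
        p <- ratio_spec[[g]][[tk]]
        ratio <- -1
        while (ratio < 0.02) ratio <- stats::rnorm(1, p[1], p[2])
        K <- K_scale[[tk]]
        B <- ratio * K
        pars <- list(M = hand$inertia, B = B, K = K)
        trials[[tk]] <- if (tk == "step") {
          unlist(lapply(seq_len(step_reps), function(rep)
            lapply(names(canonical_directions), function(d)
              simulate_trial("step", pars, direction = d, fs = fs,
                             snr_db = snr_db,
                             co_contraction = co_contraction,
                             angle_noise_sd_deg = angle_noise_sd_deg))),
            recursive = FALSE)
        } else {
          lapply(seq_len(pursuit_reps), function(rep)
            simulate_trial("pursuit", pars, fs = fs, snr_db = snr_db,
                           co_contraction = co_contraction,
                           angle_noise_sd_deg = angle_noise_sd_deg))
        }
        gt[[length(gt) + 1L]] <- data.frame(
          subject_id = id, group = g, task = tk, M = hand$inertia,
          B = B, K = K, ratio = ratio)
      }
      subjects[[si]] <- list(id = id, group = g, M = hand$inertia,
                             radius = radius, trials = trials)
    }
    structure(list(
      subjects = subjects,
      ground_truth = if (length(gt)) do.call(rbind, gt) else
        data.frame(subject_id = character(), group = character(),
                   task = character(), M = numeric(), B = numeric(),
                   K = numeric(), ratio = numeric()),
      config = list(seed = seed, snr_db = snr_db, fs = fs,
                    step_reps = step_reps, pursuit_reps = pursuit_reps,
                    co_contraction = co_contraction,
                    angle_noise_sd_deg = angle_noise_sd_deg,
                    tasks = tasks)),
      class = "wrist_cohort")
  })
}

#' Identify weight ratios for every subject and task of a cohort
#'
#' Runs the processing and identification pipeline (CCA by default, or the
#' grid search) on each subject/task of a synthetic cohort and pairs the
#' estimates with the generator's ground truth.
#'
#' @param cohort A `wrist_cohort` from [generate_cohort()].
#' @param method `"cca"` or `"grid"`.
#' @param include_acceleration Passed to [identify_task()] (CCA route).
#' @param spec Muscle spec.
#' @param ... Further arguments to the identification function.
#' @return Data.frame with `subject_id`, `group`, `task`, `ratio_true`,
#'   `ratio_est`, `rel_error`, and for the CCA route `cc`,
#'   `eigen_proportion_first`, `mk_ratio`.
#' @export
identify_cohort <- function(cohort, method = c("cca", "grid"),
                            include_acceleration = TRUE,
                            spec = default_muscle_spec(), ...) {
  method <- match.arg(method)
  rows <- list()
  for (subj in cohort$subjects) {
    for (tk in names(subj$trials)) {
      ptr <- lapply(subj$trials[[tk]], process_trial)
      truth <- cohort$ground_truth
      truth <- truth[truth$subject_id == subj$id & truth$task == tk, ]
      if (method == "cca") {
        fit <- identify_task(ptr, include_acceleration = include_acceleration,
                             spec = spec, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj$id, group = subj$group, task = tk,
          ratio_true = truth$ratio, ratio_est = fit$ratio,
          rel_error = abs(fit$ratio - truth$ratio) / truth$ratio,
          cc = fit$cc, eigen_proportion_first = fit$eigen_proportion_first,
          mk_ratio = fit$mk_ratio)
      } else {
        fit <- grid_search_bk(ptr, M = subj$M, spec = spec, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj$id, group = subj$group, task = tk,
          ratio_true = truth$ratio, ratio_est = fit$best_ratio,
          rel_error = abs(fit$best_ratio - truth$ratio) / truth$ratio,
          best_R = fit$best_R)
      }
    }
  }
  do.call(rbind, rows)
}
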