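#' Rectify a raw EMG signal and extract its low-pass envelope
#'
#' Full-wave rectifies a raw EMG series and applies a zero-phase second-order
#' Butterworth low-pass filter (forward-backward, so the envelope is not
#' delayed relative to simultaneously recorded kinematics). Small negative
#' excursions caused by filter ringing are clipped to zero.
#'
#' @param raw Numeric vector, raw EMG (volts), uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @param cutoff Low-pass cutoff frequency in Hz (default 3.0).
#' @param order Butterworth order (default 2).
#' @return Numeric vector of the same length: the nonnegative envelope.
#' @examples
#' fs <- 2000
#' t <- seq(0, 1, by = 1 / fs)
#' env <- rectify_and_envelope(sin(2 * pi * 150 * t), fs)
#' mean(env)  # close to 2/pi
#' @export
rectify_and_envelope <- function(raw, fs, cutoff = 3.0, order = 2L) {
  if (!is.numeric(raw) || !all(is.finite(raw)))
    stop("raw EMG must be finite numeric")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency fs/2")
  if (fs <= 2 * cutoff) stop("sampling rate too low for requested cutoff")
  pmax(zerophase_lowpass(abs(raw), fs, cutoff, order), 0)
}

# zero-phase Butterworth low-pass with constant end padding. Plain
# forward-backward filtering implicitly pads with zeros, which injects large
# transients when a trial ends at a held non-zero level; padding each channel
# with its own endpoint value suppresses them while keeping the operator
# linear in the signal (so identities between linearly related channels are
# preserved exactly).
zerophase_lowpass <- function(x, fs, cutoff, order = 2L, pad_s = 2) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(x)
  np <- min(n, as.integer(round(pad_s * fs)))
  xp <- c(rep(x[1], np), x, rep(x[n], np))
  y <- signal::filtfilt(bf, xp)
  y[(np + 1L):(np + n)]
}

#' Normalize a tension envelope against an isometric calibration
#'
#' Scales an EMG envelope so that the envelope amplitude recorded during a
#' reference isometric contraction maps to 1.0 per 0.78 Nm of wrist joint
#' torque, then subtracts the mean normalized tension during the
#' central-position hold so that tension at the central position is zero.
#' Baseline-subtracted tensions may therefore be (slightly) negative.
#'
#' @param envelope Numeric vector, rectified-and-filtered EMG envelope.
#' @param calib Either a single positive number (the calibration-contraction
#'   envelope amplitude) or a list with elements `level` (amplitude),
#'   `torque_nm` (torque produced, default 0.78) and optionally `noise_floor`
#'   (resting envelope level; the calibration is rejected if `level` does not
#'   exceed it).
#' @param central_hold Integer indices of the central-position hold epoch
#'   used for baseline subtraction; `NULL` skips baseline subtraction.
#' @param ref_torque_nm Torque level mapped to unit tension (default 0.78).
#' @return Numeric vector of dimensionless normalized tensions.
#' @export
normalize_tension <- function(envelope, calib, central_hold = NULL,
                              ref_torque_nm = 0.78) {
  if (is.numeric(calib) && length(calib) == 1L)
    calib <- list(level = calib, torque_nm = ref_torque_nm)
  level <- calib$level
  torque <- if (is.null(calib$torque_nm)) ref_torque_nm else calib$torque_nm
  if (!is.numeric(level) || level <= 0)
    stop("calibration envelope level must be positive")
  if (torque <= 0) stop("calibration torque level must be positive")
  if (!is.null(calib$noise_floor) && level <= calib$noise_floor)
    stop(sprintf(
      "calibration level (%.3g) does not exceed the noise floor (%.3g)",
      level, calib$noise_floor))
  gain <- level * ref_torque_nm / torque  # envelope units per unit tension
  tension <- envelope / gain
  if (!is.null(central_hold)) {
    if (any(central_hold < 1L) || any(central_hold > length(envelope)))
      stop("central_hold indices out of range")
    tension <- tension - mean(tension[central_hold])
  }
  tension
}

#' Differentiate wrist angle into position, velocity and acceleration
#'
#' Converts a sampled wrist angle from degrees to radians and differentiates
#' it twice with central differences (one-sided at the two endpoints, so all
#' outputs keep the input length). The angle can optionally be low-pass
#' filtered (zero-phase Butterworth, same family as the EMG envelope filter)
#' before differencing so that the acceleration is not noise-dominated.
#'
#' @param angle_deg Numeric vector of wrist angle in degrees.
#' @param fs Sampling rate in Hz.
#' @param smooth Logical; low-pass filter the angle before differencing.
#' @param cutoff Cutoff of the smoothing filter in Hz (default 3.0).
#' @return List with `theta` (rad), `vel` (rad/s), `acc` (rad/s^2).
#' @export
differentiate_kinematics <- function(angle_deg, fs, smooth = FALSE,
                                     cutoff = 3.0) {
  if (length(angle_deg) < 5L) stop("need at least 5 samples to differentiate")
  if (!all(is.finite(angle_deg))) stop("angle contains non-finite values")
  theta_deg <- angle_deg
  if (smooth) theta_deg <- zerophase_lowpass(angle_deg, fs, cutoff)
  theta <- theta_deg * pi / 180
  vel <- finite_gradient(theta, fs)
  acc <- finite_gradient(vel, fs)
  list(theta = theta, vel = vel, acc = acc)
}

# central differences with one-sided endpoints
finite_gradient <- function(y, fs) {
  n <- length(y)
  g <- numeric(n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) * fs / 2
  g[1] <- (y[2] - y[1]) * fs
  g[n] <- (y[n] - y[n - 1]) * fs
  g
}

#' Detect movement onset from a velocity series
#'
#' Onset is the first time the tangential speed exceeds 5% of its trial peak
#' and stays above that threshold for at least 50 ms.
#'
#' @param vel Numeric vector (rad/s) or two-column matrix (one column per
#'   axis); for a matrix the tangential speed is the row-wise Euclidean norm.
#' @param fs Sampling rate in Hz.
#' @param threshold_frac Fraction of the peak speed (default 0.05).
#' @param sustain_s Minimum supra-threshold duration in seconds (default 0.05).
#' @param min_peak Minimum peak speed (rad/s) for the trial to count as
#'   containing a movement.
#' @return Onset time in seconds (relative to the start of the series).
#' @export
detect_movement_onset <- function(vel, fs, threshold_frac = 0.05,
                                  sustain_s = 0.05, min_peak = 1e-3) {
  speed <- if (is.matrix(vel)) sqrt(rowSums(vel^2)) else abs(vel)
  peak <- max(speed)
  if (!is.finite(peak) || peak < min_peak)
    stop("no movement detected: peak speed below threshold")
  thr <- threshold_frac * peak
  need <- max(1L, ceiling(sustain_s * fs))
  above <- speed > thr
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= need)
  if (length(ok) == 0L) stop("no movement detected: threshold never sustained")
  (starts[ok[1]] - 1L) / fs
}

#' Process a recorded trial into model-ready tensions and kinematics
#'
#' Runs the full conditioning chain on one trial: EMG rectification and
#' zero-phase envelope extraction (or pass-through of precomputed tension
#' envelopes), calibration-based normalization, central-hold baseline
#' subtraction, zero-phase low-pass filtering of the wrist angles,
#' decimation to a common working rate, and double differentiation of the
#' angles. The 3 Hz-band signals are vastly oversampled at the 2 kHz
#' acquisition rate, so analyses run at a decimated working rate (default
#' 100 Hz) without information loss. All model-facing quantities are in SI
#' units (radians); degrees appear only at the I/O boundary.
#'
#' @param trial A `wrist_trial` object (see [read_trial()] or
#'   [simulate_trial()]): a list with `time`, `fs`, `angle_deg` (n x 2,
#'   degrees), either `emg` (n x 4, volts) or `tension` (n x 4, normalized
#'   envelopes), `task`, optional `direction` and `hold_idx` (central-hold
#'   sample indices).
#' @param calib Calibration per channel for raw EMG: a list of four
#'   calibration descriptors accepted by [normalize_tension()]. Ignored when
#'   the trial carries precomputed tensions.
#' @param cutoff Envelope/kinematics low-pass cutoff in Hz (default 3.0).
#' @param order Butterworth order (default 2).
#' @param working_fs Working sampling rate in Hz after decimation
#'   (default 100; must divide `fs`).
#' @return A `processed_trial` object: list with `fs`, `tension` (n x 4),
#'   `theta`, `vel`, `acc` (n x 2 matrices, rad-based), `task`, `direction`,
#'   `hold_idx` on the working clock.
#' @export
process_trial <- function(trial, calib = NULL, cutoff = 3.0, order = 2L,
                          working_fs = 100) {
  stopifnot(inherits(trial, "wrist_trial"))
  fs <- trial$fs
  validate_uniform_time(trial$time, fs)
  n <- length(trial$time)

  if (!is.null(trial$tension)) {
    # precomputed envelopes get the same zero-phase filter as the angles so
    # the linear tension-kinematics relation is preserved exactly
    tension <- apply(as.matrix(trial$tension), 2, zerophase_lowpass,
                     fs = fs, cutoff = cutoff, order = order)
  } else {
    if (is.null(trial$emg)) stop("trial carries neither EMG nor tensions")
    if (is.null(calib)) stop("raw EMG requires a calibration")
    emg <- as.matrix(trial$emg)
    tension <- matrix(0, n, 4L)
    for (i in 1:4) {
      env <- rectify_and_envelope(emg[, i], fs, cutoff, order)
      tension[, i] <- normalize_tension(env, calib[[i]], central_hold = NULL)
    }
  }

  ang <- apply(as.matrix(trial$angle_deg), 2, zerophase_lowpass,
               fs = fs, cutoff = cutoff, order = order)

  hold <- trial$hold_idx
  if (fs > working_fs) {
    if (abs(fs / working_fs - round(fs / working_fs)) > 1e-9)
      stop("working_fs must divide the acquisition rate")
    step <- as.integer(round(fs / working_fs))
    keep <- seq(1L, n, by = step)
    tension <- tension[keep, , drop = FALSE]
    ang <- ang[keep, , drop = FALSE]
    if (!is.null(hold))
      hold <- which(keep %in% hold)
    fs <- working_fs
  }

  # baseline: zero the tensions at the central-position hold
  if (!is.null(hold) && length(hold) > 0L)
    tension <- sweep(tension, 2, colMeans(tension[hold, , drop = FALSE]))

  kx <- differentiate_kinematics(ang[, 1], fs)
  ky <- differentiate_kinematics(ang[, 2], fs)
  theta <- cbind(kx$theta, ky$theta)
  vel <- cbind(kx$vel, ky$vel)
  acc <- cbind(kx$acc, ky$acc)
  if (!all(is.finite(theta)) || !all(is.finite(vel)) || !all(is.finite(acc)))
    stop("kinematic channels contain non-finite values")
  colnames(tension) <- c("ECR", "ECU", "FCU", "FCR")
  colnames(theta) <- colnames(vel) <- colnames(acc) <- c("x", "y")

  structure(list(fs = fs, tension = tension, theta = theta, vel = vel,
                 acc = acc, task = trial$task, direction = trial$direction,
                 hold_idx = hold),
            class = "processed_trial")
}

validate_uniform_time <- function(time, fs, tol = 1e-6) {
  if (length(time) < 2L) stop("trial too short")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - 1 / fs)) > tol / fs)
    stop("non-uniform sampling: time step does not match fs")
  invisible(TRUE)
}
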