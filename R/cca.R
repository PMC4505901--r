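#' Build design matrices for torque identification
#'
#' Concatenates processed trials along time and assembles the two design
#' matrices whose linear combinations are the muscle torque and the
#' kinematic torque. In the default stacked two-axis formulation the
#' kinematic matrix `Y` holds (acc, vel, theta) rows for axis x followed by
#' axis y, so one scalar (M, B, K) triple is shared by both axes, while the
#' tension matrix `X` is block-structured (each axis gets its own four
#' muscle columns), yielding eight muscle weights. Per-axis matrices are
#' also available. Trials with no appreciable movement (peak |theta| at or
#' below `min_excursion_deg` on both axes) are excluded.
#'
#' @param trials A `processed_trial` or list of them (one subject, one task).
#' @param include_acceleration Include the acceleration column in `Y`.
#' @param axis `"both"` (stacked), `"x"` or `"y"`.
#' @param min_excursion_deg Minimum peak excursion for a trial to enter the
#'   design (default 1 degree).
#' @return List with `X`, `Y`, `n_samples` (samples per axis), `n_trials`.
#' @export
build_design_matrices <- function(trials, include_acceleration = TRUE,
                                  axis = c("both", "x", "y"),
                                  min_excursion_deg = 1) {
  axis <- match.arg(axis)
  if (inherits(trials, "processed_trial")) trials <- list(trials)
  if (length(trials) == 0L) stop("no trials supplied")
  keep <- vapply(trials, function(tr)
    max(abs(tr$theta)) > min_excursion_deg * pi / 180, logical(1))
  trials <- trials[keep]
  if (length(trials) == 0L) stop("all trials degenerate (no movement)")

  tension <- do.call(rbind, lapply(trials, `[[`, "tension"))
  theta <- do.call(rbind, lapply(trials, `[[`, "theta"))
  vel <- do.call(rbind, lapply(trials, `[[`, "vel"))
  acc <- do.call(rbind, lapply(trials, `[[`, "acc"))
  n <- nrow(tension)

  kin_cols <- function(ax) {
    out <- cbind(acc = acc[, ax], vel = vel[, ax], theta = theta[, ax])
    if (!include_acceleration) out <- out[, c("vel", "theta"), drop = FALSE]
    out
  }
  zero <- matrix(0, n, 4L)
  mus <- colnames(tension)
  if (axis == "both") {
    Y <- rbind(kin_cols(1L), kin_cols(2L))
    X <- rbind(cbind(tension, zero), cbind(zero, tension))
    colnames(X) <- c(paste0(mus, "_x"), paste0(mus, "_y"))
  } else {
    ax <- if (axis == "x") 1L else 2L
    Y <- kin_cols(ax)
    X <- tension
    colnames(X) <- paste0(mus, "_", axis)
  }
  list(X = X, Y = Y, n_samples = n, n_trials = length(trials))
}

#' Uncentered canonical correlation analysis
#'
#' Finds weight vectors maximizing the correlation between `X w_x` and
#' `Y w_y` with the cross-product matrices X'X, X'Y, Y'Y computed WITHOUT
#' mean subtraction (the "no intercept" convention, which keeps muscle
#' activities referenced to the central-position zero rather than to their
#' means). Solved by whitening with Cholesky factors and an SVD; the
#' singular values are the canonical correlations of all pairs, and the
#' squared values yield the eigenvalue proportion carried by the first
#' pair. Weights are sign-normalized so that the coefficient of the angle
#' column (the elastic weight K) is positive, and the muscle-side variate
#' is scaled to match the kinematic variate's norm.
#'
#' @param X n x p matrix (muscle tensions design).
#' @param Y n x q matrix (kinematics design; columns named, with `theta`
#'   identifying the angle column when present).
#' @param ridge_eps Relative ridge added to a rank-deficient cross-product
#'   (with a warning) so the whitening stays defined.
#' @return An object of class `wrist_cca`: list with `weights_x`,
#'   `weights_y`, `cc` (first canonical correlation), `cc_all`,
#'   `eigen_proportion_first`, `n`.
#' @export
cca_uncentered <- function(X, Y, ridge_eps = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts")
  if (any(colSums(abs(X)) == 0) || any(colSums(abs(Y)) == 0))
    stop("all-zero column in X or Y")
  Sxx <- crossprod(X); Syy <- crossprod(Y); Sxy <- crossprod(X, Y)
  chol_safe <- function(S, label) {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) {
      warning(sprintf(
        "rank-deficient %s cross-product: ridge-regularized (eps = %g)",
        label, ridge_eps))
      R <- chol(S + diag(ridge_eps * mean(diag(S)), nrow(S)))
    }
    R
  }
  Rx <- chol_safe(Sxx, "X"); Ry <- chol_safe(Syy, "Y")
  # C = Rx^-T Sxy Ry^-1 ; svd(C) gives canonical pairs
  C <- backsolve(Rx, t(backsolve(Ry, t(Sxy), transpose = TRUE)),
                 transpose = TRUE)
  sv <- svd(C)
  cc_all <- pmin(sv$d, 1)
  wx <- backsolve(Rx, sv$u[, 1])
  wy <- backsolve(Ry, sv$v[, 1])
  # sign convention: elastic (angle) coefficient positive
  th <- which(colnames(Y) == "theta")
  pivot <- if (length(th) == 1L) wy[th] else wy[which.max(abs(wy))]
  if (pivot < 0) { wx <- -wx; wy <- -wy }
  # match variate scales so muscle torque and kinematic torque are comparable
  nx <- sqrt(sum((X %*% wx)^2)); ny <- sqrt(sum((Y %*% wy)^2))
  if (nx > 0) wx <- wx * ny / nx
  names(wx) <- colnames(X); names(wy) <- colnames(Y)
  structure(list(weights_x = wx, weights_y = wy, cc = cc_all[1],
                 cc_all = cc_all,
                 eigen_proportion_first = cc_all[1]^2 / sum(cc_all^2),
                 n = nrow(X)),
            class = "wrist_cca")
}

#' Identify the joint-model weight ratio for one task by CCA
#'
#' Runs [build_design_matrices()] and [cca_uncentered()] on the trials of
#' one subject and task, and extracts the viscoelastic weight ratio B/K
#' (and M/K when the acceleration term is included). Kinematic weights are
#' reported normalized so K = 1; the identification determines ratios only.
#' Sign constraints on the muscle weights are not imposed inside the CCA;
#' fits whose recovered muscle-weight signs violate the muscle spec are
#' flagged post hoc.
#'
#' @param trials A `processed_trial` or list of them.
#' @param include_acceleration Include the inertial term (default TRUE).
#' @param axis_mode `"stacked"` (one CCA pooling both axes, the default) or
#'   `"per_axis"` (independent CCAs per axis, ratios averaged).
#' @param spec Muscle spec used for the post-hoc sign check.
#' @param min_excursion_deg Degenerate-trial filter passed through.
#' @return An object of class `wrist_cca_fit`: list with `ratio` (B/K),
#'   `mk_ratio` (M/K or NA), `weights_kin` (normalized, K = 1),
#'   `weights_muscle` (4 x 2 matrix, or 4-vector per axis in per-axis
#'   mode), `cc`, `eigen_proportion_first`, `sign_violations`,
#'   `include_acceleration`, `axis_mode`, `n_samples`, and in per-axis mode
#'   `per_axis` (the two axis fits).
#' @export
identify_task <- function(trials, include_acceleration = TRUE,
                          axis_mode = c("stacked", "per_axis"),
                          spec = default_muscle_spec(),
                          min_excursion_deg = 1) {
  axis_mode <- match.arg(axis_mode)
  if (axis_mode == "stacked") {
    d <- build_design_matrices(trials, include_acceleration, "both",
                               min_excursion_deg)
    cca <- cca_uncentered(d$X, d$Y)
    fit <- extract_fit(cca, include_acceleration, spec)
    fit$axis_mode <- "stacked"
    fit$n_samples <- d$n_samples
    return(fit)
  }
  fits <- lapply(c("x", "y"), function(ax) {
    d <- build_design_matrices(trials, include_acceleration, ax,
                               min_excursion_deg)
    f <- extract_fit(cca_uncentered(d$X, d$Y), include_acceleration, spec,
                     axis = ax)
    f$n_samples <- d$n_samples
    f
  })
  avg <- structure(list(
    ratio = mean(vapply(fits, `[[`, numeric(1), "ratio")),
    mk_ratio = mean(vapply(fits, `[[`, numeric(1), "mk_ratio")),
    weights_kin = (fits[[1]]$weights_kin + fits[[2]]$weights_kin) / 2,
    weights_muscle = cbind(x = fits[[1]]$weights_muscle,
                           y = fits[[2]]$weights_muscle),
    cc = mean(vapply(fits, `[[`, numeric(1), "cc")),
    eigen_proportion_first =
      mean(vapply(fits, `[[`, numeric(1), "eigen_proportion_first")),
    sign_violations = unique(c(fits[[1]]$sign_violations,
                               fits[[2]]$sign_violations)),
    include_acceleration = include_acceleration,
    axis_mode = "per_axis",
    n_samples = fits[[1]]$n_samples,
    per_axis = fits), class = "wrist_cca_fit")
  avg
}

extract_fit <- function(cca, include_acceleration, spec, axis = NULL) {
  wy <- cca$weights_y
  K <- wy[["theta"]]; B <- wy[["vel"]]
  M <- if (include_acceleration) wy[["acc"]] else NA_real_
  wx <- cca$weights_x / K
  wkin <- wy / K
  wm <- if (is.null(axis)) {
    m <- cbind(x = wx[1:4], y = wx[5:8])
    rownames(m) <- sub("_x$", "", names(wx)[1:4])
    m
  } else {
    v <- wx
    names(v) <- sub(paste0("_", axis, "$"), "", names(wx))
    v
  }
  viol <- character(0)
  if (!is.null(spec)) {
    sgn <- cbind(spec$sign_x, spec$sign_y)
    rownames(sgn) <- spec$name
    wmat <- if (is.matrix(wm)) wm else
      matrix(wm, ncol = 1, dimnames = list(names(wm), axis))
    scol <- if (is.matrix(wm)) 1:2 else if (axis == "x") 1L else 2L
    bad <- sign(wmat) != 0 &
      sign(wmat) != sgn[rownames(wmat), scol, drop = FALSE]
    viol <- rownames(wmat)[rowSums(bad) > 0]
  }
  structure(list(ratio = B / K, mk_ratio = if (is.na(M)) NA_real_ else M / K,
                 weights_kin = wkin, weights_muscle = wm, cc = cca$cc,
                 eigen_proportion_first = cca$eigen_proportion_first,
                 sign_violations = viol,
                 include_acceleration = include_acceleration),
            class = "wrist_cca_fit")
}

#' @export
print.wrist_cca_fit <- function(x, ...) {
  cat("Wrist joint model fit (uncentered CCA, ", x$axis_mode, " axes)\n",
      sep = "")
  cat(sprintf("  B/K ratio: %.4g   CC: %.3f   first-pair eigen prop: %.3f\n",
              x$ratio, x$cc, x$eigen_proportion_first))
  if (!is.na(x$mk_ratio))
    cat(sprintf("  M/K ratio: %.4g\n", x$mk_ratio))
  if (length(x$sign_violations))
    cat("  sign-constraint violations:",
        paste(x$sign_violations, collapse = ", "), "\n")
  invisible(x)
}
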