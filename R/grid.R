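#' Sign-constrained least-squares fit of muscle-to-torque weights
#'
#' Minimizes ||tau_kin - sum_i a_i T_i||^2 subject to each weight having the
#' sign prescribed by the muscle spec (or being zero). Solved exactly by
#' enumerating all 2^4 zero/free active sets, solving each reduced
#' unconstrained problem, and keeping the best sign-feasible candidate —
#' small, deterministic, and free of iterative tolerances.
#'
#' @param tension n x 4 matrix of normalized tensions.
#' @param tau_kin Length-n kinematic torque series (one axis).
#' @param signs Length-4 vector of allowed signs (+1/-1; 0 forces the
#'   weight to zero), e.g. `default_muscle_spec()$sign_x`.
#' @return List with `a` (length-4 weights), `R` (uncentered correlation
#'   between the fitted muscle torque and `tau_kin`), `residual` (sum of
#'   squared errors).
#' @export
fit_muscle_weights_constrained <- function(tension, tau_kin, signs) {
  tension <- as.matrix(tension)
  if (ncol(tension) != 4L || nrow(tension) != length(tau_kin))
    stop("tension must be n x 4 and aligned with tau_kin")
  if (all(abs(tension) < .Machine$double.eps))
    stop("all-zero tensions: fit undefined")
  G <- crossprod(tension)
  b <- crossprod(tension, tau_kin)[, 1]
  tt <- sum(tau_kin^2)
  sol <- constrained_ls_core(G, b, tt, signs)
  sol$a <- as.numeric(sol$a)
  names(sol$a) <- colnames(tension)
  sol
}

# exact active-set enumeration on the normal equations.
# G = T'T, b = T'tau, tt = tau'tau; signs in {-1, 0, 1}.
constrained_ls_core <- function(G, b, tt, signs) {
  p <- length(b)
  allowed <- which(signs != 0)
  best <- list(a = rep(0, p), obj = tt)
  for (mask in 0:(2^length(allowed) - 1)) {
    free <- allowed[bitwAnd(mask, 2^(seq_along(allowed) - 1)) > 0]
    if (length(free) == 0L) next
    aS <- tryCatch(
      solve(G[free, free, drop = FALSE], b[free]),
      error = function(e) NULL)
    if (is.null(aS)) next
    if (any(sign(aS) != 0 & sign(aS) != signs[free])) next
    obj <- tt - sum(b[free] * aS)  # = ||tau - T a||^2 at the LS optimum
    if (obj < best$obj - 1e-12 ||
        (obj < best$obj + 1e-12 && length(free) < sum(best$a != 0))) {
      a <- rep(0, p); a[free] <- aS
      best <- list(a = a, obj = obj)
    }
  }
  fit_ss <- sum(best$a * (G %*% best$a))
  R <- if (fit_ss <= 0 || tt <= 0) 0 else
    sum(best$a * b) / sqrt(tt * fit_ss)
  list(a = best$a, R = R, residual = best$obj)
}

#' Exhaustive (B, K) grid search for the joint-model weight ratio
#'
#' The search-based alternative to the CCA identification: for every (B, K)
#' combination on a physiological grid (default 0 to 10 in steps of 0.2,
#' in Nm s/rad and Nm/rad), the kinematic torque M theta'' + B theta' +
#' K theta is computed per axis, the muscle weights are fitted under the
#' pulling-direction sign constraints, and the arithmetic mean of the x and
#' y uncentered correlations is recorded. Because the muscle weights can
#' absorb a common scaling of (B, K) whenever the inertial term is
#' negligible, the surface forms a ridge along rays of constant B/K and the
#' scientifically meaningful output is the ridge ratio. A refinement pass
#' (log-spaced ratios through the best cell) resolves ratios finer than the
#' coarse 0.2 grid step.
#'
#' @param trials A `processed_trial` or list of them.
#' @param M Inertia in kg m^2 (from [hand_inertia()]).
#' @param B_grid,K_grid Grid axes (defaults `seq(0, 10, by = 0.2)`).
#' @param spec Muscle spec giving per-axis sign constraints.
#' @param refine Run the ratio refinement pass (default TRUE).
#' @param min_excursion_deg Degenerate-trial filter.
#' @return An object of class `wrist_grid_fit`: list with `B_grid`,
#'   `K_grid`, `R_surface` (length(B) x length(K); the B = K = 0 cell is
#'   NA), `best_B`, `best_K`, `best_R`, `best_ratio` (refined when
#'   `refine`), `coarse_ratio`, `a_best` (4 x 2 weights at the best cell),
#'   `refinement` (data.frame of ratio vs R, or NULL).
#' @export
grid_search_bk <- function(trials, M,
                           B_grid = seq(0, 10, by = 0.2),
                           K_grid = seq(0, 10, by = 0.2),
                           spec = default_muscle_spec(),
                           refine = TRUE, min_excursion_deg = 1) {
  if (length(B_grid) == 0L || length(K_grid) == 0L) stop("empty grid")
  if (inherits(trials, "processed_trial")) trials <- list(trials)
  keep <- vapply(trials, function(tr)
    max(abs(tr$theta)) > min_excursion_deg * pi / 180, logical(1))
  trials <- trials[keep]
  if (length(trials) == 0L) stop("all trials degenerate (no movement)")

  tension <- do.call(rbind, lapply(trials, `[[`, "tension"))
  theta <- do.call(rbind, lapply(trials, `[[`, "theta"))
  vel <- do.call(rbind, lapply(trials, `[[`, "vel"))
  acc <- do.call(rbind, lapply(trials, `[[`, "acc"))

  # sufficient statistics per axis: cell cost is then independent of n
  axes <- lapply(1:2, function(ax) {
    Kin <- cbind(acc[, ax], vel[, ax], theta[, ax])
    list(G = crossprod(tension),
         TK = crossprod(tension, Kin),     # 4 x 3
         KK = crossprod(Kin),              # 3 x 3
         signs = if (ax == 1) spec$sign_x else spec$sign_y)
  })

  cell_R <- function(B, K, want_weights = FALSE) {
    w <- c(M, B, K)
    res <- lapply(axes, function(axd) {
      b <- as.numeric(axd$TK %*% w)
      tt <- as.numeric(t(w) %*% axd$KK %*% w)
      if (tt <= 0) return(list(R = NA_real_, a = rep(0, 4)))
      constrained_ls_core(axd$G, b, tt, axd$signs)
    })
    Rm <- mean(vapply(res, `[[`, numeric(1), "R"))
    if (want_weights)
      list(R = Rm, a = cbind(x = res[[1]]$a, y = res[[2]]$a))
    else Rm
  }

  Rsurf <- matrix(NA_real_, length(B_grid), length(K_grid),
                  dimnames = list(B = B_grid, K = K_grid))
  for (i in seq_along(B_grid)) for (j in seq_along(K_grid)) {
    if (B_grid[i] == 0 && K_grid[j] == 0) next  # torque ~ M*acc only
    Rsurf[i, j] <- cell_R(B_grid[i], K_grid[j])
  }
  bidx <- which(Rsurf == max(Rsurf, na.rm = TRUE), arr.ind = TRUE)[1, ]
  best_B <- B_grid[bidx[1]]; best_K <- K_grid[bidx[2]]
  bw <- cell_R(best_B, best_K, want_weights = TRUE)
  coarse_ratio <- if (best_K > 0) best_B / best_K else Inf

  refinement <- NULL
  best_ratio <- coarse_ratio
  best_R <- bw$R
  if (refine) {
    if (best_K > 0) {
      ratios <- if (best_B > 0)
        coarse_ratio * 10^seq(-0.5, 0.5, length.out = 81)
      else
        seq(0, (if (length(B_grid) > 1) diff(B_grid)[1] else 0.2) / best_K,
            length.out = 41)
      Rs <- vapply(ratios, function(r) cell_R(r * best_K, best_K), numeric(1))
    } else {
      # pure-velocity ridge: refine K downward at fixed B
      Ks <- best_B / (10^seq(-0.5, 3, length.out = 81))
      Rs <- vapply(Ks, function(k) cell_R(best_B, k), numeric(1))
      ratios <- best_B / Ks
    }
    refinement <- data.frame(ratio = ratios, R = Rs)
    bi <- which.max(Rs)
    if (is.finite(Rs[bi]) && Rs[bi] >= best_R) {
      best_ratio <- ratios[bi]
      best_R <- Rs[bi]
    }
  }

  structure(list(B_grid = B_grid, K_grid = K_grid, R_surface = Rsurf,
                 best_B = best_B, best_K = best_K, best_R = best_R,
                 best_ratio = best_ratio, coarse_ratio = coarse_ratio,
                 a_best = bw$a, M = M, refinement = refinement),
            class = "wrist_grid_fit")
}

#' @export
print.wrist_grid_fit <- function(x, ...) {
  cat("Wrist joint model grid search\n")
  cat(sprintf("  best cell: B = %.3g, K = %.3g (R = %.3f)\n",
              x$best_B, x$best_K, x$best_R))
  cat(sprintf("  B/K ratio: coarse %.4g, refined %.4g\n",
              x$coarse_ratio, x$best_ratio))
  invisible(x)
}

#' Contour plot of the grid-search correlation surface
#'
#' @param x A `wrist_grid_fit`.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.wrist_grid_fit <- function(x, ...) {
  graphics::filled.contour(
    x$B_grid, x$K_grid, x$R_surface,
    xlab = "B (Nms/rad)", ylab = "K (Nm/rad)",
    main = sprintf("mean R over axes (best B/K = %.3g)", x$best_ratio), ...)
  invisible(x)
}

#' Agreement between CCA-derived and grid-derived weight ratios
#'
#' Pairs the B/K ratios produced by the two identification routes on the
#' same trials (across subjects and/or tasks) and reports their Pearson
#' correlation. With fewer than three pairs the correlation is undefined
#' and flagged.
#'
#' @param cca_ratios Numeric vector of CCA ratios (or list of
#'   `wrist_cca_fit`).
#' @param grid_ratios Numeric vector of grid ratios (or list of
#'   `wrist_grid_fit`), same order/length.
#' @return List with `pairs` (data.frame `cca`, `grid`), `r` (Pearson, NA
#'   when undefined), `n`, `correlation_defined`.
#' @export
compare_ratio_methods <- function(cca_ratios, grid_ratios) {
  if (is.list(cca_ratios))
    cca_ratios <- vapply(cca_ratios, `[[`, numeric(1), "ratio")
  if (is.list(grid_ratios))
    grid_ratios <- vapply(grid_ratios, `[[`, numeric(1), "best_ratio")
  if (length(cca_ratios) != length(grid_ratios))
    stop("ratio vectors must be paired")
  n <- length(cca_ratios)
  ok <- n >= 3L && stats::sd(cca_ratios) > 0 && stats::sd(grid_ratios) > 0
  list(pairs = data.frame(cca = cca_ratios, grid = grid_ratios),
       r = if (ok) stats::cor(cca_ratios, grid_ratios) else NA_real_,
       n = n, correlation_defined = ok)
}
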