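#' Cosine fit of a muscle's preferred direction
#'
#' Fits m(d) = b0 + b1 cos(d - pd) by least squares to per-direction mean
#' activities (classically, the mean activity in a +/-25 ms window around
#' movement onset for each of the eight step directions). The fit is linear
#' in (b0, b1 cos(pd), b1 sin(pd)), so pd and the modulation depth b1 come
#' from the fitted cosine/sine coefficients; pd is wrapped to [0, 360).
#' Tuning is flagged unreliable when the cosine/sine terms are not jointly
#' significant (F-test) or the depth is numerically zero.
#'
#' @param activity Numeric vector of mean activities, one per direction.
#' @param directions_deg Direction of each entry in cursor-space degrees
#'   (default the 8 canonical directions 0, 45, ..., 315).
#' @param alpha Significance level of the reliability F-test (default 0.05).
#' @return An object of class `wrist_tuning`: list with `pd` (degrees in
#'   [0, 360)), `depth`, `baseline`, `r2`, `p_value`, `reliable`.
#' @export
preferred_direction <- function(activity,
                                directions_deg = seq(0, 315, by = 45),
                                alpha = 0.05) {
  if (length(activity) != length(directions_deg) || length(activity) < 4L)
    stop("need matched activity/direction vectors (>= 4 directions)")
  d <- directions_deg * pi / 180
  fit <- stats::lm(activity ~ cos(d) + sin(d))
  cf <- stats::coef(fit)
  depth <- sqrt(cf[2]^2 + cf[3]^2)
  pd <- (atan2(cf[3], cf[2]) * 180 / pi) %% 360
  # noise-free tuning curves fit perfectly; summary.lm warns about that
  sm <- suppressWarnings(summary(fit))
  p <- if (is.null(sm$fstatistic)) 1 else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  r2 <- sm$r.squared
  reliable <- is.finite(p) && p < alpha && depth > 1e-12
  structure(list(pd = as.numeric(pd), depth = as.numeric(depth),
                 baseline = as.numeric(cf[1]), r2 = r2,
                 p_value = as.numeric(p), reliable = reliable),
            class = "wrist_tuning")
}

#' @export
print.wrist_tuning <- function(x, ...) {
  cat(sprintf(
    "Cosine tuning: pd = %.1f deg, depth = %.3g, baseline = %.3g, r2 = %.3f%s\n",
    x$pd, x$depth, x$baseline, x$r2,
    if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' Assign agonist muscles to a movement direction
#'
#' A muscle is an agonist for a direction when the circular distance between
#' its preferred direction and the movement direction is below 67.5 degrees
#' (half of 135), keeping at most the two nearest such muscles; if no muscle
#' falls inside the window the nearest muscle is taken. This yields one or
#' two agonists for each of the eight canonical directions with the default
#' preferred directions.
#'
#' @param direction_deg Movement direction in cursor-space degrees.
#' @param spec Muscle spec carrying preferred directions.
#' @param window_deg Half-width of the agonist window (default 67.5).
#' @return Character vector of 1-2 muscle names.
#' @export
assign_agonists <- function(direction_deg, spec = default_muscle_spec(),
                            window_deg = 67.5) {
  if (nrow(spec) == 0L) stop("empty muscle spec")
  dist <- abs(circular_difference(spec$pd_deg, direction_deg))
  hit <- which(dist < window_deg)
  if (length(hit) == 0L) hit <- which.min(dist)
  if (length(hit) > 2L) hit <- hit[order(dist[hit])][1:2]
  spec$name[sort(hit)]
}

#' Correlation of agonist activity with displacement and velocity
#'
#' For a processed step-tracking trial, correlates each agonist muscle's
#' tension with (i) the displacement of the wrist along the target
#' direction and (ii) the tangential speed, over the window from movement
#' onset to the end of the trial, and averages across agonists when there
#' are two. High displacement correlations relative to velocity
#' correlations indicate position-weighted motor commands.
#'
#' @param ptrial A `processed_trial` from a step trial.
#' @param direction_deg Target direction in cursor-space degrees.
#' @param spec Muscle spec (for agonist assignment).
#' @param agonists Optional explicit agonist muscle names; default from
#'   [assign_agonists()].
#' @return List with `direction_deg`, `agonists`, `r_displacement`,
#'   `r_velocity` (means across agonists), `per_muscle` (data.frame),
#'   `degenerate` flag.
#' @export
agonist_kinematics_correlation <- function(ptrial, direction_deg,
                                           spec = default_muscle_spec(),
                                           agonists = NULL) {
  stopifnot(inherits(ptrial, "processed_trial"))
  if (is.null(agonists)) agonists <- assign_agonists(direction_deg, spec)
  onset <- detect_movement_onset(ptrial$vel, ptrial$fs)
  i0 <- max(1L, 1L + as.integer(round(onset * ptrial$fs)))
  idx <- i0:nrow(ptrial$theta)
  u <- c(cos(direction_deg * pi / 180), sin(direction_deg * pi / 180))
  disp <- as.numeric((ptrial$theta[idx, , drop = FALSE] -
                        matrix(ptrial$theta[i0, ], length(idx), 2,
                               byrow = TRUE)) %*% u)
  speed <- sqrt(rowSums(ptrial$vel[idx, , drop = FALSE]^2))
  per <- lapply(agonists, function(m) {
    tens <- ptrial$tension[idx, m]
    if (stats::sd(tens) == 0 || stats::sd(disp) == 0 || stats::sd(speed) == 0)
      return(data.frame(muscle = m, r_displacement = NA_real_,
                        r_velocity = NA_real_))
    data.frame(muscle = m,
               r_displacement = stats::cor(tens, disp),
               r_velocity = stats::cor(tens, speed))
  })
  per <- do.call(rbind, per)
  list(direction_deg = direction_deg, agonists = agonists,
       r_displacement = mean(per$r_displacement),
       r_velocity = mean(per$r_velocity),
       per_muscle = per,
       degenerate = anyNA(per$r_displacement) || anyNA(per$r_velocity))
}
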