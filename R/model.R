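#' Moment of inertia of the hand about the wrist joint
#'
#' Models the hand as a uniform sphere rotating about an axis on its surface
#' (parallel-axis theorem): M = 2mr^2/5 + mr^2 = 7mr^2/5.
#'
#' @param mass Hand mass in kg.
#' @param radius Hand radius in m.
#' @return Inertia in kg m^2.
#' @examples
#' hand_inertia(0.5, 0.05)
#' @export
hand_inertia <- function(mass, radius) {
  if (any(mass <= 0) || any(radius <= 0))
    stop("mass and radius must be positive")
  7 * mass * radius^2 / 5
}

#' Hand radius and mass from sphere density
#'
#' Convenience inversion of the spherical-hand assumption at density
#' 1.0 g/ml: given an inertia, returns the radius and mass of the uniform
#' sphere producing it; given a radius, returns mass and inertia.
#'
#' @param radius Hand radius in m (give exactly one of `radius`/`inertia`).
#' @param inertia Inertia in kg m^2.
#' @param density_kg_m3 Density (default 1000, i.e. 1.0 g/ml).
#' @return List with `radius`, `mass`, `inertia`.
#' @export
spherical_hand <- function(radius = NULL, inertia = NULL,
                           density_kg_m3 = 1000) {
  if (is.null(radius) == is.null(inertia))
    stop("give exactly one of radius or inertia")
  if (is.null(radius)) {
    # M = 7/5 * (4/3 pi r^3 rho) * r^2
    radius <- (inertia * 15 / (28 * pi * density_kg_m3))^(1 / 5)
  }
  mass <- 4 / 3 * pi * radius^3 * density_kg_m3
  list(radius = radius, mass = mass, inertia = hand_inertia(mass, radius))
}

#' Torque synthesized from movement kinematics
#'
#' Evaluates the right-hand side of the linear joint model:
#' tau(t) = M theta''(t) + B theta'(t) + K theta(t), elementwise. All three
#' kinematic arguments may be vectors (one axis) or aligned matrices (one
#' column per axis); M, B, K are scalars shared by both axes.
#'
#' @param theta Angle in rad.
#' @param vel Angular velocity in rad/s.
#' @param acc Angular acceleration in rad/s^2.
#' @param M Inertia weight (kg m^2).
#' @param B Viscous weight (Nm s/rad).
#' @param K Elastic weight (Nm/rad).
#' @return Torque series (Nm), same shape as the inputs.
#' @export
kinematic_torque <- function(theta, vel, acc, M, B, K) {
  if (!identical(dim(theta), dim(vel)) || !identical(dim(theta), dim(acc)) ||
      length(theta) != length(vel) || length(theta) != length(acc))
    stop("kinematic channels must be aligned")
  if (!all(is.finite(theta)) || !all(is.finite(vel)) || !all(is.finite(acc)))
    stop("kinematic channels must be finite")
  M * acc + B * vel + K * theta
}

#' Torque synthesized from muscle tensions
#'
#' Evaluates the muscle side of the joint model: tau(t) = sum_i a_i T_i(t).
#' With a 4 x 2 weight matrix, both axes are computed at once (column 1 =
#' flexion/extension, column 2 = radial/ulnar). If a muscle spec is given,
#' the sign of each weight must equal the spec sign or be zero.
#'
#' @param tension n x 4 matrix of normalized tensions (ECR, ECU, FCU, FCR).
#' @param a Length-4 weight vector (one axis) or 4 x 2 matrix (both axes),
#'   Nm per unit tension.
#' @param spec Optional muscle spec (see [default_muscle_spec()]) enforcing
#'   pulling-direction sign constraints.
#' @return Torque vector (or n x 2 matrix) in Nm.
#' @export
muscle_torque <- function(tension, a, spec = NULL) {
  tension <- as.matrix(tension)
  if (ncol(tension) != 4L) stop("tension must have 4 aligned channels")
  a <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  if (nrow(a) != 4L) stop("need one weight per muscle")
  if (!is.null(spec)) {
    signs <- cbind(spec$sign_x, spec$sign_y)[, seq_len(ncol(a)), drop = FALSE]
    bad <- sign(a) != 0 & sign(a) != signs
    if (any(bad))
      stop("muscle weight sign violates pulling-direction constraint: ",
           paste(spec$name[which(rowSums(bad) > 0)], collapse = ", "))
  }
  out <- tension %*% a
  if (ncol(out) == 1L) drop(out) else out
}

#' Damping ratio of the identified joint model
#'
#' zeta = B / (2 sqrt(K M)). zeta < 1 is underdamped, zeta > 1 overdamped.
#' Invariant under joint scaling of (M, B, K), so it is well defined even
#' though the identification determines the parameters only up to scale.
#'
#' @param M Inertia weight (kg m^2), > 0.
#' @param B Viscous weight (Nm s/rad), >= 0.
#' @param K Elastic weight (Nm/rad), > 0.
#' @return Dimensionless damping ratio.
#' @examples
#' damping_ratio(0.0019, 0.115, 0.085)
#' @export
damping_ratio <- function(M, B, K) {
  if (any(M <= 0) || any(K <= 0)) stop("M and K must be positive")
  if (any(B < 0)) stop("B must be nonnegative")
  B / (2 * sqrt(K * M))
}
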