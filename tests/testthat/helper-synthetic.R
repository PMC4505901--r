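# shared synthetic fixtures, built once per test run

REF_HAND <- wristdecon::spherical_hand(radius = 0.049)

# one virtual subject's processed step trials (1 rep x 8 directions unless
# reps is raised); deterministic under seed
make_step_subject <- function(ratio = 0.17, K = 0.09, reps = 1L, seed = 101L,
                              snr_db = 20, ...) {
  pars <- list(M = REF_HAND$inertia, B = ratio * K, K = K)
  set.seed(seed)
  trials <- unlist(lapply(seq_len(reps), function(r)
    lapply(c("RT", "UR", "UP", "UL", "LF", "DL", "DN", "DR"), function(d)
      simulate_trial("step", pars, direction = d, snr_db = snr_db,
                     hold_pre = 1.5, ...))), recursive = FALSE)
  lapply(trials, process_trial)
}

make_pursuit_subject <- function(ratio = 1.30, K = 0.085, reps = 2L,
                                 seed = 202L, snr_db = 20, ...) {
  pars <- list(M = REF_HAND$inertia, B = ratio * K, K = K)
  set.seed(seed)
  lapply(seq_len(reps), function(r)
    process_trial(simulate_trial("pursuit", pars, snr_db = snr_db, ...)))
}

# brute-force uncentered-CCA oracle: two-stage search over unit-sphere
# weight directions (coarse grid then local refinement)
cca_sphere_oracle <- function(X, Y, coarse_deg = 2, refine_deg = 0.1) {
  Sxx <- crossprod(X); Syy <- crossprod(Y); Sxy <- crossprod(X, Y)
  stopifnot(ncol(X) == 3L, ncol(Y) == 2L)
  eval_grid <- function(thetas, phis, psis) {
    U <- cbind(sin(thetas) * cos(phis), sin(thetas) * sin(phis),
               cos(thetas))
    V <- cbind(cos(psis), sin(psis))
    A <- (U %*% Sxy) %*% t(V)
    qu <- rowSums((U %*% Sxx) * U)
    qv <- rowSums((V %*% Syy) * V)
    cors <- abs(A) / sqrt(outer(qu, qv))
    idx <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    list(cc = max(cors), theta = thetas[idx[1]], phi = phis[idx[1]],
         psi = psis[idx[2]])
  }
  th <- seq(0, pi, by = coarse_deg * pi / 180)
  ph <- seq(0, 2 * pi, by = coarse_deg * pi / 180)
  ps <- seq(0, pi, by = coarse_deg * pi / 180)  # sign absorbed by |.|
  g <- expand.grid(theta = th, phi = ph)
  best <- eval_grid(g$theta, g$phi, ps)
  # local refinement around the coarse optimum
  dth <- seq(-coarse_deg, coarse_deg, by = refine_deg) * pi / 180
  g2 <- expand.grid(theta = best$theta + dth, phi = best$phi + dth)
  best2 <- eval_grid(g2$theta, g2$phi, best$psi + dth)
  best2$cc
}

# sign-constrained LS oracle via NNLS on sign-flipped columns
cls_nnls_oracle <- function(tension, tau, signs) {
  Ts <- sweep(tension[, signs != 0, drop = FALSE], 2, signs[signs != 0], `*`)
  fit <- pracma::lsqnonneg(Ts, tau)
  a <- numeric(length(signs))
  a[signs != 0] <- fit$x * signs[signs != 0]
  a
}

# exact Mann-Whitney p by full enumeration of group assignments
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  r <- rank(v)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}
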