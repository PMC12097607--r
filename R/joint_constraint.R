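# Kinematic-constraint self-calibration of two limb-mounted IMUs to a hinge
# joint, and joint-angle / range-of-motion estimation.
#
# The hinge constraint: the angular-velocity components of the two segments
# perpendicular to the joint axis have equal magnitude at all times, so the
# unit axis directions j1, j2 (sensor frames) minimize
#   sum_t ( ||g1 x j1|| - ||g2 x j2|| )^2 .
# The joint-center constraint: the acceleration of the joint center,
# reconstructed from each sensor by removing the lever-arm rotational terms,
# must agree in magnitude, which identifies the lever arms o1, o2.

# row-wise cross product of an n x 3 matrix with a fixed 3-vector
cross_rows <- function(M, v) {
  cbind(M[, 2] * v[3] - M[, 3] * v[2],
        M[, 3] * v[1] - M[, 1] * v[3],
        M[, 1] * v[2] - M[, 2] * v[1])
}

# row-wise cross product of two n x 3 matrices
cross_rows2 <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

row_norms <- function(M) sqrt(rowSums(M^2))

unwrap_angle <- function(x) {
  d <- diff(x)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(x[1], x[1] + cumsum(d))
}

#' Synchronized two-sensor dataset with angular accelerations
#'
#' Merges two time-aligned IMU streams and appends the angular accelerations
#' by central differences (one-sided at the record ends), optionally after
#' wavelet-denoising the angular rates.
#'
#' @param imu1,imu2 [imu_series()] objects sharing identical timestamps.
#' @param denoise `NULL`, or a [wavelet_config()] used to denoise the
#'   accelerometer and gyro channels (the rates before differentiation in
#'   particular).
#' @param bandlimit_hz optional voluntary-motion bandwidth cutoff, Hz,
#'   applied with the denoising (see [wavelet_denoise()]).
#' @return object of class `joint_dataset`: list with `t`, `dt`, `a1`, `a2`,
#'   `g1`, `g2`, `dg1`, `dg2`.
#' @export
build_joint_dataset <- function(imu1, imu2, denoise = NULL,
                                bandlimit_hz = NULL) {
  stopifnot(inherits(imu1, "imu_series"), inherits(imu2, "imu_series"))
  if (length(imu1$t) != length(imu2$t) ||
      max(abs(imu1$t - imu2$t)) > 1e-9) {
    stopf("the two IMU streams must share identical timestamps; resample first")
  }
  if (!is.null(denoise)) {
    imu1 <- denoise_imu(imu1, denoise, bandlimit_hz = bandlimit_hz)
    imu2 <- denoise_imu(imu2, denoise, bandlimit_hz = bandlimit_hz)
  }
  g1 <- imu1$gyro; g2 <- imu2$gyro
  # centered differentiation: 4th-order 5-point stencil in the interior
  # (truncation error ~ dt^4, needed for millimetre-grade lever-arm
  # calibration at 100 Hz), 2nd-order 3-point next to the edges, one-sided
  # at the ends
  ddt <- function(g, dt) {
    n <- nrow(g)
    d <- matrix(0, n, 3)
    if (n >= 5) {
      i <- 3:(n - 2)
      d[i, ] <- (-g[i + 2, ] + 8 * g[i + 1, ] - 8 * g[i - 1, ] + g[i - 2, ]) /
        (12 * dt)
    }
    if (n >= 3) {
      for (k in c(2L, n - 1L)) d[k, ] <- (g[k + 1, ] - g[k - 1, ]) / (2 * dt)
      if (n == 4) d[2:3, ] <- (g[3:4, ] - g[1:2, ]) / (2 * dt)
    }
    d[1, ] <- (g[2, ] - g[1, ]) / dt
    d[n, ] <- (g[n, ] - g[n - 1, ]) / dt
    d
  }
  structure(list(t = imu1$t, dt = imu1$dt,
                 a1 = imu1$accel, a2 = imu2$accel,
                 g1 = g1, g2 = g2,
                 dg1 = ddt(g1, imu1$dt), dg2 = ddt(g2, imu1$dt)),
            class = "joint_dataset")
}

#' Hinge-axis constraint residual
#'
#' For each sample, the difference of the projected angular-rate magnitudes
#' perpendicular to the candidate axes: `||g1 x j1|| - ||g2 x j2||`. Zero at
#' every sample for the true axes of an ideal hinge.
#'
#' @param W a [build_joint_dataset()] result.
#' @param j1,j2 unit axis candidates, sensor frames.
#' @return numeric residual vector, one value per sample, rad/s.
#' @export
axis_residual <- function(W, j1, j2) {
  if (abs(vnorm(j1) - 1) > 1e-6 || abs(vnorm(j2) - 1) > 1e-6) {
    stopf("axis candidates must be unit vectors")
  }
  row_norms(cross_rows(W$g1, j1)) - row_norms(cross_rows(W$g2, j2))
}

sph_to_unit <- function(incl, az) {
  c(sin(incl) * cos(az), sin(incl) * sin(az), cos(incl))
}

#' Estimate the hinge-axis directions of both sensors
#'
#' Minimizes the summed squared [axis_residual()] over the pair of unit axes,
#' parametrized in spherical coordinates and solved by Levenberg-Marquardt
#' from a deterministic set of multi-starts. The sign ambiguity (j and -j
#' satisfy the constraint equally) is resolved in two steps: the pair is
#' coupled through the frame-invariant projection of gravity onto the axis
#' (falling back to rate correlation when the axis stays horizontal), and
#' the coupled pair is oriented so the hinge rate is positive at motion
#' onset (flexion-positive convention).
#'
#' @param W a [build_joint_dataset()] result.
#' @param motion_floor angular-rate magnitude (rad/s) above which a sample
#'   counts as moving; estimation uses moving samples only.
#' @param n_starts number of deterministic multi-starts (default 8).
#' @return list with unit vectors `j1`, `j2` and the residual RMS `rms`.
#' @export
estimate_joint_axes <- function(W, motion_floor = 0.2, n_starts = 8) {
  moving <- row_norms(W$g1) > motion_floor | row_norms(W$g2) > motion_floor
  if (sum(moving) < 20) {
    stopf("insufficient excitation: only %d moving samples (need >= 20)",
          sum(moving))
  }
  Wm <- list(g1 = W$g1[moving, , drop = FALSE], g2 = W$g2[moving, , drop = FALSE],
             a1 = W$a1[moving, , drop = FALSE], a2 = W$a2[moving, , drop = FALSE])
  resid_fn <- function(par) {
    j1 <- sph_to_unit(par[1], par[2]); j2 <- sph_to_unit(par[3], par[4])
    row_norms(cross_rows(Wm$g1, j1)) - row_norms(cross_rows(Wm$g2, j2))
  }
  starts <- expand.grid(incl = c(pi / 4, 3 * pi / 4),
                        az = c(pi / 4, 5 * pi / 4))
  best <- NULL
  for (s in seq_len(min(n_starts, nrow(starts)^2))) {
    i <- ((s - 1) %% nrow(starts)) + 1
    j <- ((s - 1) %/% nrow(starts)) + 1
    par0 <- c(starts$incl[i], starts$az[i], starts$incl[j], starts$az[j])
    fit <- try(minpack.lm::nls.lm(
      par = par0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           gtol = 1e-10)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stopf("axis estimation failed to converge")
  j1 <- sph_to_unit(best$par[1], best$par[2])
  j2 <- sph_to_unit(best$par[3], best$par[4])
  p1 <- drop(Wm$g1 %*% j1); p2 <- drop(Wm$g2 %*% j2)
  # Couple the signs. Primary rule: j . g_gravity is frame-invariant, so the
  # accelerometer projections onto the two axes must agree in sign (they are
  # the same world quantity seen from two frames); this is robust whenever
  # the axis tilts away from horizontal at some point. Fallback when the
  # axis stays perpendicular to gravity: correlate the axis-projected rates.
  d1 <- drop(Wm$a1 %*% j1); d2 <- drop(Wm$a2 %*% j2)
  cg <- sum(d1 * d2)
  if (abs(cg) > 0.02 * sqrt(sum(d1^2) * sum(d2^2))) {
    if (cg < 0) { j2 <- -j2; p2 <- -p2 }
  } else if (stats::sd(p2) > 0 && stats::cor(p1, p2) < 0) {
    j2 <- -j2; p2 <- -p2
  }
  # global sign convention: the hinge rate is positive at motion onset
  # (flexion positive); flip the coupled pair if the first sustained rate
  # excursion is negative
  rate <- p1 - p2
  big <- which(abs(rate) > 0.3 * max(abs(rate)))
  if (length(big) && rate[big[1]] < 0) { j1 <- -j1; j2 <- -j2 }
  list(j1 = j1, j2 = j2,
       rms = sqrt(best$deviance / length(p1)))
}

#' Rotational acceleration of a point at a lever arm
#'
#' The acceleration of a point rigidly attached at lever arm `o` from the
#' rotation center, under angular rate `g` and angular acceleration `dg`:
#' the centripetal term `g x (g x o)` plus the tangential term `dg x o`.
#'
#' @param g angular rate, rad/s: a 3-vector or n x 3 matrix.
#' @param dg angular acceleration, rad/s^2, same shape as `g`.
#' @param o lever arm, m (3-vector).
#' @return acceleration in m/s^2, same shape as `g`.
#' @export
rotational_accel <- function(g, dg, o) {
  if (is.null(dim(g))) {
    cross3(g, cross3(g, o)) + cross3(dg, o)
  } else {
    cross_rows2(g, cross_rows(g, o)) + cross_rows(dg, o)
  }
}

#' Joint-center constraint residual
#'
#' Per-sample difference of the joint-center acceleration magnitudes
#' reconstructed from the two sensors:
#' `||a1 - Gamma_g1(o1)|| - ||a2 - Gamma_g2(o2)||`. Zero at every sample for
#' the true lever arms.
#'
#' @param W a [build_joint_dataset()] result.
#' @param o1,o2 candidate lever arms, m, sensor frames.
#' @return numeric residual vector, m/s^2.
#' @export
center_residual <- function(W, o1, o2) {
  if (!all(is.finite(c(o1, o2)))) stopf("lever arms must be finite")
  row_norms(W$a1 - rotational_accel(W$g1, W$dg1, o1)) -
    row_norms(W$a2 - rotational_accel(W$g2, W$dg2, o2))
}

#' Gauge-fix hinge lever arms to the minimum-norm axis point
#'
#' For a hinge, every point on the joint axis is a valid "joint center":
#' shifting both lever arms by the same distance along their respective axis
#' directions leaves the joint-center acceleration constraint untouched.
#' This picks the unique representative minimizing `||o1||^2 + ||o2||^2`,
#' making lever arms comparable across runs.
#'
#' @param o1,o2 lever arms, m, sensor frames.
#' @param j1,j2 unit hinge-axis directions, sensor frames.
#' @return list with gauge-fixed `o1`, `o2`.
#' @export
canonical_lever_arms <- function(o1, o2, j1, j2) {
  cc <- -(sum(o1 * j1) + sum(o2 * j2)) / 2
  list(o1 = o1 + cc * j1, o2 = o2 + cc * j2)
}

#' Estimate the joint-center lever arms of both sensors
#'
#' Stage one minimizes the summed squared [center_residual()] (the
#' magnitude-consistency constraint) over the pair of lever arms by
#' Levenberg-Marquardt, from the origin start plus six axis-aligned 5 cm
#' starts. When the axis directions are supplied, a refinement stage then
#' enforces the stronger form of the same constraint: the joint-center
#' accelerations, mapped into a common frame through the relative rotation
#' matrix (reconstructed per sample from the shared axis and the
#' joint-center specific-force direction), must agree as vectors, not just
#' in norm. The vector residual is sensitive to lever-arm components the
#' norm residual is first-order blind to, which matters for the weakly
#' excited proximal sensor under noise. Requires rotational excitation with
#' varying angular rate: a constant-rate (or still) record leaves the
#' tangential term unidentifiable. With axes supplied, the along-axis gauge
#' freedom (see [canonical_lever_arms()]) is fixed to the minimum-norm axis
#' point.
#'
#' @param W a [build_joint_dataset()] result.
#' @param axes optional list with unit vectors `j1`, `j2` (the output of
#'   [estimate_joint_axes()]); enables the vector-consistency refinement and
#'   the gauge fixing.
#' @param motion_floor angular-rate magnitude (rad/s) defining motion.
#' @param accel_floor minimum standard deviation of the angular acceleration
#'   (rad/s^2) for identifiability.
#' @param refine_iters vector-consistency refinement iterations (0 disables).
#' @return list with `o1`, `o2` (m, sensor frames) and residual RMS `rms`.
#' @export
estimate_joint_centers <- function(W, axes = NULL, motion_floor = 0.2,
                                   accel_floor = 0.05, refine_iters = 3) {
  moving <- row_norms(W$g1) > motion_floor | row_norms(W$g2) > motion_floor
  if (sum(moving) < 20) {
    stopf("insufficient excitation: only %d moving samples (need >= 20)",
          sum(moving))
  }
  if (max(stats::sd(row_norms(W$dg1[moving, , drop = FALSE])),
          stats::sd(row_norms(W$dg2[moving, , drop = FALSE]))) < accel_floor) {
    stopf("unidentifiable lever arms: angular rate is (near) constant")
  }
  Wm <- list(a1 = W$a1[moving, , drop = FALSE], a2 = W$a2[moving, , drop = FALSE],
             g1 = W$g1[moving, , drop = FALSE], g2 = W$g2[moving, , drop = FALSE],
             dg1 = W$dg1[moving, , drop = FALSE], dg2 = W$dg2[moving, , drop = FALSE])
  resid_fn <- function(par) center_residual(Wm, par[1:3], par[4:6])
  starts <- rbind(rep(0, 6),
                  0.05 * cbind(diag(3), diag(3)),
                  -0.05 * cbind(diag(3), diag(3)))[1:7, , drop = FALSE]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[s, ], fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           gtol = 1e-10)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stopf("lever-arm estimation failed to converge")
  o1 <- best$par[1:3]; o2 <- best$par[4:6]
  rms <- sqrt(best$deviance / sum(moving))
  if (!is.null(axes)) {
    if (refine_iters > 0) {
      rf <- refine_centers_vector(W, axes$j1, axes$j2, o1, o2, moving,
                                  iters = refine_iters)
      o1 <- rf$o1; o2 <- rf$o2; rms <- rf$rms
    }
    oo <- canonical_lever_arms(o1, o2, axes$j1, axes$j2)
    o1 <- oo$o1; o2 <- oo$o2
  }
  list(o1 = o1, o2 = o2, rms = rms)
}

#' Full hinge calibration of a two-sensor rig
#'
#' Runs [estimate_joint_axes()] then [estimate_joint_centers()] and bundles
#' the result.
#'
#' @param imu1,imu2 time-aligned [imu_series()] streams.
#' @param denoise a [wavelet_config()] applied to all channels before
#'   differentiation (`NULL` disables); the default universal-threshold
#'   denoising is essentially a no-op on clean signals.
#' @param bandlimit_hz voluntary-motion bandwidth cutoff, Hz: calibration
#'   uses only sub-cutoff signal content, rejecting soft-tissue oscillation
#'   and similar coherent disturbances above it. Voluntary joint motion sits
#'   below a few Hz, so the 3 Hz default passes it untouched while keeping
#'   8-12 Hz soft-tissue wobble (and its spectral leakage into neighboring
#'   wavelet bands) out of the constraint fits.
#' @param motion_floor angular-rate magnitude (rad/s) defining motion.
#' @return a [joint_calibration()].
#' @export
calibrate_joint <- function(imu1, imu2, denoise = wavelet_config(),
                            bandlimit_hz = 3, motion_floor = 0.2) {
  W <- build_joint_dataset(imu1, imu2, denoise = denoise,
                           bandlimit_hz = bandlimit_hz)
  ax <- estimate_joint_axes(W, motion_floor = motion_floor)
  ce <- estimate_joint_centers(W, axes = ax, motion_floor = motion_floor)
  joint_calibration(j1 = ax$j1, j2 = ax$j2, o1 = ce$o1, o2 = ce$o2,
                    axis_rms = ax$rms, center_rms = ce$rms)
}

# Rotate rows of V (joint-frame coordinates) about the shared X axis by the
# per-row angle chi.
rotx_rows <- function(V, chi) {
  cbind(V[, 1],
        cos(chi) * V[, 2] - sin(chi) * V[, 3],
        sin(chi) * V[, 2] + cos(chi) * V[, 3])
}

# Raw relative hinge angle per sample from the in-plane phases of the
# joint-center specific-force directions (no unwrapping or anchoring), plus
# a validity mask for samples with enough perpendicular component.
raw_hinge_phase <- function(at1, at2, B1, B2, min_perp = 0.05) {
  u1 <- at1 / pmax(row_norms(at1), 1e-9)
  u2 <- at2 / pmax(row_norms(at2), 1e-9)
  v1 <- u1 %*% B1; v2 <- u2 %*% B2
  list(chi = atan2(v2[, 3], v2[, 2]) - atan2(v1[, 3], v1[, 2]),
       ok = sqrt(v1[, 2]^2 + v1[, 3]^2) > min_perp &
         sqrt(v2[, 2]^2 + v2[, 3]^2) > min_perp)
}

# Vector-consistency refinement of the lever arms: alternate between
# reconstructing the per-sample relative rotation (shared hinge axis +
# joint-center specific-force direction at the current lever arms) and
# re-fitting the lever arms so the mapped joint-center accelerations agree
# component-wise.
refine_centers_vector <- function(W, j1, j2, o1, o2, moving, iters = 3) {
  b1 <- joint_plane_basis(j1); b2 <- joint_plane_basis(j2)
  B1 <- cbind(j1, b1$x, b1$y); B2 <- cbind(j2, b2$x, b2$y)
  fit <- NULL; nsel <- 1L
  for (it in seq_len(iters)) {
    at1 <- W$a1 - rotational_accel(W$g1, W$dg1, o1)
    at2 <- W$a2 - rotational_accel(W$g2, W$dg2, o2)
    ph <- raw_hinge_phase(at1, at2, B1, B2)
    sel <- moving & ph$ok
    if (sum(sel) < 20) break
    chi <- ph$chi[sel]; nsel <- sum(sel)
    resfn <- function(par) {
      a1t <- (W$a1 - rotational_accel(W$g1, W$dg1, par[1:3]))[sel, , drop = FALSE]
      a2t <- (W$a2 - rotational_accel(W$g2, W$dg2, par[4:6]))[sel, , drop = FALSE]
      as.vector(rotx_rows(a1t %*% B1, chi) %*% t(B2) - a2t)
    }
    fit <- minpack.lm::nls.lm(
      par = c(o1, o2), fn = resfn,
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12))
    o1 <- fit$par[1:3]; o2 <- fit$par[4:6]
  }
  list(o1 = o1, o2 = o2,
       rms = if (is.null(fit)) NA_real_ else sqrt(fit$deviance / nsel))
}

#' Joint angle by integrating the axis-projected angular-rate difference
#'
#' `alpha_f(t) = alpha0 + int (g1 . j1 - g2 . j2) dt` (trapezoidal rule):
#' the gyro-only hinge angle. A rate bias common to both sensors' axis
#' components cancels; a single-sensor bias drifts the trace linearly.
#'
#' @param W a [build_joint_dataset()] result.
#' @param j1,j2 calibrated unit axes.
#' @param alpha0 initial angle, radians.
#' @return an [angle_trace()] with source `"gyro"`.
#' @export
joint_angle_gyro <- function(W, j1, j2, alpha0 = 0) {
  rate <- drop(W$g1 %*% j1) - drop(W$g2 %*% j2)
  angle_trace(W$t, alpha0 + cumtrapz1(W$t, rate), source = "gyro")
}

# per-sensor joint-plane basis: two unit vectors spanning the plane
# perpendicular to the axis j
joint_plane_basis <- function(j) {
  e <- diag(3)[, which.min(abs(j))]
  x <- e - sum(e * j) * j
  x <- x / vnorm(x)
  list(x = x, y = cross3(j, x))
}

#' Joint angle from lever-arm-corrected accelerations
#'
#' Removes each sensor's lever-arm rotational terms to recover the
#' joint-center specific force, projects it onto the joint plane
#' (perpendicular to the calibrated axis) in each sensor frame, and takes
#' the difference of the two in-plane phase angles. Samples whose projection
#' is too small (acceleration nearly parallel to the axis) are flagged and
#' carry the previous value forward. The additive offset is anchored on a
#' reference (still) interval; the sign convention follows `sign`.
#'
#' @param W a [build_joint_dataset()] result.
#' @param calib a [joint_calibration()] with lever arms.
#' @param alpha0 angle value assigned at the reference interval, radians.
#' @param ref integer sample interval `c(start, end)` (half-open) used to
#'   anchor the offset; defaults to the first sample.
#' @param sign `NULL` (default) orients the trace automatically so its rate
#'   correlates positively with the axis-projected gyro rate difference
#'   (the in-plane bases have an arbitrary handedness); +1 or -1 forces the
#'   orientation.
#' @param min_proj minimum in-plane projection norm, m/s^2.
#' @return an [angle_trace()] with source `"accel"`.
#' @export
joint_angle_accel <- function(W, calib, alpha0 = 0, ref = NULL, sign = NULL,
                              min_proj = 0.5) {
  n <- length(W$t)
  b1 <- joint_plane_basis(calib$j1); b2 <- joint_plane_basis(calib$j2)
  at1 <- W$a1 - rotational_accel(W$g1, W$dg1, calib$o1)
  at2 <- W$a2 - rotational_accel(W$g2, W$dg2, calib$o2)
  ang1 <- atan2(drop(at1 %*% b1$y), drop(at1 %*% b1$x))
  ang2 <- atan2(drop(at2 %*% b2$y), drop(at2 %*% b2$x))
  p1 <- sqrt(drop(at1 %*% b1$x)^2 + drop(at1 %*% b1$y)^2)
  p2 <- sqrt(drop(at2 %*% b2$x)^2 + drop(at2 %*% b2$y)^2)
  flagged <- p1 < min_proj | p2 < min_proj
  raw <- unwrap_angle(ang1 - ang2)
  for (k in seq_len(n)) if (flagged[k] && k > 1) raw[k] <- raw[k - 1]
  if (is.null(sign)) sign <- hinge_sign(raw, W, calib)
  raw <- sign * raw
  if (is.null(ref)) ref <- c(1L, 2L)
  idx <- ref[1]:(ref[2] - 1L)
  raw <- raw - mean(raw[idx]) + alpha0
  angle_trace(W$t, raw, source = "accel", flagged = flagged)
}

# Orient a raw relative-angle trace: its rate must correlate positively with
# the axis-projected gyro rate difference (g1.j1 - g2.j2). Returns +1/-1.
hinge_sign <- function(raw, W, calib) {
  rate_g <- drop(W$g1 %*% calib$j1) - drop(W$g2 %*% calib$j2)
  n <- length(raw)
  s <- sum(diff(raw) * (rate_g[-n] + rate_g[-1]) / 2)
  if (s < 0) -1 else 1
}

#' Complementary fusion of accelerometer and gyro joint angles
#'
#' Recursive blend `alpha(t) = coeff * (alpha(t - dt) + d_alpha_f) +
#' (1 - coeff) * alpha_s(t)`: the gyro increment carries the high-frequency
#' motion, the accelerometer angle pins the low frequencies and removes
#' integration drift.
#'
#' @param accel_trace an [angle_trace()] (accelerometer angle).
#' @param gyro_trace an [angle_trace()] (integrated gyro angle).
#' @param coeff gyro weight in [0, 1]; default 0.98.
#' @return an [angle_trace()] with source `"fused"`.
#' @export
fuse_joint_angles <- function(accel_trace, gyro_trace, coeff = 0.98) {
  n <- length(accel_trace$t)
  if (length(gyro_trace$t) != n ||
      max(abs(accel_trace$t - gyro_trace$t)) > 1e-9) {
    stopf("accel and gyro angle traces must share timestamps")
  }
  if (coeff < 0 || coeff > 1) stopf("fusion coefficient must lie in [0, 1]")
  out <- numeric(n)
  out[1] <- coeff * gyro_trace$angle[1] + (1 - coeff) * accel_trace$angle[1]
  for (k in 2:n) {
    df <- gyro_trace$angle[k] - gyro_trace$angle[k - 1]
    out[k] <- coeff * (out[k - 1] + df) + (1 - coeff) * accel_trace$angle[k]
  }
  angle_trace(accel_trace$t, out, source = "fused")
}

#' Joint angle from per-sample best-fit relative rotation (SVD)
#'
#' Expresses, in per-sensor joint frames whose X axis is the calibrated
#' hinge axis, the vector pairs known to coincide in the world frame: the
#' hinge axis itself, the lever-arm-corrected specific-force (joint-center
#' gravity) direction, and their cross product. The proper rotation best
#' aligning the two sets (Kabsch/SVD) is then a rotation about X whose angle
#' `atan2(R[3,2], R[3,3])` is the hinge angle. An optional window pools the
#' vector pairs of neighboring samples to average noise. Samples whose
#' specific force is nearly parallel to the axis give collinear pairs; they
#' are flagged and carry the previous value forward.
#'
#' @param W a [build_joint_dataset()] result.
#' @param calib a [joint_calibration()].
#' @param window pooling window, s.
#' @param alpha0,ref,sign offset/sign anchoring as in [joint_angle_accel()].
#' @param min_perp minimum norm of the specific-force component
#'   perpendicular to the axis, relative to the vector norm.
#' @return an [angle_trace()] with source `"svd"`.
#' @export
joint_angle_svd <- function(W, calib, window = 0.2, alpha0 = 0, ref = NULL,
                            sign = NULL, min_perp = 0.05) {
  n <- length(W$t)
  b1 <- joint_plane_basis(calib$j1); b2 <- joint_plane_basis(calib$j2)
  B1 <- cbind(calib$j1, b1$x, b1$y); B2 <- cbind(calib$j2, b2$x, b2$y)
  at1 <- W$a1 - rotational_accel(W$g1, W$dg1, calib$o1 %||% c(0, 0, 0))
  at2 <- W$a2 - rotational_accel(W$g2, W$dg2, calib$o2 %||% c(0, 0, 0))
  unit_rows <- function(M, floor = 1e-9) {
    nn <- row_norms(M)
    M / pmax(nn, floor) * (nn > floor)
  }
  u1 <- unit_rows(at1) %*% B1; u2 <- unit_rows(at2) %*% B2
  ex <- c(1, 0, 0)                      # the shared axis in both joint frames
  c1 <- cross_rows(u1, -ex); c2 <- cross_rows(u2, -ex)  # ex x u
  perp_ok <- row_norms(c1) > min_perp & row_norms(c2) > min_perp
  half <- max(0L, as.integer(round(window / W$dt / 2)))
  theta <- numeric(n); flagged <- rep(FALSE, n)
  prev <- NA_real_
  for (k in seq_len(n)) {
    lo <- max(1L, k - half); hi <- min(n, k + half)
    sel <- (lo:hi)[perp_ok[lo:hi]]
    if (!length(sel)) {
      flagged[k] <- TRUE
      theta[k] <- if (is.na(prev)) 0 else prev
      next
    }
    v1 <- rbind(ex, u1[sel, , drop = FALSE], c1[sel, , drop = FALSE])
    v2 <- rbind(ex, u2[sel, , drop = FALSE], c2[sel, , drop = FALSE])
    R <- try(best_fit_rotation(v1, v2), silent = TRUE)
    if (inherits(R, "try-error")) {
      flagged[k] <- TRUE
      theta[k] <- if (is.na(prev)) 0 else prev
    } else {
      theta[k] <- atan2(R[3, 2], R[3, 3])
      prev <- theta[k]
    }
  }
  # carry the first valid value backwards over a flagged prefix
  if (flagged[1] && any(!flagged)) {
    first <- which(!flagged)[1]
    theta[seq_len(first - 1L)] <- theta[first]
  }
  raw <- unwrap_angle(theta)
  if (is.null(sign)) sign <- hinge_sign(raw, W, calib)
  raw <- sign * raw
  if (is.null(ref)) ref <- c(1L, 2L)
  idx <- ref[1]:(ref[2] - 1L)
  raw <- raw - mean(raw[idx]) + alpha0
  angle_trace(W$t, raw, source = "svd", flagged = flagged)
}

#' Estimate the hinge joint angle of a calibrated two-sensor rig
#'
#' End-to-end joint-angle estimation: builds the synchronized dataset,
#' integrates the axis-projected rate difference (gyro angle), computes the
#' accelerometer angle with its sign and offset anchored to the gyro trace
#' on the leading still interval, and blends the two by complementary
#' filtering. `method = "svd"` instead uses the per-sample best-fit relative
#' rotation.
#'
#' @param imu1,imu2 time-aligned [imu_series()] streams.
#' @param calib a [joint_calibration()].
#' @param method `"fused"`, `"gyro"`, `"accel"` or `"svd"`.
#' @param alpha0 joint angle at the leading still reference, radians.
#' @param coeff complementary fusion coefficient (gyro weight).
#' @param denoise optional [wavelet_config()] applied to all channels.
#' @param bandlimit_hz optional voluntary-motion cutoff, Hz (with `denoise`).
#' @param still_threshold accelerometer variance threshold used to find the
#'   reference still interval.
#' @return an [angle_trace()].
#' @export
joint_angle <- function(imu1, imu2, calib,
                        method = c("fused", "gyro", "accel", "svd"),
                        alpha0 = 0, coeff = 0.98, denoise = NULL,
                        bandlimit_hz = NULL, still_threshold = 5e-2) {
  method <- match.arg(method)
  W <- build_joint_dataset(imu1, imu2, denoise = denoise,
                           bandlimit_hz = bandlimit_hz)
  af <- joint_angle_gyro(W, calib$j1, calib$j2, alpha0 = alpha0)
  if (method == "gyro") return(af)
  ref <- tryCatch({
    iv <- detect_still(imu1, threshold = still_threshold)
    if (nrow(iv)) c(iv[1, 1], iv[1, 2]) else c(1L, 2L)
  }, error = function(e) c(1L, 2L))
  if (method %in% c("accel", "fused")) {
    as0 <- joint_angle_accel(W, calib, alpha0 = alpha0, ref = ref)
    if (method == "accel") return(as0)
    return(fuse_joint_angles(as0, af, coeff = coeff))
  }
  joint_angle_svd(W, calib, alpha0 = alpha0, ref = ref)
}

#' Range of motion of a joint-angle trace
#'
#' @param trace an [angle_trace()] (radians internally).
#' @return object of class `rom_summary`: list with `min`, `max` and
#'   `range`, all in degrees.
#' @export
range_of_motion <- function(trace) {
  if (!inherits(trace, "angle_trace") || length(trace$angle) == 0) {
    stopf("non-empty angle_trace required")
  }
  deg <- rad2deg(trace$angle)
  structure(list(min = min(deg), max = max(deg), range = diff(range(deg))),
            class = "rom_summary")
}

#' @export
print.rom_summary <- function(x, ...) {
  cat(sprintf("range of motion: %.1f deg (min %.1f, max %.1f)\n",
              x$range, x$min, x$max))
  invisible(x)
}
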