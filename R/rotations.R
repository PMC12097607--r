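# ---- internal helpers -------------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Cross product of two 3-vectors
#' @param a,b numeric length-3 vectors.
#' @return numeric length-3 vector `a x b`.
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param v numeric length-3 vector.
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

vnorm <- function(v) sqrt(sum(v * v))

#' Euler angles in the yaw-pitch-roll (ZYX) convention
#'
#' Constructs a validated set of intrinsic ZYX Euler angles: yaw about Z,
#' then pitch about Y, then roll about X. All angles are radians. The
#' decomposition is unique only for |pitch| < pi/2; configurations at or past
#' the gimbal singularity are rejected.
#'
#' @param yaw,pitch,roll angles in radians.
#' @return An object of class `euler_zyx` (named numeric vector).
#' @examples
#' euler_zyx(0.1, 0.2, 0.3)
#' @export
euler_zyx <- function(yaw = 0, pitch = 0, roll = 0) {
  ang <- c(yaw = yaw, pitch = pitch, roll = roll)
  if (!all(is.finite(ang))) stopf("Euler angles must be finite")
  if (abs(pitch) >= pi / 2) {
    stopf("singular attitude: |pitch| must be < pi/2 (got %.4f rad)", pitch)
  }
  structure(ang, class = "euler_zyx")
}

#' @export
print.euler_zyx <- function(x, ...) {
  cat(sprintf("ZYX Euler angles [rad]: yaw=%.6g pitch=%.6g roll=%.6g\n",
              x[["yaw"]], x[["pitch"]], x[["roll"]]))
  invisible(x)
}

#' Check that a matrix is a proper rotation
#'
#' @param R a 3x3 numeric matrix.
#' @param tol orthonormality / determinant tolerance.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
assert_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != 3) || !all(is.finite(R))) {
    stopf("not a finite 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) stopf("matrix is not orthonormal")
  if (abs(det(R) - 1) > tol) stopf("matrix determinant is not +1")
  invisible(TRUE)
}

#' Elemental rotation matrix about a coordinate axis
#'
#' Right-handed active rotation by `angle` radians about the X, Y or Z axis.
#'
#' @param axis one of `"X"`, `"Y"`, `"Z"`.
#' @param angle rotation angle, radians.
#' @return 3x3 rotation matrix.
#' @examples
#' elemental_rotation("Z", pi / 2) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
elemental_rotation <- function(axis, angle) {
  if (length(angle) != 1 || !is.finite(angle)) stopf("angle must be a finite scalar")
  axis <- match.arg(toupper(axis), c("X", "Y", "Z"))
  cs <- cos(angle); sn <- sin(angle)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, cs, -sn, 0, sn, cs), 3, 3, byrow = TRUE),
    Y = matrix(c(cs, 0, sn, 0, 1, 0, -sn, 0, cs), 3, 3, byrow = TRUE),
    Z = matrix(c(cs, -sn, 0, sn, cs, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

#' Body-to-world rotation matrix from ZYX Euler angles
#'
#' `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`: maps vectors expressed in the
#' sensor/body frame to the world frame.
#'
#' @param att an [euler_zyx()] attitude (or anything coercible by it).
#' @return 3x3 rotation matrix.
#' @export
rotation_from_euler <- function(att) {
  att <- as_euler(att)
  elemental_rotation("Z", att[["yaw"]]) %*%
    elemental_rotation("Y", att[["pitch"]]) %*%
    elemental_rotation("X", att[["roll"]])
}

as_euler <- function(x) {
  if (inherits(x, "euler_zyx")) return(x)
  if (is.numeric(x) && length(x) == 3) {
    nm <- names(x)
    if (!is.null(nm) && all(c("yaw", "pitch", "roll") %in% nm)) {
      return(euler_zyx(x[["yaw"]], x[["pitch"]], x[["roll"]]))
    }
    return(euler_zyx(x[1], x[2], x[3]))
  }
  stopf("cannot interpret input as ZYX Euler angles")
}

#' ZYX Euler angles from a body-to-world rotation matrix
#'
#' Inverse of [rotation_from_euler()] away from the gimbal singularity.
#'
#' @param R 3x3 rotation matrix.
#' @param tol gimbal-proximity tolerance on |cos(pitch)|.
#' @return An [euler_zyx()] attitude.
#' @export
euler_from_rotation <- function(R, tol = 1e-9) {
  assert_rotation(R, tol = 1e-6)
  sp <- -R[3, 1]
  if (abs(sp) >= 1 - tol) stopf("gimbal singularity: |pitch| ~ pi/2")
  euler_zyx(yaw = atan2(R[2, 1], R[1, 1]),
            pitch = asin(max(-1, min(1, sp))),
            roll = atan2(R[3, 2], R[3, 3]))
}

#' Ideal static accelerometer reading for a given attitude
#'
#' The specific force measured by a motionless triaxial accelerometer whose
#' attitude is given by ZYX Euler angles: the world gravity vector `(0, 0, g)`
#' expressed in the sensor frame by the three successive coordinate rotations
#' about Z, Y and X. Its Euclidean norm is `g` for every attitude, and any
#' yaw with zero pitch/roll leaves the reading at `(0, 0, g)` (rotation about
#' the vertical does not move gravity — which is why heading is unobservable
#' from an accelerometer).
#'
#' @param att an [euler_zyx()] attitude.
#' @param g gravitational acceleration, m/s^2.
#' @return length-3 numeric: the sensor-frame reading, m/s^2.
#' @export
body_gravity <- function(att, g = 9.81) {
  att <- as_euler(att)
  drop(t(rotation_from_euler(att)) %*% c(0, 0, g))
}

#' Roll and pitch from a static accelerometer sample
#'
#' Recovers the roll (about X) and pitch (about Y) angles from the gravity
#' components of a static specific-force sample: `roll = atan2(sy, sz)` and
#' `pitch = -atan(sx / sqrt(sy^2 + sz^2))`. Yaw is unobservable and not
#' returned.
#'
#' @param s length-3 numeric, sensor-frame specific force in m/s^2.
#' @param eps minimum admissible norm of `s`, m/s^2.
#' @return named numeric `c(roll =, pitch =)`, radians.
#' @export
accel_roll_pitch <- function(s, eps = 0.1) {
  if (length(s) != 3 || !all(is.finite(s))) stopf("s must be a finite 3-vector")
  if (vnorm(s) <= eps) {
    stopf("attitude unobservable: ||s|| = %.3g <= %.3g m/s^2", vnorm(s), eps)
  }
  c(roll = atan2(s[2], s[3]),
    pitch = -atan(s[1] / sqrt(s[2]^2 + s[3]^2)))
}

#' Body angular rates from ZYX Euler-angle rates
#'
#' Forward Euler-rate kinematics: the gyroscope reading
#' `[fx, fy, fz] = Rx(-roll) Ry(-pitch) [0, 0, dyaw] + Rx(-roll) [0, dpitch, 0]
#' + [droll, 0, 0]`.
#'
#' @param att an [euler_zyx()] attitude.
#' @param euler_rates length-3 numeric `c(dyaw, dpitch, droll)`, rad/s.
#' @return length-3 numeric body angular rate `(x, y, z)`, rad/s.
#' @export
euler_rates_to_body_rates <- function(att, euler_rates) {
  att <- as_euler(att)
  if (length(euler_rates) != 3 || !all(is.finite(euler_rates))) {
    stopf("euler_rates must be a finite 3-vector (dyaw, dpitch, droll)")
  }
  GX <- elemental_rotation("X", -att[["roll"]])
  GY <- elemental_rotation("Y", -att[["pitch"]])
  drop(GX %*% GY %*% c(0, 0, euler_rates[1]) +
         GX %*% c(0, euler_rates[2], 0) +
         c(euler_rates[3], 0, 0))
}

#' ZYX Euler-angle rates from body angular rates
#'
#' Exact inverse of [euler_rates_to_body_rates()]: standard ZYX Euler
#' kinematics. Singular at |pitch| = pi/2 where yaw and roll rates become
#' indistinguishable.
#'
#' @param att an [euler_zyx()] attitude.
#' @param omega_body length-3 body angular rate `(x, y, z)`, rad/s.
#' @param delta gimbal guard: requires |pitch| < pi/2 - delta.
#' @return length-3 numeric `c(dyaw, dpitch, droll)`, rad/s.
#' @export
body_rates_to_euler_rates <- function(att, omega_body, delta = 1e-3) {
  att <- as_euler(att)
  if (length(omega_body) != 3 || !all(is.finite(omega_body))) {
    stopf("omega_body must be a finite 3-vector")
  }
  b <- att[["pitch"]]; cr <- cos(att[["roll"]]); sr <- sin(att[["roll"]])
  if (abs(b) >= pi / 2 - delta) {
    stopf("gimbal proximity: |pitch| = %.4f rad within %.0e of pi/2", abs(b), delta)
  }
  p <- omega_body[1]; q <- omega_body[2]; r <- omega_body[3]
  c(dyaw = (q * sr + r * cr) / cos(b),
    dpitch = q * cr - r * sr,
    droll = p + tan(b) * (q * sr + r * cr))
}

#' Best-fit proper rotation between paired vector sets (Kabsch/SVD)
#'
#' Finds the rotation `R` minimizing `sum ||R v1_i - v2_i||^2` over proper
#' rotations, via the singular value decomposition of the correlation matrix
#' with the standard determinant correction `diag(1, 1, sign(det(U V^T)))`
#' so a reflection is never returned.
#'
#' @param v1,v2 n x 3 matrices (or lists of 3-vectors) of paired vectors.
#' @param tol degeneracy tolerance on the second singular value relative to
#'   the first.
#' @return 3x3 proper rotation matrix.
#' @export
best_fit_rotation <- function(v1, v2, tol = 1e-8) {
  v1 <- to_mat3(v1); v2 <- to_mat3(v2)
  if (nrow(v1) != nrow(v2)) stopf("paired vector sets differ in length")
  if (nrow(v1) < 2) stopf("need at least 2 vector pairs")
  B <- crossprod(v2, v1)  # sum v2_i v1_i^T
  sv <- svd(B)
  if (sv$d[2] <= tol * max(sv$d[1], .Machine$double.eps)) {
    stopf("unidentifiable rotation: vector pairs are collinear/degenerate")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  R
}

to_mat3 <- function(v) {
  if (is.list(v)) v <- do.call(rbind, v)
  if (is.null(dim(v))) v <- matrix(v, 1, 3)
  if (ncol(v) != 3) stopf("expected 3-column vector set")
  storage.mode(v) <- "double"
  dimnames(v) <- NULL
  v
}

#' Hinge angle from a relative rotation matrix
#'
#' For a one-degree-of-freedom hinge whose axis is the shared X axis of the
#' two frames, the joint angle is `atan2(R[3, 2], R[3, 3])`.
#'
#' @param R_rel 3x3 relative rotation matrix.
#' @return angle in radians, in (-pi, pi].
#' @export
hinge_angle_from_relative <- function(R_rel) {
  assert_rotation(R_rel, tol = 1e-6)
  atan2(R_rel[3, 2], R_rel[3, 3])
}
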