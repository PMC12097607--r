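# Rigid-body two-segment hinge-limb simulator.
#
# Segment 1 (the "base", e.g. thigh) carries IMU1, segment 2 (e.g. shank)
# carries IMU2; the two are connected by a one-degree-of-freedom hinge whose
# center stays at the world origin. All sensor streams are derived
# analytically from the motion profile (angular acceleration included), so
# the simulator output is exact to machine precision and usable as an oracle.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

axis_angle_rotation <- function(u, ang) {
  u <- u / vnorm(u)
  diag(3) * cos(ang) + sin(ang) * skew3(u) + (1 - cos(ang)) * tcrossprod(u)
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# ---- series containers ------------------------------------------------------

#' Uniformly sampled triaxial IMU stream
#'
#' @param t numeric timestamps, s, uniformly spaced.
#' @param accel n x 3 matrix of specific force, m/s^2, sensor frame.
#' @param gyro n x 3 matrix of angular rate, rad/s, sensor frame.
#' @return object of class `imu_series`.
#' @export
imu_series <- function(t, accel, gyro) {
  accel <- to_mat3(accel); gyro <- to_mat3(gyro)
  n <- length(t)
  if (n < 2) stopf("an imu_series needs at least 2 samples")
  if (nrow(accel) != n || nrow(gyro) != n) stopf("accel/gyro length mismatch with t")
  if (!all(is.finite(t)) || !all(is.finite(accel)) || !all(is.finite(gyro))) {
    stopf("non-finite values in imu_series")
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9) stopf("timestamps are not uniform within 1e-9 s")
  structure(list(t = as.numeric(t), accel = accel, gyro = gyro, dt = dt[1]),
            class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("imu_series: %d samples @ %.6g Hz (%.3g s)\n",
              length(x$t), 1 / x$dt, diff(range(x$t))))
  invisible(x)
}

#' Position/velocity fix stream (GPS-like)
#'
#' @param t numeric timestamps, s, strictly increasing.
#' @param pos n x 3 world positions, m.
#' @param vel n x 3 world velocities, m/s.
#' @return object of class `gps_series`.
#' @export
gps_series <- function(t, pos, vel) {
  pos <- to_mat3(pos); vel <- to_mat3(vel)
  if (length(t) < 1) stopf("empty gps_series")
  if (any(diff(t) <= 0)) stopf("gps timestamps must be strictly increasing")
  if (nrow(pos) != length(t) || nrow(vel) != length(t)) stopf("gps stream length mismatch")
  structure(list(t = as.numeric(t), pos = pos, vel = vel), class = "gps_series")
}

#' Time-stamped world trajectory (position + velocity)
#' @param t,pos,vel timestamps (s), n x 3 positions (m), n x 3 velocities (m/s).
#' @export
trajectory <- function(t, pos, vel) {
  structure(list(t = as.numeric(t), pos = to_mat3(pos), vel = to_mat3(vel)),
            class = "trajectory")
}

#' Time-stamped joint-angle trace
#'
#' @param t timestamps, s.
#' @param angle joint angle, radians.
#' @param source one of `"truth"`, `"gyro"`, `"accel"`, `"fused"`, `"svd"`.
#' @param flagged optional logical vector marking unreliable samples.
#' @export
angle_trace <- function(t, angle, source = "truth", flagged = NULL) {
  if (length(t) != length(angle)) stopf("angle trace length mismatch")
  if (!all(is.finite(angle))) stopf("non-finite angles in trace")
  structure(list(t = as.numeric(t), angle = as.numeric(angle), source = source,
                 flagged = flagged %||% rep(FALSE, length(t))),
            class = "angle_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hinge-joint calibration: axes and joint-center lever arms
#'
#' @param j1,j2 unit joint-axis vectors in the two sensor frames.
#' @param o1,o2 lever arms (joint center -> sensor), m, sensor frames.
#' @param axis_rms,center_rms residual RMS of the two calibration stages.
#' @export
joint_calibration <- function(j1, j2, o1 = NULL, o2 = NULL,
                              axis_rms = NA_real_, center_rms = NA_real_) {
  chk <- function(j) {
    if (abs(vnorm(j) - 1) > 1e-9) stopf("joint axis must be a unit vector")
    j
  }
  structure(list(j1 = chk(j1), j2 = chk(j2), o1 = o1, o2 = o2,
                 axis_rms = axis_rms, center_rms = center_rms),
            class = "joint_calibration")
}

#' @export
print.joint_calibration <- function(x, ...) {
  cat("joint_calibration\n")
  cat("  j1:", sprintf("%+.4f", x$j1), "\n  j2:", sprintf("%+.4f", x$j2), "\n")
  if (!is.null(x$o1)) {
    cat("  o1:", sprintf("%+.4f", x$o1), "m\n  o2:", sprintf("%+.4f", x$o2), "m\n")
  }
  cat(sprintf("  residual RMS: axis %.3g, center %.3g\n", x$axis_rms, x$center_rms))
  invisible(x)
}

# ---- motion profile ---------------------------------------------------------

#' Hinge motion profile with smooth still/move schedule
#'
#' Describes the joint-angle trajectory and an optional whole-limb base
#' rotation. The active movement is windowed by a raised-cosine envelope of
#' ramp time `smooth` seconds so the trajectory is twice differentiable at
#' the still/move boundaries, and lead/tail still segments are appended for
#' reference-attitude determination.
#'
#' @param type `"sinusoid"` (angle = amplitude * env(t) * sin(2 pi f t + phase)),
#'   `"ramp"` (angular rate = rate_dps * env(t)) or `"still"`.
#' @param amplitude_deg sinusoid amplitude, degrees.
#' @param freq_hz sinusoid frequency, Hz.
#' @param phase sinusoid phase, radians.
#' @param rate_dps ramp angular rate, deg/s.
#' @param duration active-motion duration, s.
#' @param still_lead,still_tail still-segment durations, s.
#' @param smooth envelope ramp time, s.
#' @param base_angle_deg initial joint angle, degrees.
#' @param base_rotation optional list(axis, amplitude_deg, freq_hz, phase)
#'   describing a sinusoidal whole-limb rotation about a world axis.
#' @return object of class `motion_profile`.
#' @export
motion_profile <- function(type = c("sinusoid", "ramp", "still"),
                           amplitude_deg = 30, freq_hz = 0.5, phase = 0,
                           rate_dps = 10, duration = 20,
                           still_lead = 3, still_tail = 3, smooth = 1,
                           base_angle_deg = 0, base_rotation = NULL) {
  type <- match.arg(type)
  if (duration <= 0) stopf("motion duration must be > 0")
  if (smooth <= 0 || 2 * smooth > duration) stopf("invalid envelope ramp time")
  if (!is.null(base_rotation)) {
    if (!is.null(base_rotation$axis)) base_rotation <- list(base_rotation)
    base_rotation <- lapply(base_rotation, function(br) {
      br$axis <- br$axis / vnorm(br$axis)
      br$phase <- br$phase %||% 0
      br
    })
    if (length(base_rotation) > 2) stopf("at most two base-rotation components")
  }
  structure(list(type = type, amplitude = deg2rad(amplitude_deg),
                 freq = freq_hz, phase = phase, rate = deg2rad(rate_dps),
                 duration = duration, still_lead = still_lead,
                 still_tail = still_tail, smooth = smooth,
                 theta0 = deg2rad(base_angle_deg), base_rotation = base_rotation),
            class = "motion_profile")
}

# Raised-cosine envelope on [0, Tm] with ramp tau: value, first and second
# derivative, and running integral (all closed form).
envelope_eval <- function(u, Tm, tau) {
  e <- de <- d2e <- E <- numeric(length(u))
  up <- u > 0 & u < tau
  mid <- u >= tau & u <= Tm - tau
  dn <- u > Tm - tau & u < Tm
  post <- u >= Tm
  k <- pi / tau
  # ramp up
  uu <- u[up]
  e[up] <- 0.5 * (1 - cos(k * uu))
  de[up] <- 0.5 * k * sin(k * uu)
  d2e[up] <- 0.5 * k^2 * cos(k * uu)
  E[up] <- 0.5 * (uu - sin(k * uu) / k)
  # flat
  E_tau <- 0.5 * tau
  e[mid] <- 1
  E[mid] <- E_tau + (u[mid] - tau)
  # ramp down (mirror)
  E_flat <- E_tau + (Tm - 2 * tau)
  vv <- Tm - u[dn]
  e[dn] <- 0.5 * (1 - cos(k * vv))
  de[dn] <- -0.5 * k * sin(k * vv)
  d2e[dn] <- 0.5 * k^2 * cos(k * vv)
  E[dn] <- E_flat + E_tau - 0.5 * (vv - sin(k * vv) / k)
  E[post] <- E_flat + E_tau
  list(e = e, de = de, d2e = d2e, E = E)
}

# Enveloped sinusoid angle(u) = base + A * e(u) * sin(w u + phase) with
# analytic first/second derivatives; zero motion outside (0, Tm).
enveloped_sinusoid <- function(u, A, freq, phase, Tm, tau, base = 0) {
  uc <- pmin(pmax(u, 0), Tm)
  env <- envelope_eval(uc, Tm, tau)
  w <- 2 * pi * freq
  s <- sin(w * uc + phase); cs <- cos(w * uc + phase)
  theta <- base + A * env$e * s
  dtheta <- A * (env$de * s + env$e * w * cs)
  ddtheta <- A * (env$d2e * s + 2 * env$de * w * cs - env$e * w^2 * s)
  out <- u <= 0 | u >= Tm
  theta[out] <- base          # envelope is 0 at both ends
  dtheta[out] <- 0; ddtheta[out] <- 0
  list(theta = theta, dtheta = dtheta, ddtheta = ddtheta)
}

# Joint angle and analytic derivatives at times t (absolute clock).
profile_angle <- function(mp, t) {
  u <- t - mp$still_lead
  if (mp$type == "still") {
    z <- numeric(length(t))
    return(list(theta = rep(mp$theta0, length(t)), dtheta = z, ddtheta = z))
  }
  if (mp$type == "sinusoid") {
    return(enveloped_sinusoid(u, mp$amplitude, mp$freq, mp$phase,
                              mp$duration, mp$smooth, base = mp$theta0))
  }
  # ramp: angular rate = rate * envelope; angle from the closed-form integral
  uc <- pmin(pmax(u, 0), mp$duration)
  env <- envelope_eval(uc, mp$duration, mp$smooth)
  theta <- mp$theta0 + mp$rate * env$E
  dtheta <- mp$rate * env$e
  ddtheta <- mp$rate * env$de
  out <- u <= 0 | u >= mp$duration
  dtheta[out] <- 0; ddtheta[out] <- 0
  list(theta = theta, dtheta = dtheta, ddtheta = ddtheta)
}

# Base (whole-limb) rotation: one or two composed sinusoidal rotations about
# fixed axes, with analytic derivatives per component. Two components give
# the direction-varying angular velocity needed to identify the proximal
# sensor's axis and lever arm.
profile_base <- function(mp, t) {
  if (is.null(mp$base_rotation)) return(NULL)
  u <- t - mp$still_lead
  lapply(mp$base_rotation, function(br) {
    sv <- enveloped_sinusoid(u, deg2rad(br$amplitude_deg), br$freq_hz,
                             br$phase, mp$duration, mp$smooth)
    list(psi = sv$theta, dpsi = sv$dtheta, ddpsi = sv$ddtheta, axis = br$axis)
  })
}

# Base orientation, angular velocity and acceleration (world frame) at
# sample k, composing up to two rotation components.
base_state <- function(base, k) {
  if (is.null(base)) {
    return(list(R = diag(3), w = c(0, 0, 0), dw = c(0, 0, 0)))
  }
  c1 <- base[[1]]
  R1 <- axis_angle_rotation(c1$axis, c1$psi[k])
  w <- c1$axis * c1$dpsi[k]
  dw <- c1$axis * c1$ddpsi[k]
  R <- R1
  if (length(base) >= 2) {
    c2 <- base[[2]]
    R2 <- axis_angle_rotation(c2$axis, c2$psi[k])
    u2w <- drop(R1 %*% c2$axis)
    w <- w + u2w * c2$dpsi[k]
    dw <- dw + cross3(c1$axis * c1$dpsi[k], u2w) * c2$dpsi[k] + u2w * c2$ddpsi[k]
    R <- R1 %*% R2
  }
  list(R = R, w = w, dw = dw)
}

# ---- rig configuration ------------------------------------------------------

#' Two-IMU hinge rig configuration
#'
#' @param axis joint axis direction, world frame at t = 0 (unit vector).
#' @param mount1,mount2 per-sensor mounting: `list(R =, o =)` with `R` the
#'   segment-to-sensor rotation matrix and `o` the sensor position relative to
#'   the joint center, m, segment frame.
#' @param g gravitational acceleration, m/s^2.
#' @param rate sampling rate, Hz.
#' @return object of class `hinge_rig`.
#' @export
hinge_rig <- function(axis = c(1, 0, 0),
                      mount1 = list(R = rotation_from_euler(euler_zyx(0.3, -0.15, 0.2)),
                                    o = c(0.02, -0.12, 0.03)),
                      mount2 = list(R = rotation_from_euler(euler_zyx(-0.2, 0.1, -0.25)),
                                    o = c(-0.01, 0.15, -0.02)),
                      g = 9.81, rate = 100) {
  if (abs(vnorm(axis) - 1) > 1e-9) axis <- axis / vnorm(axis)
  assert_rotation(mount1$R); assert_rotation(mount2$R)
  if (rate <= 0) stopf("sample rate must be > 0")
  if (!all(is.finite(c(mount1$o, mount2$o)))) stopf("lever arms must be finite")
  structure(list(axis = axis, mount1 = mount1, mount2 = mount2, g = g,
                 rate = rate), class = "hinge_rig")
}

# ---- forward simulation -----------------------------------------------------

#' Simulate noise-free IMU streams of a two-segment hinge limb
#'
#' Produces kinematically exact sensor streams: each gyro reads the body-frame
#' angular velocity of its segment, each accelerometer the specific force at
#' its mounting point (gravity plus the centripetal and tangential terms of
#' the lever arm), with all angular accelerations evaluated analytically from
#' the motion profile. The returned truth block (joint-angle trace, per-sensor
#' attitudes, world trajectories, calibration) is exact.
#'
#' @param rig a [hinge_rig()].
#' @param motion a [motion_profile()].
#' @return A `synthetic_dataset`: list with elements `t`, `imu1`, `imu2`,
#'   `truth` (angle trace, attitude matrices, calibration), `traj1`, `traj2`,
#'   `rig`, `motion`.
#' @export
simulate_hinge <- function(rig, motion) {
  total <- motion$still_lead + motion$duration + motion$still_tail
  if (total <= 0) stopf("zero-duration motion")
  dt <- 1 / rig$rate
  t <- seq(0, total, by = dt)
  n <- length(t)
  ang <- profile_angle(motion, t)
  base <- profile_base(motion, t)
  j_w0 <- rig$axis

  M1 <- rig$mount1$R; M2 <- rig$mount2$R
  o1s <- rig$mount1$o; o2s <- rig$mount2$o
  gup <- c(0, 0, rig$g)

  acc1 <- gyr1 <- acc2 <- gyr2 <- dgyr1 <- dgyr2 <- matrix(0, n, 3)
  att1 <- att2 <- matrix(0, n, 3)  # yaw, pitch, roll of each *sensor*
  pos1 <- vel1 <- pos2 <- vel2 <- matrix(0, n, 3)

  for (k in seq_len(n)) {
    bs <- base_state(base, k)
    Rb <- bs$R; w1 <- bs$w; dw1 <- bs$dw
    Rj <- axis_angle_rotation(j_w0, ang$theta[k])
    Rseg1 <- Rb
    Rseg2 <- Rb %*% Rj
    jw <- drop(Rseg1 %*% j_w0)          # hinge axis in world at time t
    w2 <- w1 + jw * ang$dtheta[k]
    dw2 <- dw1 + cross3(w1, jw) * ang$dtheta[k] + jw * ang$ddtheta[k]

    Rs1 <- Rseg1 %*% t(M1)
    Rs2 <- Rseg2 %*% t(M2)

    # world kinematics of the sensor points (joint center fixed at origin)
    r1w <- drop(Rseg1 %*% o1s); r2w <- drop(Rseg2 %*% o2s)
    v1 <- cross3(w1, r1w); v2 <- cross3(w2, r2w)
    a1w <- cross3(dw1, r1w) + cross3(w1, cross3(w1, r1w))
    a2w <- cross3(dw2, r2w) + cross3(w2, cross3(w2, r2w))

    gyr1[k, ] <- drop(t(Rs1) %*% w1)
    gyr2[k, ] <- drop(t(Rs2) %*% w2)
    dgyr1[k, ] <- drop(t(Rs1) %*% dw1)   # d/dt of the sensor-frame rate
    dgyr2[k, ] <- drop(t(Rs2) %*% dw2)
    acc1[k, ] <- drop(t(Rs1) %*% (a1w + gup))
    acc2[k, ] <- drop(t(Rs2) %*% (a2w + gup))
    e1 <- euler_from_rotation(Rs1); e2 <- euler_from_rotation(Rs2)
    att1[k, ] <- unclass(e1); att2[k, ] <- unclass(e2)
    pos1[k, ] <- r1w; vel1[k, ] <- v1
    pos2[k, ] <- r2w; vel2[k, ] <- v2
  }

  # Axis signs follow the estimator's convention (g1.j1 - g2.j2 = +dtheta,
  # which for this rig means -M j); lever arms are gauge-fixed to the
  # minimum-norm point on the hinge axis, the only point identifiable from
  # the joint-center constraint.
  oo <- canonical_lever_arms(drop(M1 %*% o1s), drop(M2 %*% o2s),
                             drop(M1 %*% j_w0), drop(M2 %*% j_w0))
  truth_calib <- joint_calibration(
    j1 = -drop(M1 %*% j_w0), j2 = -drop(M2 %*% j_w0),
    o1 = oo$o1, o2 = oo$o2,
    axis_rms = 0, center_rms = 0)

  structure(list(
    t = t,
    imu1 = imu_series(t, acc1, gyr1),
    imu2 = imu_series(t, acc2, gyr2),
    truth = list(angle = angle_trace(t, ang$theta, "truth"),
                 rate = ang$dtheta,
                 att1 = att1, att2 = att2, calib = truth_calib,
                 dg1 = dgyr1, dg2 = dgyr2),
    traj1 = trajectory(t, pos1, vel1),
    traj2 = trajectory(t, pos2, vel2),
    rig = rig, motion = motion), class = "synthetic_dataset")
}

#' Sensor error model for corrupting ideal IMU streams
#'
#' @param accel_noise_sd white accelerometer noise, m/s^2.
#' @param gyro_noise_sd white gyro noise, rad/s.
#' @param gyro_bias constant gyro bias, rad/s (scalar recycled to 3 axes).
#' @param gyro_bias_rw_sd gyro bias random-walk intensity, rad/s/sqrt(s).
#' @param accel_bias constant accelerometer bias, m/s^2.
#' @param soft_tissue `NULL` or `list(amp_deg, freq_hz, damping)`: a damped
#'   oscillation of the mount orientation, excited by limb motion (the
#'   envelope is a leaky integrator of gyro speed with the given damping rate,
#'   1/s), emulating skin/soft-tissue wobble.
#' @param seed RNG seed for reproducibility.
#' @export
sensor_error_model <- function(accel_noise_sd = 0, gyro_noise_sd = 0,
                               gyro_bias = 0, gyro_bias_rw_sd = 0,
                               accel_bias = 0, soft_tissue = NULL,
                               seed = 1L) {
  if (accel_noise_sd < 0 || gyro_noise_sd < 0 || gyro_bias_rw_sd < 0) {
    stopf("noise standard deviations must be >= 0")
  }
  structure(list(accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 gyro_bias = rep_len(gyro_bias, 3),
                 gyro_bias_rw_sd = gyro_bias_rw_sd,
                 accel_bias = rep_len(accel_bias, 3),
                 soft_tissue = soft_tissue, seed = as.integer(seed)),
            class = "sensor_error_model")
}

#' Named error presets
#'
#' `"none"`: ideal sensors. `"low"`: white noise typical of a consumer MEMS
#' IMU. `"drift"`: low noise plus a constant 0.5 deg/s-per-axis gyro bias
#' with seed-drawn signs (turn-on bias differs between devices, so two
#' sensors never share it) and a 0.05 m/s^2 accelerometer bias.
#' `"soft-tissue"`: low noise plus an 8 Hz, 2 degree motion-excited mount
#' oscillation.
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @export
noise_preset <- function(preset = c("none", "low", "drift", "soft-tissue"),
                         seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "none" = sensor_error_model(seed = seed),
    "low" = sensor_error_model(accel_noise_sd = 0.05, gyro_noise_sd = 0.005,
                               seed = seed),
    "drift" = {
      signs <- with_local_seed(seed + 1L,
                               sample(c(-1, 1), 3, replace = TRUE))
      sensor_error_model(accel_noise_sd = 0.05, gyro_noise_sd = 0.005,
                         gyro_bias = deg2rad(0.5) * signs,
                         accel_bias = c(0.05, 0, 0), seed = seed)
    },
    "soft-tissue" = sensor_error_model(accel_noise_sd = 0.05,
                                       gyro_noise_sd = 0.005,
                                       soft_tissue = list(amp_deg = 2,
                                                          freq_hz = 8,
                                                          damping = 3),
                                       seed = seed))
}

#' Corrupt an ideal IMU stream with a sensor error model
#'
#' Applies, in order: the soft-tissue mount-orientation artifact (re-rotating
#' both accel and gyro readings and adding the artifact's own angular rate),
#' constant biases, integrated gyro bias random walk, and white Gaussian
#' noise. Deterministic for a given seed.
#'
#' @param series an [imu_series()].
#' @param err a [sensor_error_model()].
#' @return corrupted [imu_series()] with identical timestamps.
#' @export
corrupt <- function(series, err) {
  stopifnot(inherits(series, "imu_series"), inherits(err, "sensor_error_model"))
  n <- length(series$t); dt <- series$dt
  acc <- series$accel; gyr <- series$gyro
  with_local_seed(err$seed, {
    if (!is.null(err$soft_tissue)) {
      st <- err$soft_tissue
      u <- stats::rnorm(3); u <- u / vnorm(u)   # perturbation axis, sensor frame
      phase <- stats::runif(1, 0, 2 * pi)
      speed <- sqrt(rowSums(gyr^2))
      env <- numeric(n)
      decay <- exp(-st$damping * dt)
      acc_e <- 0
      for (k in seq_len(n)) {
        acc_e <- acc_e * decay + speed[k] * dt
        env[k] <- min(1, acc_e)
      }
      phi <- deg2rad(st$amp_deg) * env * sin(2 * pi * st$freq_hz * series$t + phase)
      dphi <- c(diff(phi) / dt, 0)
      for (k in seq_len(n)) {
        dR <- axis_angle_rotation(u, phi[k])
        gyr[k, ] <- drop(t(dR) %*% gyr[k, ]) + u * dphi[k]
        acc[k, ] <- drop(t(dR) %*% acc[k, ])
      }
    }
    bias_rw <- if (err$gyro_bias_rw_sd > 0) {
      apply(matrix(stats::rnorm(n * 3, sd = err$gyro_bias_rw_sd * sqrt(dt)), n, 3),
            2, cumsum)
    } else matrix(0, n, 3)
    gyr <- gyr + matrix(err$gyro_bias, n, 3, byrow = TRUE) + bias_rw
    acc <- acc + matrix(err$accel_bias, n, 3, byrow = TRUE)
    if (err$gyro_noise_sd > 0) {
      gyr <- gyr + matrix(stats::rnorm(n * 3, sd = err$gyro_noise_sd), n, 3)
    }
    if (err$accel_noise_sd > 0) {
      acc <- acc + matrix(stats::rnorm(n * 3, sd = err$accel_noise_sd), n, 3)
    }
  })
  imu_series(series$t, acc, gyr)
}

#' Subsample a truth trajectory into noisy position/velocity fixes
#'
#' @param traj a [trajectory()].
#' @param rate fix rate, Hz (must not exceed the trajectory rate).
#' @param pos_sd,vel_sd Gaussian noise, m and m/s.
#' @param seed RNG seed.
#' @return a [gps_series()].
#' @export
simulate_gps <- function(traj, rate = 1, pos_sd = 0, vel_sd = 0, seed = 1L) {
  if (length(traj$t) == 0) stopf("empty trajectory")
  dt_traj <- traj$t[2] - traj$t[1]
  if (rate > 1 / dt_traj + 1e-9) stopf("GPS rate exceeds trajectory rate")
  step <- max(1L, as.integer(round(1 / (rate * dt_traj))))
  idx <- seq(1L, length(traj$t), by = step)
  m <- length(idx)
  with_local_seed(seed, {
    pos <- traj$pos[idx, , drop = FALSE] +
      matrix(stats::rnorm(m * 3, sd = pos_sd), m, 3)
    vel <- traj$vel[idx, , drop = FALSE] +
      matrix(stats::rnorm(m * 3, sd = vel_sd), m, 3)
  })
  gps_series(traj$t[idx], pos, vel)
}

#' Simulate a translating IMU at rest attitude
#'
#' A body translating along sinusoidal per-axis world trajectories with
#' identity attitude: the accelerometer reads world acceleration plus gravity
#' on Z, the gyro reads zero. Used for testing position/velocity fusion in
#' isolation from attitude estimation.
#'
#' @param duration record length, s.
#' @param rate sample rate, Hz.
#' @param amp,freq per-axis position amplitudes (m) and frequencies (Hz).
#' @param g gravitational acceleration, m/s^2.
#' @return list with `imu` ([imu_series()]) and `traj` ([trajectory()]).
#' @export
simulate_translation <- function(duration = 60, rate = 100,
                                 amp = c(2, 1, 0), freq = c(0.2, 0.13, 0),
                                 g = 9.81) {
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  pos <- vel <- acc <- matrix(0, n, 3)
  for (ax in 1:3) {
    w <- 2 * pi * freq[ax]
    pos[, ax] <- amp[ax] * sin(w * t)
    vel[, ax] <- amp[ax] * w * cos(w * t)
    acc[, ax] <- -amp[ax] * w^2 * sin(w * t)
  }
  sf <- acc; sf[, 3] <- sf[, 3] + g
  list(imu = imu_series(t, sf, matrix(0, n, 3)),
       traj = trajectory(t, pos, vel))
}
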