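# Linear Kalman filtering and IMU/position-fix fusion.

#' Linear Kalman model matrices
#'
#' @param F state-transition matrix.
#' @param H observation matrix.
#' @param Q process-noise covariance (symmetric PSD).
#' @param R measurement-noise covariance (symmetric PSD).
#' @param B control-input matrix (optional).
#' @return object of class `kalman_model`.
#' @export
kalman_model <- function(F, H, Q, R, B = NULL) {
  F <- as.matrix(F); H <- as.matrix(H); Q <- as.matrix(Q); R <- as.matrix(R)
  d <- nrow(F)
  if (ncol(F) != d) stopf("F must be square")
  if (ncol(H) != d) stopf("H has %d columns, state dimension is %d", ncol(H), d)
  if (any(dim(Q) != d)) stopf("Q dimension mismatch")
  if (any(dim(R) != nrow(H))) stopf("R dimension mismatch")
  chk_psd <- function(M, name) {
    if (max(abs(M - t(M))) > 1e-9) stopf("%s must be symmetric", name)
    if (min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-9) stopf("%s must be positive semidefinite", name)
  }
  chk_psd(Q, "Q"); chk_psd(R, "R")
  if (!is.null(B)) {
    B <- as.matrix(B)
    if (nrow(B) != d) stopf("B row dimension mismatch")
  }
  structure(list(F = F, H = H, Q = Q, R = R, B = B), class = "kalman_model")
}

#' Kalman filter state (estimate and covariance)
#'
#' @param x state estimate vector.
#' @param P covariance matrix (symmetric, numerically PSD).
#' @export
kalman_state <- function(x, P) {
  x <- as.numeric(x); P <- as.matrix(P)
  if (any(dim(P) != length(x))) stopf("P dimension mismatch with x")
  if (max(abs(P - t(P))) > 1e-6) stopf("P must be symmetric")
  structure(list(x = x, P = (P + t(P)) / 2), class = "kalman_state")
}

#' Kalman prediction step
#'
#' `x <- F x + B u`; `P <- F P F' + Q`, with `P` re-symmetrized.
#'
#' @param state a [kalman_state()].
#' @param model a [kalman_model()].
#' @param u control input (required if the model has a B matrix).
#' @return predicted [kalman_state()].
#' @export
kf_predict <- function(state, model, u = NULL) {
  x <- model$F %*% state$x
  if (!is.null(model$B)) {
    if (is.null(u)) stopf("model has a control matrix but no u was given")
    x <- x + model$B %*% u
  }
  P <- model$F %*% state$P %*% t(model$F) + model$Q
  kalman_state(drop(x), (P + t(P)) / 2)
}

#' Kalman measurement update
#'
#' Computes the gain `K = P H' (H P H' + R)^-1`, updates
#' `x <- x + K (z - H x)` and `P <- (I - K H) P`. The gain and innovation are
#' attached as attributes `"gain"` and `"innovation"` for inspection: the
#' gain expresses how strongly the filter trusts the measurement over the
#' model.
#'
#' @param state a [kalman_state()].
#' @param model a [kalman_model()].
#' @param z measurement vector.
#' @return updated [kalman_state()] with attributes `gain` and `innovation`.
#' @export
kf_update <- function(state, model, z) {
  H <- model$H
  if (length(z) != nrow(H)) stopf("measurement dimension mismatch")
  S <- H %*% state$P %*% t(H) + model$R
  K <- tryCatch(state$P %*% t(H) %*% solve(S),
                error = function(e) stopf(
                  "singular innovation covariance (rcond ~ %.2e): %s",
                  rcond(S), conditionMessage(e)))
  innov <- z - drop(H %*% state$x)
  x <- state$x + drop(K %*% innov)
  P <- (diag(length(state$x)) - K %*% H) %*% state$P
  out <- kalman_state(x, (P + t(P)) / 2)
  attr(out, "gain") <- K
  attr(out, "innovation") <- innov
  out
}

cumtrapz1 <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

#' Dead reckoning by trapezoidal double integration
#'
#' @param t uniform timestamps, s.
#' @param accel_world n x 3 world-frame kinematic acceleration, m/s^2
#'   (gravity already removed).
#' @param p0,v0 initial position (m) and velocity (m/s).
#' @return a [trajectory()].
#' @export
dead_reckon <- function(t, accel_world, p0 = c(0, 0, 0), v0 = c(0, 0, 0)) {
  accel_world <- to_mat3(accel_world)
  n <- length(t)
  pos <- vel <- matrix(0, n, 3)
  for (ax in 1:3) {
    vel[, ax] <- v0[ax] + cumtrapz1(t, accel_world[, ax])
    pos[, ax] <- p0[ax] + cumtrapz1(t, vel[, ax])
  }
  trajectory(t, pos, vel)
}

#' Fusion configuration for IMU + position-fix Kalman filtering
#'
#' Each axis carries an independent three-state `[position, velocity,
#' acceleration]` filter. The default transition is the bidiagonal
#' constant-acceleration chain `[1 dt 0; 0 1 dt; 0 0 1]`; `exact_f = TRUE`
#' adds the `dt^2/2` position term of the exactly discretized model.
#'
#' @param q_scale acceleration-error spectral density, (m/s^2)^2/Hz: drives
#'   the process noise injected on the acceleration state and, through the
#'   kinematic coupling, on velocity and position. It must upper-bound the
#'   unmodeled accelerometer errors (bias, scale factor); too small a value
#'   makes the filter overconfident and GPS fixes are effectively ignored.
#' @param r_pos,r_vel fix measurement variances, m^2 and (m/s)^2.
#' @param r_acc accelerometer pseudo-measurement variance, (m/s^2)^2. This
#'   must cover the total accelerometer error -- white noise plus persistent
#'   bias and gravity-compensation residuals -- not just the noise floor: a
#'   too-small value pins the acceleration state to the (possibly biased)
#'   reading, collapses the covariance and starves the fix updates of gain.
#'   The default corresponds to ~0.3 m/s^2 of unmodeled error, typical of an
#'   uncalibrated consumer MEMS accelerometer.
#' @param exact_f use the exactly discretized transition.
#' @param g gravitational acceleration, m/s^2.
#' @export
fusion_config <- function(q_scale = 0.1, r_pos = 1, r_vel = 0.01,
                          r_acc = 0.1, exact_f = FALSE, g = 9.81) {
  structure(list(q_scale = q_scale, r_pos = r_pos, r_vel = r_vel,
                 r_acc = r_acc, exact_f = exact_f, g = g),
            class = "fusion_config")
}

#' Rotate specific force to the world frame and remove gravity
#'
#' @param imu an [imu_series()].
#' @param attitudes an [attitude_trace()] aligned with the series.
#' @param g gravitational acceleration, m/s^2.
#' @return n x 3 matrix of world-frame kinematic acceleration, m/s^2.
#' @export
world_accel <- function(imu, attitudes, g = 9.81) {
  n <- length(imu$t)
  if (length(attitudes$t) != n) stopf("attitude trace length mismatch")
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    R <- rotation_from_euler(euler_zyx(attitudes$yaw[k], attitudes$pitch[k],
                                       attitudes$roll[k]))
    out[k, ] <- drop(R %*% imu$accel[k, ]) - c(0, 0, g)
  }
  out
}

#' Fuse inertial dead reckoning with position/velocity fixes
#'
#' Runs a per-axis `[p, v, a]` Kalman filter: at every IMU sample the state
#' is propagated and the world-frame acceleration (attitude-rotated,
#' gravity-compensated) is applied as a low-variance pseudo-measurement; at
#' every fix epoch the position and velocity are updated. Between fixes the
#' filter runs on prediction alone, so drift grows during fix outages and is
#' pulled back at the next fix.
#'
#' @param imu an [imu_series()].
#' @param attitudes an [attitude_trace()] aligned with the IMU stream.
#' @param gps a [gps_series()] (may be `NULL`: degenerates to dead reckoning
#'   with a warning).
#' @param cfg a [fusion_config()].
#' @return a [trajectory()] with an `innovations` attribute: data frame of
#'   per-epoch position/velocity innovations.
#' @export
fuse_imu_gps <- function(imu, attitudes, gps, cfg = fusion_config()) {
  aw <- world_accel(imu, attitudes, g = cfg$g)
  t <- imu$t; n <- length(t); dt <- imu$dt
  if (is.null(gps) || length(gps$t) == 0) {
    warning("no position fixes supplied: falling back to dead reckoning",
            call. = FALSE)
    return(dead_reckon(t, aw))
  }
  if (min(gps$t) < t[1] - 1e-9 || max(gps$t) > t[n] + 1e-9) {
    stopf("fix timestamps fall outside the IMU time range")
  }
  Fm <- matrix(c(1, dt, if (cfg$exact_f) dt^2 / 2 else 0,
                 0, 1, dt,
                 0, 0, 1), 3, 3, byrow = TRUE)
  # white-noise acceleration-error model: the acceleration state receives
  # spectral density q_scale, and its kinematic integrals inflate velocity
  # and position uncertainty so fixes keep a meaningful gain
  Q <- cfg$q_scale * matrix(c(dt^5 / 20, dt^4 / 8, dt^3 / 6,
                              dt^4 / 8, dt^3 / 3, dt^2 / 2,
                              dt^3 / 6, dt^2 / 2, dt), 3, 3, byrow = TRUE)
  m_acc <- kalman_model(Fm, H = matrix(c(0, 0, 1), 1, 3), Q = Q,
                        R = matrix(cfg$r_acc, 1, 1))
  m_fix <- kalman_model(Fm, H = rbind(c(1, 0, 0), c(0, 1, 0)), Q = Q,
                        R = diag(c(cfg$r_pos, cfg$r_vel)))
  gps_idx <- as.integer(round((gps$t - t[1]) / dt)) + 1L
  gps_at <- integer(n); gps_at[gps_idx] <- seq_along(gps_idx)

  pos <- vel <- matrix(0, n, 3)
  innov <- list()
  for (ax in 1:3) {
    st <- kalman_state(c(gps$pos[1, ax], gps$vel[1, ax], aw[1, ax]), diag(3))
    k0 <- gps_idx[1]
    if (k0 > 1) { pos[1:k0, ax] <- gps$pos[1, ax]; vel[1:k0, ax] <- gps$vel[1, ax] }
    pos[k0, ax] <- st$x[1]; vel[k0, ax] <- st$x[2]
    for (k in (k0 + 1L):n) {
      st <- kf_predict(st, m_acc)
      st <- kf_update(st, m_acc, aw[k, ax])
      gi <- gps_at[k]
      if (gi > 1L) {
        st <- kf_update(st, m_fix, c(gps$pos[gi, ax], gps$vel[gi, ax]))
        innov[[length(innov) + 1L]] <-
          data.frame(t = t[k], axis = ax,
                     pos_innovation = attr(st, "innovation")[1],
                     vel_innovation = attr(st, "innovation")[2])
      }
      pos[k, ax] <- st$x[1]; vel[k, ax] <- st$x[2]
    }
  }
  out <- trajectory(t, pos, vel)
  attr(out, "innovations") <- if (length(innov)) do.call(rbind, innov) else
    data.frame(t = numeric(), axis = integer(),
               pos_innovation = numeric(), vel_innovation = numeric())
  out
}
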