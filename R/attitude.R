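# Per-sensor attitude estimation: accelerometer inclination, gyro
# integration, complementary fusion, stillness detection.

#' Time-stamped ZYX attitude trace
#'
#' @param t timestamps, s.
#' @param yaw,pitch,roll per-sample Euler angles, radians.
#' @param source one of `"accel"`, `"gyro"`, `"fused"`, `"truth"`.
#' @param flagged optional logical vector marking unreliable samples.
#' @export
attitude_trace <- function(t, yaw, pitch, roll, source = "fused",
                           flagged = NULL) {
  n <- length(t)
  if (length(yaw) != n || length(pitch) != n || length(roll) != n) {
    stopf("attitude trace length mismatch")
  }
  if (!all(is.finite(c(yaw, pitch, roll)))) stopf("non-finite attitude angles")
  structure(list(t = as.numeric(t), yaw = as.numeric(yaw),
                 pitch = as.numeric(pitch), roll = as.numeric(roll),
                 source = source, flagged = flagged %||% rep(FALSE, n)),
            class = "attitude_trace")
}

#' @export
print.attitude_trace <- function(x, ...) {
  cat(sprintf("attitude_trace (%s): %d samples over %.3g s\n",
              x$source, length(x$t), diff(range(x$t))))
  invisible(x)
}

#' Detect stillness intervals from accelerometer variance
#'
#' Slides a window over the record and marks windows whose per-axis
#' accelerometer variance all fall below a threshold; contiguous still
#' windows are merged into maximal half-open sample intervals.
#'
#' @param series an [imu_series()].
#' @param window window length, s.
#' @param threshold per-axis variance threshold, (m/s^2)^2.
#' @return integer matrix with columns `start`, `end`: 1-based half-open
#'   sample intervals (samples `start` to `end - 1` are still).
#' @export
detect_still <- function(series, window = 0.5, threshold = 1e-3) {
  stopifnot(inherits(series, "imu_series"))
  n <- length(series$t)
  w <- max(2L, as.integer(round(window / series$dt)))
  if (n < w) stopf("series (%d samples) shorter than window (%d samples)", n, w)
  if (threshold <= 0) stopf("variance threshold must be > 0")
  still_win <- rep(TRUE, n - w + 1L)
  for (ax in 1:3) {
    x <- series$accel[, ax]
    s1 <- cumsum(x); s2 <- cumsum(x^2)
    S1 <- s1[w:n] - c(0, s1[seq_len(n - w)])
    S2 <- s2[w:n] - c(0, s2[seq_len(n - w)])
    v <- pmax(0, (S2 - S1^2 / w) / (w - 1))
    still_win <- still_win & (v < threshold)
  }
  covered <- rep(FALSE, n)
  for (i in which(still_win)) covered[i:(i + w - 1L)] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' Reference attitude from a still interval
#'
#' Averages the per-sample accelerometer roll/pitch over a still interval;
#' yaw is unobservable from gravity and set to 0.
#'
#' @param series an [imu_series()].
#' @param interval length-2 integer `c(start, end)` half-open sample interval.
#' @param check_threshold per-axis variance above which a warning is issued
#'   (the average over a moving interval is unreliable).
#' @return an [euler_zyx()] attitude.
#' @export
reference_attitude <- function(series, interval, check_threshold = 1e-2) {
  stopifnot(inherits(series, "imu_series"))
  i0 <- interval[1]; i1 <- interval[2] - 1L
  if (i1 < i0) stopf("empty interval")
  idx <- i0:i1
  if (length(idx) > 2) {
    v <- apply(series$accel[idx, , drop = FALSE], 2, stats::var)
    if (any(v > check_threshold)) {
      warning("reference_attitude: interval does not look still; ",
              "average attitude is unreliable", call. = FALSE)
    }
  }
  rp <- t(apply(series$accel[idx, , drop = FALSE], 1, accel_roll_pitch))
  euler_zyx(yaw = 0, pitch = mean(rp[, "pitch"]), roll = mean(rp[, "roll"]))
}

#' Per-sample attitude from accelerometer gravity components
#'
#' Roll and pitch from each specific-force sample; yaw fixed at the
#' (unobservable) reference value 0. Samples with near-zero norm are flagged
#' and carry the previous attitude forward.
#'
#' @param series an [imu_series()].
#' @param eps minimum admissible sample norm, m/s^2.
#' @return an [attitude_trace()] with source `"accel"`.
#' @export
attitude_from_accel <- function(series, eps = 0.1) {
  stopifnot(inherits(series, "imu_series"))
  n <- length(series$t)
  roll <- pitch <- numeric(n)
  flagged <- rep(FALSE, n)
  prev <- c(roll = 0, pitch = 0)
  for (k in seq_len(n)) {
    s <- series$accel[k, ]
    if (sqrt(sum(s^2)) <= eps) {
      flagged[k] <- TRUE
      rp <- prev
    } else {
      rp <- accel_roll_pitch(s, eps = eps)
      prev <- rp
    }
    roll[k] <- rp[["roll"]]; pitch[k] <- rp[["pitch"]]
  }
  if (any(flagged)) {
    warning(sprintf("attitude_from_accel: %d near-zero-norm samples flagged",
                    sum(flagged)), call. = FALSE)
  }
  attitude_trace(series$t, yaw = numeric(n), pitch = pitch, roll = roll,
                 source = "accel", flagged = flagged)
}

#' Attitude by explicit-Euler integration of gyroscope rates
#'
#' First-order integration of the ZYX Euler-rate kinematics: at each step the
#' body rates are mapped to Euler-angle rates at the current attitude and
#' advanced by one sampling period.
#'
#' @param series an [imu_series()].
#' @param initial initial [euler_zyx()] attitude (typically the accelerometer
#'   reference attitude from a leading still segment).
#' @param delta gimbal guard passed to [body_rates_to_euler_rates()].
#' @return an [attitude_trace()] with source `"gyro"`.
#' @export
integrate_gyro <- function(series, initial = euler_zyx(), delta = 1e-3) {
  stopifnot(inherits(series, "imu_series"))
  initial <- as_euler(initial)
  n <- length(series$t); dt <- series$dt
  yaw <- pitch <- roll <- numeric(n)
  yaw[1] <- initial[["yaw"]]; pitch[1] <- initial[["pitch"]]; roll[1] <- initial[["roll"]]
  gy <- series$gyro
  for (k in seq_len(n - 1L)) {
    b <- pitch[k]
    if (abs(b) >= pi / 2 - delta) {
      stopf("gimbal proximity at sample %d: |pitch| = %.4f rad", k, abs(b))
    }
    sr <- sin(roll[k]); cr <- cos(roll[k])
    p <- gy[k, 1]; q <- gy[k, 2]; r <- gy[k, 3]
    qr <- q * sr + r * cr
    yaw[k + 1] <- yaw[k] + dt * qr / cos(b)
    pitch[k + 1] <- pitch[k] + dt * (q * cr - r * sr)
    roll[k + 1] <- roll[k] + dt * (p + tan(b) * qr)
  }
  attitude_trace(series$t, yaw, pitch, roll, source = "gyro")
}

#' Complementary fusion of accelerometer and gyro attitudes
#'
#' Per-step recursive complementary filter: the fused roll/pitch blend the
#' gyro increment added to the previous fused value (weight `alpha`) with the
#' instantaneous accelerometer angle (weight `1 - alpha`). Yaw is taken from
#' the gyro alone, since the accelerometer cannot observe heading. The blend
#' coefficient can equivalently be given as `K = 1 - alpha`, the weight of
#' the accelerometer-minus-gyro correction.
#'
#' @param accel_trace an [attitude_trace()] with source `"accel"`.
#' @param gyro_trace an [attitude_trace()] with source `"gyro"`.
#' @param alpha gyro weight in (0, 1); default 0.98.
#' @param K optional accelerometer correction weight; if supplied,
#'   `alpha = 1 - K`.
#' @return an [attitude_trace()] with source `"fused"`.
#' @export
complementary_filter <- function(accel_trace, gyro_trace, alpha = 0.98,
                                 K = NULL) {
  if (!is.null(K)) alpha <- 1 - K
  if (alpha < 0 || alpha > 1) stopf("blend coefficient must lie in [0, 1]")
  n <- length(accel_trace$t)
  if (length(gyro_trace$t) != n ||
      max(abs(accel_trace$t - gyro_trace$t)) > 1e-9) {
    stopf("accel and gyro traces must share timestamps")
  }
  roll <- pitch <- numeric(n)
  roll[1] <- alpha * gyro_trace$roll[1] + (1 - alpha) * accel_trace$roll[1]
  pitch[1] <- alpha * gyro_trace$pitch[1] + (1 - alpha) * accel_trace$pitch[1]
  for (k in 2:n) {
    droll <- gyro_trace$roll[k] - gyro_trace$roll[k - 1]
    dpitch <- gyro_trace$pitch[k] - gyro_trace$pitch[k - 1]
    roll[k] <- alpha * (roll[k - 1] + droll) + (1 - alpha) * accel_trace$roll[k]
    pitch[k] <- alpha * (pitch[k - 1] + dpitch) + (1 - alpha) * accel_trace$pitch[k]
  }
  attitude_trace(accel_trace$t, yaw = gyro_trace$yaw, pitch = pitch,
                 roll = roll, source = "fused")
}
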