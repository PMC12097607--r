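# Experiment harness, summary statistics and file I/O.

#' Round half away from zero
#'
#' Reporting convention for degree-valued tables: one decimal, halves
#' rounded up (base R's `round` rounds half to even, so 32.65 would print
#' as 32.6).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Group summary statistics (mean and sample standard deviation)
#'
#' @param values numeric vector, degrees (n >= 2).
#' @return object of class `group_stats`: list with `n`, `mean`, `sd`.
#' @export
group_stats <- function(values) {
  if (length(values) < 2) stopf("need at least 2 values")
  structure(list(n = length(values), mean = mean(values),
                 sd = stats::sd(values)), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("n = %d, %s +/- %s\n", x$n, round_half_up(x$mean),
              round_half_up(x$sd)))
  invisible(x)
}

#' Independent two-sample t test
#'
#' Pooled-variance Student t by default (Welch optional), two-sided p value.
#' Degenerate case: zero pooled variance with equal means gives t = 0,
#' p = 1; with unequal means the statistic is infinite and an error is
#' raised.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param equal_variance pooled-variance Student test if `TRUE` (default),
#'   Welch if `FALSE`.
#' @return object of class `t_test_result`: list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 1),
                       class = "t_test_result"))
    }
    stopf("zero variance with unequal means: t statistic is infinite")
  }
  ht <- stats::t.test(x, y, var.equal = equal_variance)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value), class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Bundled joint-angle measurements from a drift / soft-tissue error study
#'
#' Repeated joint-angle measurements (degrees) from three conditions of an
#' IMU error-source study: a control group measured normally, a group with
#' artificially introduced sensor drift, and a group with simulated
#' soft-tissue artifacts. Useful as a worked example for [group_stats()] and
#' [two_sample_t()].
#'
#' @return named list of three numeric vectors: `control`, `drift`,
#'   `soft_tissue`.
#' @export
imu_error_study_data <- function() {
  list(control = c(30.0, 31.2, 30.5, 29.8, 30.3, 30.7, 31.0, 30.2, 30.6, 30.9),
       drift = c(32.1, 33.5, 32.8, 31.9, 32.4, 33.0, 32.7, 32.3, 33.2, 32.6),
       soft_tissue = c(28.5, 29.0, 28.8, 29.2, 28.7, 29.1, 28.9, 29.3, 29.0,
                       28.6))
}

#' Error-injection experiment over pipeline variants
#'
#' For each error condition and seed: simulates the hinge rig, corrupts both
#' sensor streams, runs four pipeline variants, and scores them against the
#' simulator truth. The variants are `raw` (calibration and gyro-only angle
#' integration on the raw streams, with no denoising, band-limiting or
#' fusion, and a dead-reckoned trajectory), `gps` (raw angle;
#' position-fix-corrected trajectory), `constraints` (the full
#' kinematic-constraint pipeline: wavelet-denoised band-limited calibration
#' and complementary-fused joint angle; dead-reckoned trajectory) and
#' `both`.
#' Scores are the joint-angle mean absolute error and RMSE (degrees) and the
#' sensor-trajectory RMS position error (m). The specific force is rotated
#' to the world frame with the simulator's truth attitude so that the
#' trajectory scores isolate the injected sensor errors. Deterministic given
#' the seeds.
#'
#' @param conditions named list of [sensor_error_model()] factories: each
#'   element is a function of a seed returning the error model; defaults to
#'   the control / drift / soft-tissue presets.
#' @param seeds integer vector of seeds (one run per seed per condition).
#' @param rig a [hinge_rig()].
#' @param motion a [motion_profile()].
#' @param gps_pos_sd,gps_vel_sd fix noise, m and m/s.
#' @param coeff complementary fusion coefficient.
#' @return object of class `experiment_report`: list with `runs` (data frame
#'   of per-run scores), `summary` (per condition x variant x metric
#'   [group_stats()]), `tests` (t tests of each error condition against the
#'   control, per variant), and the echoed seeds.
#' @export
run_error_experiment <- function(conditions = NULL,
                                 seeds = 1:10,
                                 rig = hinge_rig(),
                                 motion = standard_protocol(),
                                 gps_pos_sd = 1, gps_vel_sd = 0.1,
                                 coeff = 0.98) {
  if (is.null(conditions)) {
    conditions <- list(
      control = function(seed) noise_preset("low", seed = seed),
      drift = function(seed) noise_preset("drift", seed = seed),
      soft_tissue = function(seed) noise_preset("soft-tissue", seed = seed))
  }
  if (length(conditions) < 1 || length(seeds) < 1) {
    stopf("need at least one condition and one seed")
  }
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stopf("conditions must be named")
  }
  ds <- simulate_hinge(rig, motion)
  truth_deg <- rad2deg(ds$truth$angle$angle)
  alpha0 <- ds$truth$angle$angle[1]
  aw_true <- matrix(0, length(ds$t), 3)
  runs <- list()
  for (cond in names(conditions)) {
    for (seed in seeds) {
      err1 <- conditions[[cond]](seed)
      err2 <- conditions[[cond]](seed + 10000L)
      imu1 <- corrupt(ds$imu1, err1)
      imu2 <- corrupt(ds$imu2, err2)
      calib <- tryCatch(calibrate_joint(imu1, imu2),
                        error = function(e) ds$truth$calib)
      calib_raw <- tryCatch(
        calibrate_joint(imu1, imu2, denoise = NULL, bandlimit_hz = NULL),
        error = function(e) calib)
      ang_raw <- joint_angle(imu1, imu2, calib_raw, method = "gyro",
                             alpha0 = alpha0)
      ang_con <- joint_angle(imu1, imu2, calib, method = "fused",
                             alpha0 = alpha0, coeff = coeff,
                             denoise = wavelet_config(), bandlimit_hz = 3)
      # trajectory branch: world accel via truth attitude of sensor 2
      att2 <- attitude_trace(ds$t, ds$truth$att2[, 1], ds$truth$att2[, 2],
                             ds$truth$att2[, 3], source = "truth")
      aw <- world_accel(imu2, att2, g = rig$g)
      dr <- dead_reckon(ds$t, aw, p0 = ds$traj2$pos[1, ],
                        v0 = ds$traj2$vel[1, ])
      gps <- simulate_gps(ds$traj2, rate = 1, pos_sd = gps_pos_sd,
                          vel_sd = gps_vel_sd, seed = seed + 20000L)
      kf <- fuse_imu_gps(imu2, att2, gps, fusion_config(g = rig$g))
      traj_rms <- function(traj) {
        sqrt(mean(rowSums((traj$pos - ds$traj2$pos)^2)))
      }
      ang_err <- function(trace) {
        e <- rad2deg(trace$angle) - truth_deg
        c(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
      }
      er <- ang_err(ang_raw); ec <- ang_err(ang_con)
      rms_dr <- traj_rms(dr); rms_kf <- traj_rms(kf)
      for (variant in c("raw", "gps", "constraints", "both")) {
        ae <- if (variant %in% c("raw", "gps")) er else ec
        tr <- if (variant %in% c("raw", "constraints")) rms_dr else rms_kf
        runs[[length(runs) + 1L]] <- data.frame(
          condition = cond, seed = seed, variant = variant,
          angle_mae = ae[["mae"]], angle_rmse = ae[["rmse"]],
          traj_rms = tr)
      }
    }
  }
  runs <- do.call(rbind, runs)
  summarize <- function(metric) {
    out <- list()
    for (cond in names(conditions)) for (v in unique(runs$variant)) {
      vals <- runs[[metric]][runs$condition == cond & runs$variant == v]
      if (length(vals) >= 2) out[[paste(cond, v, sep = ".")]] <- group_stats(vals)
    }
    out
  }
  tests <- list()
  if ("control" %in% names(conditions) && length(seeds) >= 2) {
    for (cond in setdiff(names(conditions), "control")) {
      for (v in unique(runs$variant)) {
        xs <- runs$angle_mae[runs$condition == cond & runs$variant == v]
        ys <- runs$angle_mae[runs$condition == "control" & runs$variant == v]
        tests[[paste(cond, v, sep = ".")]] <- two_sample_t(xs, ys)
      }
    }
  }
  structure(list(runs = runs,
                 summary = list(angle_mae = summarize("angle_mae"),
                                traj_rms = summarize("traj_rms")),
                 tests = tests, seeds = seeds),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("error-injection experiment:", length(unique(x$runs$condition)),
      "conditions x", length(x$seeds), "seeds\n")
  agg <- stats::aggregate(cbind(angle_mae, traj_rms) ~ condition + variant,
                          data = x$runs, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Standard synthetic movement protocol
#'
#' The default study condition for calibration and angle-estimation
#' experiments: 3 s still, 20 s of 30 degree / 0.5 Hz hinge flexion with a
#' simultaneous whole-limb wobble (25 degree / 0.5 Hz about the world
#' vertical composed with 18 degree / 0.37 Hz about the lateral axis), then
#' 3 s still, all ramped smoothly. The deliberate two-axis wobble mimics a
#' functional calibration movement: it makes the proximal sensor's
#' angular-velocity direction vary and keeps its lever-arm accelerations
#' above the accelerometer noise floor, which is what renders the proximal
#' hinge axis and lever arm identifiable from the kinematic constraints.
#'
#' @param duration active-motion duration, s.
#' @param amplitude_deg hinge sinusoid amplitude, degrees.
#' @return a [motion_profile()].
#' @export
standard_protocol <- function(duration = 20, amplitude_deg = 30) {
  motion_profile(type = "sinusoid", amplitude_deg = amplitude_deg,
                 freq_hz = 0.5, duration = duration,
                 still_lead = 3, still_tail = 3, smooth = 1,
                 base_rotation = list(
                   list(axis = c(0, 0, 1), amplitude_deg = 25, freq_hz = 0.5),
                   list(axis = c(0, 1, 0), amplitude_deg = 18,
                        freq_hz = 0.37)))
}

# ---- CSV / JSON I/O ---------------------------------------------------------

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  }
  for (col in required) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stopf("%s: non-finite value in column '%s' at data row %d",
            path, col, bad[1])
    }
  }
  df
}

#' Read an IMU stream from CSV
#'
#' Expects columns `t, ax, ay, az, gx, gy, gz` (matched by name, any order;
#' SI units: s, m/s^2, rad/s). Timestamps must be uniform within 1e-6 s;
#' records with gaps are rejected rather than silently interpolated.
#'
#' @param path CSV file path.
#' @return an [imu_series()].
#' @export
read_imu_csv <- function(path) {
  df <- read_csv_checked(path, c("t", "ax", "ay", "az", "gx", "gy", "gz"))
  dt <- diff(df$t)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6) {
    stopf("%s: non-uniform timestamps (max deviation %.3g s); resample first",
          path, max(abs(dt - dt[1])))
  }
  imu_series(df$t, as.matrix(df[, c("ax", "ay", "az")]),
             as.matrix(df[, c("gx", "gy", "gz")]))
}

#' Write an IMU stream to CSV
#' @param series an [imu_series()].
#' @param path output path.
#' @export
write_imu_csv <- function(series, path) {
  df <- data.frame(t = series$t,
                   ax = series$accel[, 1], ay = series$accel[, 2],
                   az = series$accel[, 3],
                   gx = series$gyro[, 1], gy = series$gyro[, 2],
                   gz = series$gyro[, 3])
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a position/velocity fix stream from CSV
#'
#' Expects columns `t, px, py, pz, vx, vy, vz` (s, m, m/s).
#'
#' @param path CSV file path.
#' @return a [gps_series()].
#' @export
read_gps_csv <- function(path) {
  df <- read_csv_checked(path, c("t", "px", "py", "pz", "vx", "vy", "vz"))
  gps_series(df$t, as.matrix(df[, c("px", "py", "pz")]),
             as.matrix(df[, c("vx", "vy", "vz")]))
}

#' Write a position/velocity stream to CSV
#' @param traj a [trajectory()] or [gps_series()].
#' @param path output path.
#' @export
write_gps_csv <- function(traj, path) {
  df <- data.frame(t = traj$t,
                   px = traj$pos[, 1], py = traj$pos[, 2], pz = traj$pos[, 3],
                   vx = traj$vel[, 1], vy = traj$vel[, 2], vz = traj$vel[, 3])
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an attitude trace to CSV (degrees on disk)
#' @param trace an [attitude_trace()].
#' @param path output path.
#' @export
write_attitude_csv <- function(trace, path) {
  df <- data.frame(t = trace$t, yaw = rad2deg(trace$yaw),
                   pitch = rad2deg(trace$pitch),
                   roll = rad2deg(trace$roll), source = trace$source)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an attitude trace from CSV
#' @param path CSV with columns `t`, `yaw`, `pitch`, `roll` (degrees) and
#'   optionally `source`.
#' @return an [attitude_trace()].
#' @export
read_attitude_csv <- function(path) {
  df <- read_csv_checked(path, c("t", "yaw", "pitch", "roll"))
  attitude_trace(df$t, deg2rad(df$yaw), deg2rad(df$pitch), deg2rad(df$roll),
                 source = if ("source" %in% names(df)) df$source[1] else
                   "fused")
}

#' Write an angle trace to CSV (degrees on disk)
#' @param trace an [angle_trace()].
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t = trace$t, angle_deg = rad2deg(trace$angle),
                   source = trace$source, flagged = trace$flagged)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an angle trace from CSV
#' @param path CSV with columns `t`, `angle_deg` (and optionally `source`).
#' @return an [angle_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- read_csv_checked(path, c("t", "angle_deg"))
  angle_trace(df$t, deg2rad(df$angle_deg),
              source = if ("source" %in% names(df)) df$source[1] else "fused")
}

#' Write a joint calibration to JSON
#' @param calib a [joint_calibration()].
#' @param path output path.
#' @export
write_calib_json <- function(calib, path) {
  jsonlite::write_json(list(j1 = calib$j1, j2 = calib$j2,
                            o1 = calib$o1, o2 = calib$o2,
                            axis_rms = calib$axis_rms,
                            center_rms = calib$center_rms,
                            tool = paste0("jointkin ",
                                          utils::packageVersion("jointkin"))),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a joint calibration from JSON
#' @param path JSON file written by [write_calib_json()].
#' @return a [joint_calibration()].
#' @export
read_calib_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  joint_calibration(j1 = x$j1, j2 = x$j2, o1 = x$o1, o2 = x$o2,
                    axis_rms = x$axis_rms %||% NA_real_,
                    center_rms = x$center_rms %||% NA_real_)
}
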