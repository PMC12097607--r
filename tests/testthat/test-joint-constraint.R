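# Hinge self-calibration and joint-angle estimation.

test_that("build_joint_dataset differentiates rates exactly where expected", {
  n <- 101
  t <- seq(0, 1, by = 0.01)
  gconst <- matrix(rep(c(0.1, -0.2, 0.3), each = n), n, 3)
  acc <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  i1 <- imu_series(t, acc, gconst)
  W <- build_joint_dataset(i1, i1)
  expect_equal(max(abs(W$dg1)), 0)
  # linear ramp: derivative exact everywhere away from the ends
  glin <- outer(t, c(2, -1, 0.5))
  W2 <- build_joint_dataset(imu_series(t, acc, glin),
                            imu_series(t, acc, glin))
  expect_equal(W2$dg1[2:(n - 1), ],
               matrix(rep(c(2, -1, 0.5), each = n - 2), n - 2, 3),
               tolerance = 1e-9)
  # quadratic: interior exact (centered stencils), endpoint error O(dt)
  gq <- outer(t^2, c(1, 0, 0))
  W3 <- build_joint_dataset(imu_series(t, acc, gq), imu_series(t, acc, gq))
  expect_equal(W3$dg1[3:(n - 2), 1], 2 * t[3:(n - 2)], tolerance = 1e-9)
  expect_equal(W3$dg1[n, 1], 2 * t[n], tolerance = 0.011)
  expect_error(build_joint_dataset(
    imu_series(t, acc, gconst),
    imu_series(t + 0.5, acc, gconst)), "timestamps")
})

test_that("axis residual vanishes at truth and respects sign symmetry", {
  ds <- std_dataset()
  tc <- ds$truth$calib
  W <- build_joint_dataset(ds$imu1, ds$imu2)
  r <- axis_residual(W, tc$j1, tc$j2)
  expect_lt(max(abs(r)), 1e-9)
  expect_equal(axis_residual(W, -tc$j1, -tc$j2), r)
  # wrong axes on moving data produce nonzero residuals
  wrong <- axis_residual(W, c(0, 0, 1), c(0, 1, 0))
  expect_gt(max(abs(wrong)), 0.1)
  expect_error(axis_residual(W, c(1, 1, 0), tc$j2), "unit")
})

test_that("truth axes sit at the global minimum of the axis cost", {
  ds <- std_dataset()
  tc <- ds$truth$calib
  W <- build_joint_dataset(ds$imu1, ds$imu2)
  moving <- sqrt(rowSums(W$g1^2)) > 0.2 | sqrt(rowSums(W$g2^2)) > 0.2
  sub <- list(g1 = W$g1[moving, ], g2 = W$g2[moving, ])
  cost <- function(j1, j2) sum((sqrt(rowSums((sub$g1 %*% rbind(
    c(0, j1[3], -j1[2]), c(-j1[3], 0, j1[1]), c(j1[2], -j1[1], 0)))^2)) -
      sqrt(rowSums((sub$g2 %*% rbind(c(0, j2[3], -j2[2]),
                                     c(-j2[3], 0, j2[1]),
                                     c(j2[2], -j2[1], 0)))^2)))^2)
  truth_cost <- cost(tc$j1, tc$j2)
  set.seed(17)
  for (i in 1:1000) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    expect_gte(cost(u, v), truth_cost - 1e-8)
  }
})

test_that("axis estimation recovers truth, noise-free and noisy", {
  ds <- std_dataset()
  tc <- ds$truth$calib
  W <- build_joint_dataset(ds$imu1, ds$imu2)
  ax <- estimate_joint_axes(W)
  expect_lt(angle_between_axes(ax$j1, tc$j1), 0.5)
  expect_lt(angle_between_axes(ax$j2, tc$j2), 0.5)
  # sign convention: hinge rate positive at motion onset (protocol flexes
  # upward first), so the signed dot products with truth are +1
  expect_gt(sum(ax$j1 * tc$j1), 0.99)
  expect_gt(sum(ax$j2 * tc$j2), 0.99)
  i1 <- corrupt(ds$imu1, sensor_error_model(accel_noise_sd = 0.05,
                                            gyro_noise_sd = 0.02, seed = 31))
  i2 <- corrupt(ds$imu2, sensor_error_model(accel_noise_sd = 0.05,
                                            gyro_noise_sd = 0.02, seed = 32))
  Wn <- build_joint_dataset(i1, i2, denoise = wavelet_config())
  axn <- estimate_joint_axes(Wn)
  expect_lt(angle_between_axes(axn$j1, tc$j1), 2)
  expect_lt(angle_between_axes(axn$j2, tc$j2), 2)
  # still record: unidentifiable
  ds0 <- simulate_hinge(hinge_rig(rate = 50),
                        motion_profile(type = "still", duration = 3,
                                       still_lead = 1, still_tail = 1,
                                       smooth = 1))
  W0 <- build_joint_dataset(ds0$imu1, ds0$imu2)
  expect_error(estimate_joint_axes(W0), "excitation")
})

test_that("rotational_accel reproduces closed-form special cases", {
  expect_equal(rotational_accel(c(1, 2, 3), c(0.1, 0, 0), c(0, 0, 0)),
               c(0, 0, 0))
  # constant spin about z with radial arm: pure centripetal -w^2 r
  w <- 3; r <- 0.2
  expect_equal(rotational_accel(c(0, 0, w), c(0, 0, 0), c(r, 0, 0)),
               c(-w^2 * r, 0, 0))
  # zero rate: pure tangential dg x o
  expect_equal(rotational_accel(c(0, 0, 0), c(0, 0, 2), c(0.1, 0, 0)),
               c(0, 0.2, 0))
})

test_that("center residual vanishes at truth and grows along perturbations", {
  ds <- std_dataset()
  tc <- ds$truth$calib
  W <- build_joint_dataset(ds$imu1, ds$imu2)
  # with the simulator's exact angular accelerations the residual is ~0
  We <- W; We$dg1 <- ds$truth$dg1; We$dg2 <- ds$truth$dg2
  expect_lt(max(abs(center_residual(We, tc$o1, tc$o2))), 1e-8)
  # monotone growth along a perturbation ray
  dirv <- c(0.02, -0.015, 0.01)
  rms_at <- function(s) sqrt(mean(center_residual(We, tc$o1 + s * dirv,
                                                  tc$o2)^2))
  vals <- vapply(c(0, 0.5, 1, 2, 4), rms_at, numeric(1))
  expect_true(all(diff(vals) > 0))
  # co-located identical sensors with zero arms: identically zero
  Wsame <- build_joint_dataset(ds$imu1, ds$imu1)
  expect_equal(max(abs(center_residual(Wsame, c(0, 0, 0), c(0, 0, 0)))), 0)
})

test_that("lever arms are recovered noise-free and under sensor noise", {
  ds <- std_dataset()
  tc <- ds$truth$calib
  W <- build_joint_dataset(ds$imu1, ds$imu2)
  ax <- estimate_joint_axes(W)
  ce <- estimate_joint_centers(W, axes = ax)
  expect_lt(1000 * sqrt(sum((ce$o1 - tc$o1)^2)), 5)
  expect_lt(1000 * sqrt(sum((ce$o2 - tc$o2)^2)), 5)
  i1 <- corrupt(ds$imu1, sensor_error_model(accel_noise_sd = 0.05,
                                            gyro_noise_sd = 0.02, seed = 41))
  i2 <- corrupt(ds$imu2, sensor_error_model(accel_noise_sd = 0.05,
                                            gyro_noise_sd = 0.02, seed = 42))
  cal <- calibrate_joint(i1, i2)
  expect_lt(1000 * sqrt(sum((cal$o1 - tc$o1)^2)), 15)
  expect_lt(1000 * sqrt(sum((cal$o2 - tc$o2)^2)), 15)
  # constant-rate motion leaves the tangential term unidentifiable
  dsr <- simulate_hinge(hinge_rig(rate = 50),
                        motion_profile(type = "ramp", rate_dps = 20,
                                       duration = 30, still_lead = 0.2,
                                       still_tail = 0.2, smooth = 14.9))
  Wr <- build_joint_dataset(dsr$imu1, dsr$imu2)
  expect_error(estimate_joint_centers(Wr, accel_floor = 0.2),
               "unidentifiable|excitation")
})

test_that("gyro joint angle integrates the projected rate difference", {
  ds <- std_dataset()
  tc <- ds$truth$calib
  W <- build_joint_dataset(ds$imu1, ds$imu2)
  a0 <- ds$truth$angle$angle[1]
  af <- joint_angle_gyro(W, tc$j1, tc$j2, alpha0 = a0)
  expect_lt(rmse_deg(af$angle, ds$truth$angle$angle), 0.01)
  # constant rate: alpha(T) - alpha0 = w T
  dsr <- simulate_hinge(hinge_rig(rate = 100),
                        motion_profile(type = "ramp", rate_dps = 15,
                                       duration = 4, still_lead = 0.5,
                                       still_tail = 0.5, smooth = 1))
  Wr <- build_joint_dataset(dsr$imu1, dsr$imu2)
  tcr <- dsr$truth$calib
  afr <- joint_angle_gyro(Wr, tcr$j1, tcr$j2, alpha0 = 0)
  n <- length(afr$t)
  expect_equal(afr$angle[n] * 180 / pi,
               dsr$truth$angle$angle[n] * 180 / pi, tolerance = 1e-4)
  # common-mode bias cancels exactly; single-sensor bias drifts at beta
  still <- simulate_hinge(hinge_rig(rate = 50),
                          motion_profile(type = "still", duration = 10,
                                         still_lead = 1, still_tail = 1,
                                         smooth = 1))
  tcs <- still$truth$calib
  beta <- 0.02
  both <- build_joint_dataset(
    imu_series(still$t, still$imu1$accel,
               still$imu1$gyro + matrix(beta * tcs$j1, length(still$t), 3,
                                        byrow = TRUE)),
    imu_series(still$t, still$imu2$accel,
               still$imu2$gyro + matrix(beta * tcs$j2, length(still$t), 3,
                                        byrow = TRUE)))
  af_both <- joint_angle_gyro(both, tcs$j1, tcs$j2)
  expect_lt(max(abs(af_both$angle)), 1e-12)
  one <- build_joint_dataset(
    imu_series(still$t, still$imu1$accel,
               still$imu1$gyro + matrix(beta * tcs$j1, length(still$t), 3,
                                        byrow = TRUE)),
    still$imu2)
  af_one <- joint_angle_gyro(one, tcs$j1, tcs$j2)
  Tn <- max(still$t)
  expect_equal(af_one$angle[length(still$t)], beta * Tn, tolerance = 1e-9)
})

test_that("accelerometer joint angle tracks slow flexion and still poses", {
  # slow quasi-static flexion 0 -> 60 degrees
  ds <- simulate_hinge(hinge_rig(rate = 100),
                       motion_profile(type = "ramp", rate_dps = 6,
                                      duration = 10, still_lead = 2,
                                      still_tail = 2, smooth = 1))
  tc <- ds$truth$calib
  W <- build_joint_dataset(ds$imu1, ds$imu2)
  as_tr <- joint_angle_accel(W, tc, alpha0 = 0, ref = c(1L, 100L))
  err <- abs(as_tr$angle - ds$truth$angle$angle) * 180 / pi
  expect_lt(max(err[!as_tr$flagged]), 2)
  # still at a fixed angle: recovered within 0.5 degrees
  ds30 <- simulate_hinge(hinge_rig(rate = 50),
                         motion_profile(type = "still", duration = 2,
                                        still_lead = 1, still_tail = 1,
                                        smooth = 0.5, base_angle_deg = 30))
  W30 <- build_joint_dataset(ds30$imu1, ds30$imu2)
  tr30 <- joint_angle_accel(W30, ds30$truth$calib,
                            alpha0 = ds30$truth$angle$angle[1],
                            ref = c(1L, 50L))
  expect_lt(max(abs(tr30$angle - ds30$truth$angle$angle)) * 180 / pi, 0.5)
})

test_that("complementary joint-angle fusion beats both parents under error", {
  ds <- std_dataset()
  tc <- ds$truth$calib
  a0 <- ds$truth$angle$angle[1]
  i1 <- corrupt(ds$imu1, sensor_error_model(accel_noise_sd = 0.05,
                                            gyro_noise_sd = 0.01,
                                            gyro_bias = c(0.01, -0.008, 0.012),
                                            seed = 51))
  i2 <- corrupt(ds$imu2, sensor_error_model(accel_noise_sd = 0.05,
                                            gyro_noise_sd = 0.01, seed = 52))
  W <- build_joint_dataset(i1, i2, denoise = wavelet_config())
  af <- joint_angle_gyro(W, tc$j1, tc$j2, alpha0 = a0)
  as_tr <- joint_angle_accel(W, tc, alpha0 = a0, ref = c(1L, 200L))
  fu <- fuse_joint_angles(as_tr, af, coeff = 0.98)
  truth <- ds$truth$angle$angle
  expect_lt(rmse_deg(fu$angle, truth),
            min(rmse_deg(af$angle, truth), rmse_deg(as_tr$angle, truth)))
  # endpoints collapse to the parent traces
  expect_equal(fuse_joint_angles(as_tr, af, coeff = 1)$angle, af$angle,
               tolerance = 1e-12)
  expect_equal(fuse_joint_angles(as_tr, af, coeff = 0)$angle, as_tr$angle,
               tolerance = 1e-12)
})

test_that("SVD joint angle matches truth and the fused trace", {
  ds <- std_dataset()
  tc <- ds$truth$calib
  a0 <- ds$truth$angle$angle[1]
  sv <- joint_angle(ds$imu1, ds$imu2, tc, method = "svd", alpha0 = a0)
  expect_lt(rmse_deg(sv$angle, ds$truth$angle$angle), 1)
  fu <- joint_angle(ds$imu1, ds$imu2, tc, method = "fused", alpha0 = a0)
  expect_lt(rmse_deg(sv$angle, fu$angle), 1)
  # identical static vectors: angle 0 everywhere
  ds0 <- simulate_hinge(hinge_rig(rate = 50),
                        motion_profile(type = "still", duration = 2,
                                       still_lead = 1, still_tail = 1,
                                       smooth = 0.5))
  W0 <- build_joint_dataset(ds0$imu1, ds0$imu1)
  cal0 <- joint_calibration(ds0$truth$calib$j1, ds0$truth$calib$j1,
                            o1 = c(0, 0, 0), o2 = c(0, 0, 0))
  sv0 <- joint_angle_svd(W0, cal0, ref = c(1L, 50L))
  expect_lt(max(abs(sv0$angle)), 1e-9)
})

test_that("range of motion summarizes traces correctly", {
  tr <- angle_trace(1:100, rep(0.1, 100))
  rom <- range_of_motion(tr)
  expect_equal(rom$range, 0)
  t <- seq(0, 10, by = 0.01)
  rom2 <- range_of_motion(angle_trace(t, (30 * pi / 180) * sin(2 * pi * t)))
  expect_equal(rom2$range, 60, tolerance = 0.01)
  expect_equal(rom2$max, 30, tolerance = 0.01)
  # noisy flexion 0 -> 90: range within 2 degrees
  set.seed(61)
  flex <- (90 * pi / 180) * (1 - cos(pi * t / 10)) / 2 +
    stats::rnorm(length(t), sd = 0.5 * pi / 180)
  rom3 <- range_of_motion(angle_trace(t, flex))
  expect_lt(abs(rom3$range - 90), 2)
  expect_error(range_of_motion(angle_trace(numeric(0), numeric(0))),
               "non-empty")
})

test_that("pipeline runtime scales roughly linearly in sample count", {
  mp1 <- standard_protocol(duration = 10)
  mp2 <- standard_protocol(duration = 20)
  rig <- hinge_rig()
  run_one <- function(mp) {
    ds <- simulate_hinge(rig, mp)
    W <- build_joint_dataset(ds$imu1, ds$imu2)
    tc <- ds$truth$calib
    system.time({
      joint_angle_gyro(W, tc$j1, tc$j2)
      joint_angle_accel(W, tc, ref = c(1L, 100L))
    })[["elapsed"]]
  }
  run_one(mp1)                      # warm-up
  t1 <- max(run_one(mp1), 0.02)     # floor against timer granularity
  t2 <- run_one(mp2)
  expect_lt(t2 / t1, 2.5 * 2)  # ~2x samples within 2.5x time, with slack
})
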