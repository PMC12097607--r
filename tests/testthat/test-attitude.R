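# Stillness detection, reference attitude, gyro integration, complementary
# fusion.

make_still_series <- function(att = euler_zyx(), n = 400, rate = 100,
                              noise = 0, seed = 1) {
  t <- seq(0, by = 1 / rate, length.out = n)
  acc <- matrix(rep(body_gravity(att), each = n), n, 3)
  s <- imu_series(t, acc, matrix(0, n, 3))
  if (noise > 0) s <- corrupt(s, sensor_error_model(accel_noise_sd = noise,
                                                    seed = seed))
  s
}

test_that("detect_still classifies still, moving and mixed records", {
  s <- make_still_series(noise = 0.005, seed = 2)
  iv <- detect_still(s, window = 0.5, threshold = 1e-3)
  expect_equal(nrow(iv), 1L)
  expect_equal(unname(iv[1, ]), c(1L, length(s$t) + 1L))

  ds <- simulate_hinge(hinge_rig(rate = 50),
                       motion_profile(type = "sinusoid", amplitude_deg = 30,
                                      freq_hz = 1, duration = 6,
                                      still_lead = 0.02, still_tail = 0.02,
                                      smooth = 0.5))
  iv2 <- detect_still(ds$imu2, window = 0.5, threshold = 1e-3)
  expect_equal(nrow(iv2), 0L)

  # 3 s still / motion / 3 s still: two intervals matching the schedule
  ds3 <- simulate_hinge(hinge_rig(rate = 50),
                        motion_profile(type = "sinusoid", amplitude_deg = 30,
                                       freq_hz = 0.8, duration = 10,
                                       still_lead = 3, still_tail = 3,
                                       smooth = 0.5))
  s3 <- corrupt(ds3$imu2, sensor_error_model(accel_noise_sd = 0.005,
                                             gyro_noise_sd = 0.002, seed = 4))
  iv3 <- detect_still(s3, window = 0.5, threshold = 1e-3)
  expect_equal(nrow(iv3), 2L)
  w <- 25 # 0.5 s window at 50 Hz
  expect_lte(abs(iv3[1, "end"] - 3 * 50), w + 2)
  expect_lte(abs(iv3[2, "start"] - 13 * 50), w + 2)
  expect_error(detect_still(make_still_series(n = 10), window = 0.5),
               "shorter")
})

test_that("reference_attitude averages the accel attitude over a still span", {
  s0 <- make_still_series()
  expect_equal(unclass(reference_attitude(s0, c(1L, 401L))),
               unclass(euler_zyx()), tolerance = 1e-12)
  att <- euler_zyx(0, 0.3, 0.2)
  s <- make_still_series(att, noise = 0.01, seed = 9)
  ref <- reference_attitude(s, c(1L, 401L))
  expect_equal(ref[["roll"]], 0.2, tolerance = 0.01)
  expect_equal(ref[["pitch"]], 0.3, tolerance = 0.01)
  expect_equal(ref[["yaw"]], 0)
  # moving interval: still returns a mean, but warns
  ds <- short_dataset()
  expect_warning(reference_attitude(ds$imu2, c(150L, 250L)), "unreliable")
  expect_error(reference_attitude(s, c(5L, 5L)), "empty")
})

test_that("attitude_from_accel recovers roll/pitch over an attitude grid", {
  s0 <- make_still_series()
  tr0 <- attitude_from_accel(s0)
  expect_equal(max(abs(c(tr0$roll, tr0$pitch, tr0$yaw))), 0)
  atts <- expand.grid(b = c(-0.9, 0, 0.8), r = c(-2.5, -0.4, 1.9))
  n <- nrow(atts)
  acc <- t(apply(atts, 1, function(x)
    body_gravity(euler_zyx(0.5, x[["b"]], x[["r"]]))))
  tr <- attitude_from_accel(imu_series(seq(0, by = 0.01, length.out = n),
                                       acc, matrix(0, n, 3)))
  expect_equal(tr$roll, atts$r, tolerance = 1e-10)
  expect_equal(tr$pitch, atts$b, tolerance = 1e-10)
  # zero-norm sample is flagged and carries the previous value
  acc2 <- rbind(body_gravity(euler_zyx(0, 0.1, 0.2)), c(0, 0, 0),
                body_gravity(euler_zyx(0, 0.1, 0.2)))
  expect_warning(
    tr2 <- attitude_from_accel(imu_series(c(0, 0.01, 0.02), acc2,
                                          matrix(0, 3, 3))),
    "flagged")
  expect_true(tr2$flagged[2])
  expect_equal(tr2$roll[2], tr2$roll[1])
})

test_that("gyro integration reproduces the closed-form yaw turn", {
  # 10 deg/s about Z for 1 s -> 10 deg of yaw
  n <- 101
  s <- imu_series(seq(0, 1, by = 0.01),
                  matrix(rep(c(0, 0, 9.81), each = n), n, 3),
                  matrix(rep(c(0, 0, 10 * pi / 180), each = n), n, 3))
  tr <- integrate_gyro(s, euler_zyx())
  expect_equal(tr$yaw[n] * 180 / pi, 10, tolerance = 1e-10)
  expect_equal(max(abs(tr$pitch)), 0)
  # zero rates -> constant attitude
  s0 <- imu_series(seq(0, 1, by = 0.01),
                   matrix(rep(c(0, 0, 9.81), each = n), n, 3),
                   matrix(0, n, 3))
  tr0 <- integrate_gyro(s0, euler_zyx(0.2, 0.1, -0.3))
  expect_equal(tr0$roll, rep(-0.3, n))
  expect_equal(tr0$yaw, rep(0.2, n))
})

gentle_hinge <- function(rate) {
  simulate_hinge(hinge_rig(rate = rate),
                 motion_profile(type = "sinusoid", amplitude_deg = 15,
                                freq_hz = 0.3, duration = 8,
                                still_lead = 1, still_tail = 1, smooth = 1,
                                base_rotation = list(
                                  list(axis = c(0, 0, 1), amplitude_deg = 10,
                                       freq_hz = 0.2),
                                  list(axis = c(0, 1, 0), amplitude_deg = 6,
                                       freq_hz = 0.16))))
}

test_that("halving the step changes a smooth trajectory endpoint by < 0.05 deg", {
  endpoint <- function(rate) {
    ds <- gentle_hinge(rate)
    tr <- integrate_gyro(ds$imu2, euler_zyx(ds$truth$att2[1, 1],
                                            ds$truth$att2[1, 2],
                                            ds$truth$att2[1, 3]))
    n <- length(tr$t)
    c(tr$yaw[n], tr$pitch[n], tr$roll[n])
  }
  e100 <- endpoint(100); e200 <- endpoint(200)
  expect_lt(max(abs(e100 - e200)) * 180 / pi, 0.05)
})

test_that("complementary filter reduces to its endpoints and bounds bias drift", {
  ds <- short_dataset()
  acc_tr <- attitude_from_accel(ds$imu1)
  gyr_tr <- integrate_gyro(ds$imu1, euler_zyx(ds$truth$att1[1, 1],
                                              ds$truth$att1[1, 2],
                                              ds$truth$att1[1, 3]))
  f0 <- complementary_filter(acc_tr, gyr_tr, K = 0)
  expect_equal(f0$roll, gyr_tr$roll, tolerance = 1e-12)
  expect_equal(f0$pitch, gyr_tr$pitch, tolerance = 1e-12)
  f1 <- complementary_filter(acc_tr, gyr_tr, K = 1)
  expect_equal(f1$roll, acc_tr$roll, tolerance = 1e-12)
  # fused yaw always equals gyro yaw
  fm <- complementary_filter(acc_tr, gyr_tr, alpha = 0.98)
  expect_identical(fm$yaw, gyr_tr$yaw)
  expect_identical(f1$yaw, gyr_tr$yaw)

  # static record with gyro bias: gyro-only roll drifts past 10 deg,
  # the fused roll error stays below 1 deg
  n <- 6001
  t <- seq(0, 60, by = 0.01)
  still <- imu_series(t, matrix(rep(c(0, 0, 9.81), each = n), n, 3),
                      matrix(0, n, 3))
  biased <- corrupt(still,
                    sensor_error_model(accel_noise_sd = 0.05,
                                       gyro_noise_sd = 0.005,
                                       gyro_bias = c(0.5 * pi / 180, 0, 0),
                                       seed = 21))
  at <- attitude_from_accel(biased)
  gt <- integrate_gyro(biased, euler_zyx())
  fu <- complementary_filter(at, gt, alpha = 0.98)
  expect_gt(max(abs(gt$roll)) * 180 / pi, 10)
  expect_lt(max(abs(fu$roll)) * 180 / pi, 1)
})

test_that("fused trace matches truth on clean simulated motion", {
  ds <- gentle_hinge(100)
  acc_tr <- attitude_from_accel(ds$imu1)
  gyr_tr <- integrate_gyro(ds$imu1, euler_zyx(ds$truth$att1[1, 1],
                                              ds$truth$att1[1, 2],
                                              ds$truth$att1[1, 3]))
  fu <- complementary_filter(acc_tr, gyr_tr, alpha = 1 - 1e-9)
  # near-pure gyro path on noise-free data: integrator-tolerance agreement
  expect_lt(max(abs(fu$roll - ds$truth$att1[, 3])) * 180 / pi, 0.1)
  expect_lt(max(abs(fu$pitch - ds$truth$att1[, 2])) * 180 / pi, 0.1)
  expect_lt(max(abs(fu$yaw - ds$truth$att1[, 1])) * 180 / pi, 0.1)
})
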