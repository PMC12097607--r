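# jointkin

Joint kinematics and range of motion from two body-worn inertial sensors.

After orthopedic surgery, a joint's range of motion (ROM) — the span
between the smallest and largest angle the joint reaches — is a primary
indicator of recovery. `jointkin` estimates joint angles and ROM from two
strapped-on IMUs (triaxial accelerometer + gyroscope) without any manual
alignment or distance measurement, for clinicians and movement scientists
who want continuous monitoring outside the motion-capture lab. It is an R
toolkit with a thin command-line interface.

## What it computes

For a one-degree-of-freedom (hinge) joint with sensors on the two adjacent
segments, the angular velocities `g1`, `g2` and specific forces `a1`, `a2`
obey two kinematic constraints at every instant:

* **axis**: `||g1 x j1|| = ||g2 x j2||` — the rate components
  perpendicular to the hinge axis agree, identifying the unit axis
  directions `j1`, `j2` in the sensor frames;
* **center**: `||a1 - Γ_g1(o1)|| = ||a2 - Γ_g2(o2)||`, with
  `Γ_g(o) = g x (g x o) + ġ x o` the centripetal-plus-tangential
  acceleration of a point at lever arm `o` — both sensors must reconstruct
  the same joint-center acceleration, identifying the lever arms.

Minimizing the squared violations over free movement (Levenberg–Marquardt,
deterministic multi-starts, plus a vector-consistency refinement) yields a
full self-calibration. The joint angle then comes from complementary
fusion of the integrated axis-projected rate difference
`∫ (g1·j1 − g2·j2) dt` (drift-prone, low-noise) with the accelerometer's
gravity-referenced angle (drift-free, noisy), or from a per-sample
SVD/Kabsch best-fit relative rotation with the hinge angle read off as
`atan2(R[3,2], R[3,3])`.

Around this core the package provides ZYX Euler attitude estimation
(accelerometer inclination, gyro integration, complementary filter,
stillness detection), a per-axis `[p, v, a]` Kalman filter fusing inertial
dead reckoning with GPS-like position/velocity fixes to bound drift,
wavelet universal-threshold denoising with an optional voluntary-motion
band limit, an error-injection experiment harness (drift and soft-tissue
artifact conditions vs. pipeline variants, with group statistics and t
tests), and an analytically exact rigid-body hinge-limb simulator that
serves as ground truth for everything.

## Worked example

Simulate a calibration movement (3 s still, 20 s of 30° flexion at 0.5 Hz
with a whole-limb wobble, 3 s still), corrupt it with sensor noise,
self-calibrate, and estimate the joint angle and ROM:

```r
library(jointkin)
rig <- hinge_rig()                       # two sensors, oblique mounts
ds  <- simulate_hinge(rig, standard_protocol())
err <- function(s) sensor_error_model(accel_noise_sd = 0.05,
                                      gyro_noise_sd = 0.02, seed = s)
imu1 <- corrupt(ds$imu1, err(11))
imu2 <- corrupt(ds$imu2, err(12))

calib <- calibrate_joint(imu1, imu2)
print(calib)
#> joint_calibration
#>   j1: -0.9503 -0.2717 -0.1521
#>   j2: -0.9749 +0.1980 +0.1015
#>   o1: +0.0415 -0.1134 +0.0047 m
#>   o2: +0.0129 +0.1394 -0.0562 m
#>   residual RMS: axis 0.0132, center 0.127

trace <- joint_angle(imu1, imu2, calib, method = "fused",
                     alpha0 = ds$truth$angle$angle[1])
print(range_of_motion(trace))
#> range of motion: 60.6 deg (min -30.6, max 30.0)
```

The estimated axes and lever arms sit within a degree / a few millimetres
of the simulator's truth (`ds$truth$calib`: j1 = (-0.9446, -0.2922,
-0.1494), o1 = (+0.0499, -0.1139, +0.0077) m), the recovered ROM is within
a degree of the true 60°, and the fused angle tracks the true angle to
0.41° RMSE on this record.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/jointkin.R simulate  --profile standard --noise-preset low --seed 3 --out sim
Rscript inst/cli/jointkin.R calibrate --imu1 sim/imu1.csv --imu2 sim/imu2.csv --out calib.json
Rscript inst/cli/jointkin.R angle     --imu1 sim/imu1.csv --imu2 sim/imu2.csv \
                                      --calib calib.json --method fused --out trace.csv
Rscript inst/cli/jointkin.R rom       --trace trace.csv
#> range of motion: 60.2 deg (min -30.4, max 29.9)
```

Subcommands `denoise`, `fuse` (IMU + fixes) and `experiment` cover the
remaining modules. File formats are plain CSV (`t, ax, ay, az, gx, gy, gz`
in SI units for IMU streams; `t, px, py, pz, vx, vy, vz` for fixes) and
JSON for calibrations and reports.

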