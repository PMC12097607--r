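---
title: "Assessing joint motion with two wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing joint motion with two wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointkin)
```

## The measurement problem

After orthopedic surgery, the range of motion (ROM) of a joint — the
difference between the largest and smallest joint angle a patient can
reach — is a primary clinical indicator of recovery. Optical motion capture
measures it accurately but requires a laboratory; goniometers are cheap but
manual, static and operator-dependent. Two miniature inertial measurement
units (IMUs), strapped to the segments on either side of the joint, can
measure continuously and anywhere, but three obstacles stand between their
raw signals and a trustworthy joint angle:

1. **Integration drift.** A gyroscope measures angular rate; angles come
   from integration, so any rate bias grows linearly into the angle (and
   doubly-integrated accelerometer bias grows quadratically into position).
2. **Unknown mounting.** The sensors are strapped on by hand; neither their
   orientation relative to the joint axis nor their position relative to
   the joint center is known.
3. **Noise and soft-tissue artifact.** Skin and muscle wobble adds a
   coherent oscillation (typically ~8–12 Hz) on top of the electronic
   noise floor.

`jointkin` implements a pipeline that addresses each: complementary and
Kalman filtering against drift, kinematic-constraint self-calibration
against unknown mounting, and wavelet thresholding against noise — all
validated against an analytically exact rigid-body simulator.

## Attitude from one sensor

Attitude is parametrized by intrinsic ZYX Euler angles (yaw $a$ about Z,
pitch $b$ about Y, roll $c$ about X). A motionless accelerometer reads the
gravity vector in its own frame,
$s = G_X(c)\,G_Y(b)\,G_Z(a)\,[0,0,g]^T$, from which roll and pitch follow
as

$$\mathrm{roll} = \operatorname{atan2}(s_y, s_z),\qquad
  \mathrm{pitch} = -\arctan\!\big(s_x / \sqrt{s_y^2+s_z^2}\big),$$

while yaw is unobservable (rotation about the vertical does not move
gravity). `atan2` is used for roll to preserve the quadrant; the pitch
denominator is non-negative, so plain `arctan` confines it to
$(-\pi/2, \pi/2)$ and the representation stays unique away from the gimbal
singularity at $|b| = \pi/2$, which all functions reject explicitly.

The gyroscope gives body rates; the forward map from Euler-angle rates to
body rates is well conditioned everywhere, and its inverse — the map
actually integrated — is the standard ZYX kinematics
$\dot a = (q\sin c + r\cos c)/\cos b$, $\dot b = q\cos c - r\sin c$,
$\dot c = p + \tan b\,(q\sin c + r\cos c)$. `integrate_gyro()` advances it
with the explicit first-order (Euler) scheme, matching the per-step update
formulation of the estimation pipeline; accuracy is recovered through the
sampling rate rather than a higher-order integrator. At 100 Hz on gentle
voluntary movement the induced error is below 0.1 degrees; the test suite
verifies both this and step-halving convergence.

Stillness is detected by sliding a window (default 0.5 s) over the
accelerometer and requiring the per-axis variance to stay below a
threshold (default $10^{-3}\ (\mathrm{m/s^2})^2$); the mean accelerometer
attitude over a still interval serves as the integration reference.

`complementary_filter()` blends the two sources recursively:

$$\theta_k = \alpha\,(\theta_{k-1} + \Delta\theta^{\mathrm{gyro}}_k)
           + (1-\alpha)\,\theta^{\mathrm{acc}}_k ,$$

with $\alpha = 0.98$ by default (a ~0.5 s crossover at 100 Hz): the gyro
carries the high-frequency motion, the accelerometer pins the low
frequencies so bias cannot accumulate. Two sign conventions for the blend
coefficient circulate (weight on the gyro term vs weight on the
accelerometer correction); this package treats $\alpha$ as the gyro weight
and accepts `K = 1 - alpha` for the complementary convention. Fused yaw is
always the gyro yaw — the accelerometer has no heading information to
contribute.

## Bounding positional drift with position fixes

For drift studies the package includes a per-axis linear Kalman filter
over the state $[p, v, a]$ with the bidiagonal constant-acceleration
transition

$$F = \begin{pmatrix} 1 & \Delta t & 0\\ 0 & 1 & \Delta t\\
      0 & 0 & 1\end{pmatrix},$$

(the exactly discretized variant with the $\Delta t^2/2$ term is available
behind `exact_f`). The world-frame specific force — attitude-rotated and
gravity-compensated — enters as a high-rate pseudo-measurement of the
acceleration state, and position/velocity fixes (GPS-like, default 1 Hz)
update the filter at their epochs; between fixes the filter predicts only,
so drift grows during outages and is pulled back at the next fix.

Two numerical choices matter for filter honesty:

* process noise follows the white-noise acceleration-error model, whose
  $\Delta t$-coupled covariance inflates velocity and position uncertainty
  so the fix updates keep a meaningful gain (`q_scale`, default 0.1
  $(\mathrm{m/s^2})^2/\mathrm{Hz}$);
* the accelerometer pseudo-measurement variance `r_acc` (default 0.1
  $(\mathrm{m/s^2})^2$, i.e. ~0.3 m/s² of unmodeled error) must cover the
  *persistent* errors — bias, gravity-compensation residuals — not just
  the white-noise floor. Setting it to the noise floor pins the
  acceleration state to the biased reading, collapses the covariance, and
  the filter confidently ignores its fixes while drifting.

With a 0.05 m/s² accelerometer bias over 120 s, dead reckoning diverges by
$\tfrac{1}{2}\varepsilon T^2 = 360$ m while the fix-corrected filter stays
below 2 m RMS; the acceptance tests reproduce both numbers.

## Wavelet denoising

Motion channels are denoised by multi-level discrete wavelet
decomposition, thresholding of the detail coefficients, and
reconstruction. Defaults follow common practice for 1-D motion signals:
Daubechies-4, 5 levels, symmetric (edge-reflecting) boundary handling,
soft thresholding at the universal threshold
$\lambda = \sigma\sqrt{2\ln N}$, with $\sigma$ estimated robustly from the
finest detail band as $\mathrm{MAD}/0.6745$. Signals are symmetrically
padded to a working length and trimmed after reconstruction. A periodized
boundary mode is provided as well (it is the mode in which the transform
is exactly orthogonal, which the Parseval test exploits); it requires an
even length at every decomposition scale. The filter banks and both
boundary modes are verified coefficient-for-coefficient against an
independent reference wavelet library on frozen fixtures, and
perfect-reconstruction / contraction properties are tested for every
supported wavelet.

Amplitude thresholding removes what lives near the noise floor. A
soft-tissue oscillation does not: at ~2 degrees and 8 Hz it towers above
the threshold and survives. Because voluntary joint motion in
rehabilitation settings stays below a few Hz, the preprocessing also
offers *band-limiting* (`bandlimit_hz`): detail bands lying entirely above
a cutoff are zeroed regardless of amplitude. Calibration and the fused
angle pipeline use a 3 Hz cutoff by default; the choice also absorbs the
spectral leakage of an 8 Hz artifact into the neighboring 3.1–6.25 Hz
band, which a 4 Hz cutoff would let through.

## Self-calibration to the hinge

With sensors strapped on arbitrarily, the unit hinge-axis directions
$j_1, j_2$ and the joint-center lever arms $o_1, o_2$ (all in sensor
frames) are recovered from free movement alone.

**Axes.** For a one-degree-of-freedom hinge the two segments' angular
velocities differ only by the hinge rate about the axis, so their
components perpendicular to the axis agree in magnitude:
$\lVert g_1\times j_1\rVert = \lVert g_2\times j_2\rVert$ at every sample.
`estimate_joint_axes()` minimizes the summed squared violation over the
unit sphere pair (spherical parametrization, Levenberg–Marquardt, eight
deterministic multi-starts). Two sign ambiguities remain and are resolved
deterministically: the *relative* sign of $j_1, j_2$ through the
frame-invariant projection of gravity onto the axis (the same world
quantity seen from both frames must agree in sign; the axis-projected rate
correlation is the fallback for axes that stay horizontal), and the
*global* sign by the convention that the hinge rate is positive at motion
onset (flexion-positive).

**Lever arms.** A point rigidly attached at lever arm $o$ under angular
rate $g$ and angular acceleration $\dot g$ accelerates by
$\Gamma_g(o) = g\times(g\times o) + \dot g\times o$ (centripetal plus
tangential). Both sensors must reconstruct the same joint-center
acceleration, giving the magnitude constraint
$\lVert a_1-\Gamma_{g_1}(o_1)\rVert = \lVert a_2-\Gamma_{g_2}(o_2)\rVert$.
Its least-squares solution initializes a refinement that enforces the
stronger vector form of the same constraint: the reconstructed
joint-center accelerations, mapped into a common frame through the
per-sample relative rotation (itself rebuilt from the shared axis and the
joint-center specific-force direction), must agree component-wise. The
refinement matters under noise: the magnitude residual is first-order
blind to lever-arm components perpendicular to gravity, and the weakly
excited proximal sensor can wander ~10 cm along those directions before
the second-order terms notice.

Three further numerical points:

* $\dot g$ comes from centered differences of the (denoised) rates — a
  5-point fourth-order stencil in the interior, since the second-order
  stencil's truncation error at 100 Hz alone costs several millimetres of
  lever-arm accuracy;
* for a hinge, *every point on the axis* is a valid joint center
  (shifting both lever arms by a common distance along their axes changes
  nothing), so lever arms are gauge-fixed to the minimum-norm point on the
  axis (`canonical_lever_arms()`), and the simulator reports its truth in
  the same gauge;
* both stages restrict to samples with angular rate above a motion floor
  (0.2 rad/s) and refuse to run on insufficient excitation — a still
  record for the axes, a constant-rate record for the lever arms (the
  tangential term vanishes when $\dot g \equiv 0$).

Identifiability also constrains the *movement*: if the proximal segment
never rotates, or rotates about a single fixed axis, its hinge-axis
direction and lever arm are unidentifiable in principle (a whole circle of
axes fits) or in practice (rotational accelerations below the noise
floor). The standard protocol therefore includes a deliberate two-axis
whole-limb wobble, as a clinician would prescribe for a functional
calibration movement.

## Joint angle and range of motion

Four estimators are provided, all returning radians internally (degrees
only at file and report boundaries):

* **Gyro** ($\alpha_f$): the integral of the axis-projected rate
  difference $g_1\cdot j_1 - g_2\cdot j_2$ (trapezoidal). Exact on clean
  data; drifts under single-sensor bias (a bias common to both sensors'
  axis projections cancels).
* **Accelerometer** ($\alpha_s$): the difference of the in-plane phase
  angles of the lever-arm-corrected specific force, each measured in a
  per-sensor joint frame whose X axis is the calibrated hinge axis.
  Drift-free but noisy and degraded by dynamics. Samples whose specific
  force is nearly parallel to the axis are flagged and carried forward.
  The in-plane bases have arbitrary handedness, so the trace's sign is
  oriented automatically against the axis-projected gyro rate; its offset
  is anchored on the leading still interval (the joint angle there is
  `alpha0`, default 0).
* **Fused**: the recursive complementary blend of the two (gyro weight
  0.98), which the accuracy criteria target.
* **SVD**: per sample, the vector pairs known to coincide in the world
  frame — the shared hinge axis, the joint-center specific-force
  direction, and their cross product — are expressed in the two joint
  frames and aligned by the Kabsch/SVD best-fit proper rotation (with the
  determinant correction, so a reflection is never returned); the hinge
  angle is `atan2(R[3,2], R[3,3])`. A short pooling window (0.2 s)
  averages noise. A window of gravity directions alone would not do: the
  relative orientation changes within any practical window, and the
  fitted rotation would be a window average rather than an instantaneous
  angle.

`range_of_motion()` summarizes any trace as min/max/range in degrees.

## The simulator

`simulate_hinge()` is the package's ground truth: a two-segment rigid
body, joint center fixed at the origin, segment 1 driven by an optional
one- or two-component sinusoidal base rotation, segment 2 additionally by
the hinge-angle profile. Profiles are twice differentiable by
construction (raised-cosine envelopes with closed-form derivatives), and
every sensor quantity — body rates, lever-arm specific force including
centripetal and tangential terms, per-segment attitudes, world
trajectories — is evaluated analytically, never by numerical
differentiation, so simulator truth is exact to machine precision and
usable as an oracle in tests.

`corrupt()` layers on the error model: white accelerometer/gyro noise,
constant biases, an integrated gyro bias random walk, and a soft-tissue
artifact modeled as a mount-orientation oscillation (default 2 degrees at
8 Hz) whose envelope is a leaky integrator of gyro speed with the
configured damping (3 s⁻¹) — the mount wobbles while the limb moves and
rings down when it stops. The artifact re-rotates both accelerometer and
gyro readings and adds its own angular rate. The `drift` preset draws the
per-axis gyro bias signs from the seed, since two physical devices never
share a turn-on bias (a shared bias would cancel in the joint-angle
difference and understate drift).

What the generator does *not* emulate: joint axis translation and
ligament laxity, sensor-to-sensor clock skew, magnetometer disturbances,
temperature-dependent bias, and the rich spectral content of real gait.
Passing tests demonstrate correctness of the algorithms under the stated
error models, not clinical accuracy on patients.

## The error-injection experiment

`run_error_experiment()` reproduces a drift / soft-tissue error-source
study design: conditions (control, drift, soft-tissue) crossed with
pipeline variants — `raw` (calibration and gyro-only integration on the
raw streams; dead-reckoned trajectory), `gps` (raw angle,
fix-corrected trajectory), `constraints` (denoised band-limited
calibration and fused angle; dead-reckoned trajectory) and `both`. Each
run reports the joint-angle MAE and RMSE against simulator truth and the
trajectory RMS error; group means, standard deviations and
pooled-variance t tests against the control condition accompany them
(Welch's test behind a flag; MAE is the headline metric to mirror
average-error reporting, RMSE is included alongside). The trajectory
branch rotates specific force with the simulator's truth attitude so that
the scores isolate the injected sensor errors rather than compounding
attitude-estimation error. Everything is deterministic given the seed
vector. The bundled `imu_error_study_data()` measurements serve as a
worked example for the statistics; recomputed group means are reported at
one decimal with halves rounded away from zero.

## Problem sizes and defaults

The standard protocol is 26 s at 100 Hz (3 s still, 20 s of 30°/0.5 Hz
flexion with the two-axis wobble, 3 s still): large enough for
millimetre-grade calibration, small enough that the full acceptance
experiment (3 conditions x 20 seeds x 4 variants) completes in a few
minutes on one core. Drift studies use 120 s translations at 100 Hz with
1 Hz fixes.

## Known limitations

* Hinge (1-DoF) joints only; ball-and-socket calibration is out of scope.
* The explicit-Euler attitude integrator limits accuracy for violent
  motion; raise the sampling rate rather than the motion amplitude.
* Heading (yaw) is gyro-only: without a magnetometer it drifts, which is
  why all joint-angle estimators work in axis-projected or
  gravity-referenced quantities.
* The soft-tissue artifact model is a single damped oscillation mode;
  real artifact is broadband and subject-specific.
* The joint-angle sign convention (flexion-positive at motion onset)
  assumes the record begins with a flexion; records that open with an
  extension come out mirrored and need the `sign` override.
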