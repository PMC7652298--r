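---
title: "Replaying humeral motion on an industrial robot: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replaying humeral motion on an industrial robot: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humrep)
```

# The problem

Percutaneous osseointegrated prostheses anchor directly into the residual
humerus, which makes the bone–implant interface vulnerable to fracture
under the multiaxial, high-rate loads of everyday activity. Mechanical
characterization of that interface requires reproducing those loads — not
the quasi-static uni-axial approximations of a universal testing machine.
`humrep` implements the computational side of doing this with a 6-DOF
serial industrial robot: it maps skin-marker-derived humeral trajectories
into the robot's joint space, generates and simulates motion programs,
verifies the achieved kinematics, and computes the interface loads that the
motion implies.

This vignette records the model choices, parameters, numerical decisions
and limitations. Everything quantitative stated here is computed by the
package's test suite or by `scripts/acceptance.R`; nothing is quoted from
external measurements.

# Kinematic conventions and data contracts

Poses are rigid transforms (3×3 rotation + translation in meters), SI units
throughout, degrees only at file and report boundaries. All frames are
right-handed, and gravity is `-Z` in both the motion-capture and robot
frames. That last point is a *data contract*, not a convenience: the
trajectory mapping is restricted to a rotation about the gravity axis
precisely so that the orientation of the motion relative to gravity — and
hence the gravitational contribution to the interface loads — is preserved.
If your capture frame has a different up-axis, re-express the data first.

Orientations are reported in the rotation-vector formulation. Two
subtleties:

* At a rotation angle of exactly π the two antipodal rotation vectors are
  equivalent. Trajectory code resolves the ambiguity by continuity with the
  previous sample (`unwrap_rotvecs()`); standalone conversions return the
  representative whose largest-magnitude component is non-negative.
* `rotation_angle()` and the near-π branch of `rotmat_to_rotvec()` use
  atan2/asin-of-sine forms rather than `acos`. The arccosine of a
  near-unity trace has a precision floor around 1e-8, which would mask the
  package's own 1e-9 consistency contracts; the sine-based forms keep full
  precision at small angles.

# The robot model

The robot is configured from a YAML file of standard Denavit–Hartenberg
rows plus joint and joint-velocity limits (degrees in the file, radians
internally). The shipped default, `default_robot()`, is an *approximate*
M20iA-class 6R geometry (~1.8 m reach, vendor-class limits): vendors do not
publish exact kinematic parameters, so the default is a realistic stand-in
and every algorithm treats the robot as data. A planar two-link test model
(`planar_test_robot()`) exists purely for hand-checkable kinematics tests.

Inverse kinematics is numeric damped least squares with adaptive Levenberg
damping and a Jacobian-transpose fallback, converging to residuals around
1e-10 (the contract is 1e-6 m / 1e-6 rad). There is deliberately no
closed-form wrist solution: branch selection is by continuity — each
timepoint is seeded with the previous solution — which makes the joint
trajectory implied by an initial configuration unique. Joint velocities are
central finite differences at the native rate, with one-sided differences
at the endpoints.

# Mapping optimization

The mapping `R_T_MC` has 4 parameters: yaw `theta` about gravity and a
translation `t`. Two optimizers are provided.

**Derivative-free (COBYLA over `q(0)`).** The decision variables are the 6
initial joint angles. Each candidate implies a mapping: compose
`K(q0) . EE_T_H . (MC_T_H^0)^-1`, project its rotation onto the gravity
axis (best-fit yaw), and keep the translation. The *tilt residual* — the
angle between the candidate rotation and its yaw projection — is
constrained to 1e-3 rad, alongside joint limits and velocity utilization
≤ 1. The objective is the max-over-joints-and-time velocity utilization
(minimax matches the semantics of "utilization"). The seed is constructed
by IK after placing the first pose at a nominal workspace anchor, choosing
among eight yaws the configuration with the largest normalized joint-limit
margin and wrapping wide-range wrist joints to their 2π-equivalent nearest
zero — without this, trajectories drifting near a wrist limit are
spuriously infeasible.

**Gradient-based (SLSQP over the full trajectory).** Decision variables are
every joint vector plus `(theta, t)`; equality constraints impose the pose
constraint at every waypoint (position residual and rotation-vector
residual, with analytic Jacobians from the geometric Jacobian); joint
limits are bounds and velocity limits linear inequalities; the objective is
the smooth surrogate `sum (qdot/qdot_max)^2`. After the solver stops, the
equality constraints are *pinned* by re-running sequential IK at the
returned mapping, so the returned FK residual is at solver-independent
IK precision, and a descent guard returns the warm start unchanged if no
improvement was found for the same tool frame. Its intended use is the
virtual-to-physical tool-frame substitution: warm-start from a
derivative-free result for a nearby tool frame, refine for the digitized
one. Because the solve is dense (6n + 4 variables), decimate the trajectory
to ≲ 60 waypoints before calling.

An infeasible outcome (no mapping satisfies the velocity limits) is a valid
scientific result, reported as a `mapping_result` with `feasible = FALSE`,
not an error.

One invariant worth stating honestly: Cartesian speed profiles are exactly
invariant under mapping translation shifts, but the *joint-space*
utilization objective is not — moving the trajectory within the workspace
changes the arm configurations. The tests check kinetic invariance at the
Cartesian level and check the objective against `check_limits()`
consistency instead.

# Subsampling and the virtual controller

Industrial controllers slow down on dense waypoint streams, so trajectories
are subsampled to a budget (default 20% of 200 Hz, i.e. waypoints ~25 ms
apart on average). The selection is greedy farthest-point refinement under
the combined metric `||dp|| + rho * angle(dR)` with `rho = 0.3` m — a
characteristic humeral length converting orientation error to meters:
starting from the endpoints, repeatedly keep the discarded point deviating
most from the interpolated kept path. Two auxiliary rules make the
procedure well-behaved: when all remaining deviations are numerically zero
(straight stretches) the longest segment is split at its midpoint, and the
final selection is guaranteed never to have larger maximum deviation than
uniform subsampling at the same count (greedy insertion is a heuristic and
can otherwise lose by a hair on uniform-curvature signals).

The motion program is a line-oriented text dialect (index, six joint angles
in degrees, timestamp, per-segment speed in mm/s, smoothness 0–100) that
round-trips losslessly through its parser; vendor-specific emitters are an
extension point, not core.

The virtual controller exists to exercise the verification pipeline end to
end, not to model any vendor's look-ahead: joint-space piecewise-linear
motion with parabolic corner blends (blend half-window =
`smoothness/100 * min(adjacent durations)/2`), per-segment duration
stretched when the programmed speed exceeds a joint's velocity limit (the
robot saturates and arrives late), an optional first-order lag time
constant, and resampling at 200 Hz. With smoothness 0 and no lag it passes
through every waypoint exactly. Consequently, pipeline error numbers on the
virtual robot are an idealized floor; the lag parameter is how the tests
produce realistic monotone degradation of velocity- and acceleration-level
errors.

# Frame identification

The tracker-to-robot rotation `R_OT` and the end-effector-to-rigid-body
transform `EE_T_HS` are identified from ≥ 3 paired poses as an `AX = ZB`
problem: rotations first, by stacking the Kronecker-form linear system over
all pairs and taking the SVD null vector (both unknown rotations projected
back to SO(3) by polar decomposition), then translations by linear least
squares given the rotations. The translation of `Z` is estimated but
discarded — downstream metrics normalize to the first waypoint, so a common
translation is irrelevant. Identifiability requires the relative robot
rotations to span at least two independent axes; degenerate sets raise an
error rather than returning garbage. Robot poses are treated as exact
(controller repeatability is two orders below tracker noise); noise is
modeled on the tracker side only, at the marker level: poses are
re-estimated by Procrustes fits of a perturbed virtual marker
constellation, which makes orientation noise scale as
`sigma / constellation_radius` — the physically correct coupling.

With 0.1 mm marker noise and 20 poses, the median errors over 100 repeats
are around 0.02 degrees and 0.03 mm (computed by `scripts/acceptance.R`),
comfortably below the 1-degree / 1-mm precision the procedure is expected
to deliver.

# Verification metrics

Desired and achieved trajectories are temporally aligned by the integer
offset maximizing the summed correlation over the three position and three
rotation-vector channels; channels are z-scored first so meters and radians
contribute comparably ("simultaneously" interpreted as one summed
objective), zero-variance channels are dropped, and ties break toward zero
offset. Both trajectories are then normalized to their first waypoint
(kinetics are translation-invariant), differentiated after 8 Hz
fourth-order bidirectional Butterworth smoothing (filter once, then
differentiate twice), and expressed along the anatomical axes of the
thorax pose in the trial's initial frame (ML/AP/IS).

The error measure is span-normalized MAE: mean absolute error divided by
the desired signal's span (max − min), as a percentage — per axis, and for
the Euclidean-magnitude series using the span of the magnitude signal (the
literal reading of span normalization for magnitudes; the alternative,
magnitude of per-axis spans, is not used). Axes whose desired span is
numerically zero are reported `NA` rather than divided by a floor: span
normalization legitimately inflates errors on secondary axes of
near-planar motions (internal rotation especially), and an undefined value
is more honest than an arbitrary large one. No mean-centering is applied
anywhere, including in the load error-at-peak metric
`|desired(t*) − achieved(t*)| / span(desired)` at the instant `t*` of
maximum desired load — adding a common constant to both signals *does*
change it, by design of the formula.

The Butterworth implementation is worth a note: it uses `signal::butter`
coefficients but its own forward–backward pass with steady-state initial
conditions (the unit-step fixed point of the filter state) and reflection
padding. Naive zero-initial-state filtering distorts even a constant signal
by percent-level transients, which after double differentiation produced
order-of-magnitude endpoint artifacts.

# Inverse dynamics

The prosthesis is modeled as uniform solid cylinders: arm connection
(length 0.75 × arm length, diameter 0.060 m, mass
`0.50823 kg/m × length + 0.3 kg`), forearm (0.2540 m, 0.0762 m, 1.013 kg),
hand (0.1524 m, 0.0540 m, 0.416 kg) and, for jug lifts, a jug (0.2500 m,
0.1500 m, 3.800 kg). The elbow is fixed per activity (90° jogging/internal
rotation, 135° jumping jacks, 180° jug lift), so the chain moves rigidly
with the humerus. Geometry conventions the table does not specify, chosen
once and documented: humeral frame origin at the glenohumeral center with
+Y superior; the interface cross-section at 25% of arm length down the
shaft (consistent with the 0.75 × arm-length connection); the forearm folds
at the elbow in the humeral sagittal (X–Y) plane; the hand is collinear
with the forearm; the jug is centered at the hand's distal end with its
axis along the forearm. Gravity defaults to `(0, 0, -9.81)` m/s².

The recursion propagates humeral angular velocity/acceleration and
per-centroid accelerations outward and sums forces and moments inward to
the interface. Angular velocity is computed through the exact
rotation-vector-rate map `omega = A(r) rdot` (the trajectory module's
derivatives are rotation-vector rates, which are only second-order close to
body rates); angular acceleration is its finite difference. The result is
validated two independent ways: a hand statics calculation for a horizontal
arm, and a momentum-theorem oracle (wrench from finite differences of
summed segment momenta) that agrees within 1% on smooth trajectories.
Equivalence-principle cases (free fall; zero gravity at rest) return zero
wrench to 1e-9.

Load projections follow the humeral axis (body +Y rotated by the current
pose): axial force along it, torsional moment along it (both signed),
bending moment as the norm of the orthogonal moment component.
`gravitational_fraction()` reruns the dynamics with inertial terms zeroed;
for a slow jug lift (peak angular speed ≤ 30°/s) the gravitational share of
the peak bending moment exceeds 90% — the jug's weight, not inertia,
dominates — which is why moderate acceleration-level replication error is
tolerable for that activity's kinetics.

# Synthetic data

The generator produces C-infinity pose trajectories as sums of a base
sinusoid and a quarter-amplitude first harmonic per axis, with seeded
random phases and ±10% amplitude/frequency jitter, at 200 Hz by default.
The archetypes encode what matters to the pipeline — spans, speeds,
smoothness — rather than biomechanical detail:

| activity | character | key defaults |
|---|---|---|
| jumping_jack | large elevation oscillation, compact translation | 1.1 rad @ 0.5 Hz about ML, ≤ 0.12 m translation |
| jogging | long anterior excursion + oscillation | 0.9 m anterior drift over 2 s, 0.45 rad swing |
| jug_lift | slow large bending-plane rotation | 0.60 rad @ 0.06 Hz, 8 s; worst-case angular speed ≤ 30°/s including harmonic and jitter |
| internal_rotation | fast axial rotation, mm-scale translation | 1.0 rad @ 1 Hz axial, ≤ 6 mm translation |

The jug-lift amplitudes were chosen so that the ≤ 30°/s contract holds for
the *worst case* of jitter and harmonic content, not just the nominal
values. What the generator deliberately does not emulate: soft-tissue
artefact (the dominant error source of real skin-marker data), subject
anthropometric variation, and non-stationary frequency content. Passing
tests on synthetic data therefore demonstrate pipeline correctness, not
robustness to soft-tissue artefact.

Tracker noise is marker-level (see frame identification), and calibration
fixtures are built from ground-truth transforms with rotation axes spanning
3D, so exact-recovery tests are meaningful.

# Problem sizes and tolerances

Defaults: FK/IK residual tolerance 1e-6 (achieved ~1e-10); tilt constraint
1e-3 rad; optimizer relative stopping 1e-8; COBYLA budget 60 evaluations;
verification filter 8 Hz, input-data convention 6 Hz; subsample fraction
0.2; ramp length 30 points (0.15 s) built from a quartic with five boundary
conditions — zero velocity and acceleration at the rest end, matched
position/velocity/acceleration at the junction. (A quartic's jerk is
linear, not constant; the package reads the "constant-jerk" naming of such
ramps as loose terminology and documents the quartic's conditions instead.)

The test suite and acceptance script run everything at desk scale as the
package's own choice of problem size: optimization loops on 1–2 s
trajectories at 50 Hz (the gradient stage on ~20–30 decimated waypoints),
pipeline smoke tests on 2.5–4 s trials at 200 Hz, Monte-Carlo precision
studies at 100 repeats. All randomness is seeded; reruns are bit-identical.

# Known limitations

* The virtual controller has no look-ahead model; real-controller velocity
  and acceleration errors will exceed the simulated floor.
* The M20iA-class geometry is approximate; results on a physical robot
  require that robot's own config file.
* The gradient-based solve is dense and intended for decimated waypoint
  sets, not full 200 Hz trajectories.
* Rotation-vector-rate differentiation (the verification convention)
  differs from body angular velocity at second order; inverse dynamics uses
  the exact map, but the kinematic MAE tables inherit the convention.
* Soft-tissue artefact, muscle/contact loads, robot torque limits, and
  load-rate (third-derivative) statistics are out of scope.
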