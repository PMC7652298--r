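# humrep — robotic replication of humeral motion

`humrep` is an R toolkit for replaying in-vivo humeral kinematics on a
6-degree-of-freedom serial industrial robot and for quantifying how well the
robot reproduced them — kinematically and in terms of the loads at the
bone–implant interface of a transhumeral osseointegrated prosthesis.

It is aimed at biomechanics and orthopaedics researchers who want to use an
industrial manipulator as a next-generation universal testing machine:
instead of quasi-static uni-/bi-axial loading, the robot replays
skin-marker-derived trajectories of advanced activities of daily living
(jumping jacks, jogging, jug lifts, rapid internal rotation) at full speed,
recreating the multiaxial inertial loading environment of the humerus.

## What the package computes

**Gravity-consistent trajectory mapping.** A humeral pose trajectory
`MC_T_H^k` recorded in a motion-capture frame is relocated into the robot
frame by `R_T_MC`, restricted to a rotation about the gravity axis plus a
translation (4 parameters, so gravitational load directions relative to the
motion are preserved):

    D_R_T_H^k = R_T_MC(theta, t) . MC_T_H^k        for all k
    K(q(k))   = D_R_T_H^k . (EE_T_H)^-1            joint-space constraint

where `K` is the robot forward kinematics and `EE_T_H` the humeral tool
frame. Two optimizers minimize joint-velocity utilization subject to joint
and joint-velocity limits: a derivative-free COBYLA search over the initial
joint angles `q(0)` (each candidate implies a mapping, solved to joint space
by sequential damped-least-squares IK), and a gradient-based SQP refinement
over the full joint trajectory plus `(theta, t)` with analytic constraint
Jacobians — useful when a virtual tool frame is replaced by the physically
clamped one.

**Frame identification.** The tracker-to-robot rotation `R_OT` and the
end-effector-to-rigid-body transform `EE_T_HS` are identified from paired
controller/tracker poses as an `AX = ZB` calibration (separable linear least
squares on rotations, then translations). With 0.1 mm tracker noise and 20
poses it recovers both to well under 1 degree / 1 mm.

**Program generation and virtual execution.** Dense 200 Hz trajectories are
subsampled (default: keep 20%, so waypoints average 25 ms apart) by a
pose-aware greedy max-deviation rule (`||dp|| + 0.3 * angle(dR)`), emitted as
a line-oriented motion program (waypoints, per-segment speeds, smoothness),
and executed on a simple virtual controller (piecewise-linear joint motion
with parabolic blends, speed saturation, optional first-order lag).

**Verification metrics.** Achieved trajectories (from tracking or
simulation) are temporally aligned by summed cross-correlation over
position and rotation-vector channels, expressed along the initial-thorax
anatomical axes, and compared by span-normalized mean absolute error (MAE)
for pose, velocity and acceleration, per axis and for Euclidean magnitudes.

**Interface loads.** A cylinder-segment prosthesis model (arm connection
0.75 × arm length; forearm 0.254 m / 1.013 kg; hand 0.1524 m / 0.416 kg;
jug 3.8 kg for jug lifts; elbow fixed per activity) feeds a
recursive-Newton–Euler inverse dynamics of the rigid chain, reporting the
wrench at the 25% amputation level projected into axial force, torsional
moment and bending moment about the humeral axis, plus span-normalized MAE
and error-at-peak between desired and achieved loads.

A synthetic-data module generates smooth activity-archetype trajectories,
marker-level optical noise, and calibration fixtures, so the entire pipeline
is testable without any data download.

## Worked example

```r
library(humrep)

gen   <- generate_activity("jug_lift", duration = 4, rate = 200, seed = 11,
                           position_scale = 0.7, orientation_scale = 0.5)
robot <- default_robot()                       # approximate M20iA-class 6R
tool  <- rt(rotation_about_axis(c(1, 0, 0), 0.3), c(0, 0, 0.10))

res <- run_pipeline(gen$trajectory, gen$thorax_pose, robot = robot,
                    tool = tool, activity = "jug_lift", arm_length = 0.30)

print(res$mapping_result)
print(res$program)
rep <- res$report
print(rep[rep$axis == "magnitude", ])
cat(sprintf("bending-moment error at peak: %.3f %%\n",
            res$loads$error_at_peak_pct[["bending"]]))
```

Output:

```
<mapping result: feasible, objective (velocity utilization) = 0.0279>
<frame mapping: theta = 1.5708 rad, t = (1.4575, 0.0000, -0.2075) m>
  max FK residual: 2.75e-14 m, 1.42e-14 rad
<motion program: 160 waypoints, 4.00 s, speeds 15-28 mm/s>
<comparison report: temporal offset 0 samples>
             variable      axis nmae_pct    span
             position magnitude     0.00 0.09275
          orientation magnitude     0.00 0.06646
      linear_velocity magnitude     0.01 0.01316
     angular_velocity magnitude     0.01 0.22010
  linear_acceleration magnitude     0.10 0.09931
 angular_acceleration magnitude     0.10 0.86570
bending-moment error at peak: 0.023 %
```

Reading this: the slow jug lift was mapped into the robot workspace with a
90-degree yaw and used under 3% of the robot's joint-speed budget; the
160-waypoint program (20% of 800 timepoints) replayed on the idealized
virtual controller reproduces position and orientation essentially exactly,
with the error growing with each differentiation (velocity, then
acceleration) as expected; the peak bending moment — dominated by the jug's
weight — is reproduced to a fraction of a percent. A real controller adds
lag and blending error on top of this idealized floor (see the
`simulate_execution` lag parameter and the methods vignette).

A command-line interface wrapping the same functions ships in
`inst/cli/humrep` with subcommands `synth`, `identify-frames`, `optimize`
(including a 36-frame `--tool-frame-sweep`), `subsample`, `emit-program`,
`simulate`, `inverse-dynamics`, `compare`, and `run-pipeline`.

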