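test_that("applying a frame mapping preserves speeds and matches hand algebra", {
  traj <- sinusoid_trajectory(n = 51, rate = 50)
  # identity mapping leaves the trajectory unchanged
  m0 <- apply_mapping(frame_mapping(0, c(0, 0, 0)), traj)
  expect_lt(max(vapply(seq_along(traj$poses), function(k)
    max_rt_diff(traj$poses[[k]], m0$poses[[k]]), numeric(1))), 1e-15)
  # any mapping: per-timepoint speed magnitudes unchanged (true angular
  # velocity, which unlike the rotation-vector rate is frame-invariant)
  m1 <- apply_mapping(frame_mapping(1.2, c(0.5, -0.3, 0.1)), traj)
  d0 <- derive_kinematics(traj, cutoff = NULL)
  d1 <- derive_kinematics(m1, cutoff = NULL)
  expect_lt(max(abs(d0$magnitudes$linear_velocity -
                    d1$magnitudes$linear_velocity)), 1e-9)
  omega_mag <- function(tr) {
    n <- length(tr$poses)
    vapply(2:(n - 1), function(k) {
      W <- (tr$poses[[k + 1]]$R - tr$poses[[k - 1]]$R) %*%
        t(tr$poses[[k]]$R) * tr$rate / 2
      sqrt(sum(c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1],
                 W[2, 1] - W[1, 2])^2)) / 2
    }, numeric(1))
  }
  expect_lt(max(abs(omega_mag(traj) - omega_mag(m1))), 1e-9)
  # theta = pi flips a +X trajectory to -X
  line <- pose_trajectory(lapply(0:10, function(k)
    rt(diag(3), c(0.1 * k, 0, 0.5), validate = FALSE)), rate = 10,
    validate = FALSE)
  flipped <- apply_mapping(frame_mapping(pi, c(0, 0, 0)), line)
  expect_equal(flipped$poses[[11]]$t, c(-1, 0, 0.5), tolerance = 1e-12)
  # the implied transform's rotation axis is the gravity axis
  Tm <- mapping_to_rt(frame_mapping(0.9, c(1, 2, 3)))
  v <- rotmat_to_rotvec(Tm$R)
  expect_equal(v / sqrt(sum(v^2)), c(0, 0, 1), tolerance = 1e-9)
})

test_that("implied mapping from initial joints projects onto the gravity axis", {
  rb <- default_robot()
  tool <- default_tool()
  traj <- sinusoid_trajectory(n = 21, rate = 50)
  q0 <- humrep:::seed_initial_joints(rb, traj, tool)
  imp <- implied_mapping_from_initial_joints(rb, q0, tool, traj$poses[[1]])
  # seed construction is gravity-consistent: tilt ~ 0 and round-trip holds
  expect_lt(imp$tilt_residual, 1e-6)
  mapped0 <- rt_compose(mapping_to_rt(imp$mapping), traj$poses[[1]])
  fk0 <- rt_compose(forward_kinematics(rb, q0), tool)
  expect_lt(max_rt_diff(mapped0, fk0), 1e-6)
  # constructed tilt: perturbing the candidate by 0.1 rad about X shows up
  cand <- rt_compose(rt_compose(forward_kinematics(rb, q0), tool),
                     rt_invert(traj$poses[[1]]))
  tilted <- rt(rotation_about_axis(c(1, 0, 0), 0.1) %*% cand$R, cand$t)
  # rebuild a q0 that realizes the tilted candidate
  target <- rt_compose(rt_compose(tilted, traj$poses[[1]]), rt_invert(tool))
  q_tilt <- inverse_kinematics(rb, target, q0)
  imp2 <- implied_mapping_from_initial_joints(rb, q_tilt, tool, traj$poses[[1]])
  expect_equal(imp2$tilt_residual, 0.1, tolerance = 1e-6)
  # translation is taken exactly (no projection)
  cand2 <- rt_compose(rt_compose(forward_kinematics(rb, q_tilt), tool),
                      rt_invert(traj$poses[[1]]))
  expect_equal(imp2$mapping$translation, cand2$t, tolerance = 1e-9)
})

test_that("derivative-free optimization finds feasible mappings on slow trials", {
  rb <- default_robot()
  tool <- default_tool()
  # (near-)stationary trajectory: feasible with objective ~ 0
  g0 <- constant_trajectory(rt(rotvec_to_rotmat(c(0.2, 0.1, 0)), c(0, 0, 1.3)),
                            n = 20, rate = 50)
  r0 <- optimize_derivative_free(rb, g0, tool, control = list(maxeval = 10))
  expect_true(r0$feasible)
  expect_lt(r0$objective, 1e-9)
  # slow small-amplitude trajectory: feasible, low utilization, tight FK
  g <- generate_activity("jug_lift", duration = 1.5, rate = 50, seed = 7,
                         position_scale = 0.5, orientation_scale = 0.3)
  r1 <- optimize_derivative_free(rb, g$trajectory, tool,
                                 control = list(maxeval = 25))
  expect_true(r1$feasible)
  expect_lt(r1$objective, 0.2)
  expect_lt(max(r1$fk_residual_pos), 1e-6)
  expect_lt(max(r1$fk_residual_rot), 1e-6)
  # cross-check the reported objective against check_limits
  lim <- check_limits(rb, r1$joint_trajectory)
  expect_equal(r1$objective, max(lim$utilization), tolerance = 1e-12)
  # mapping translation shifts leave the Cartesian speed profile unchanged
  # (the joint-space utilization changes with workspace placement, so the
  # kinetic invariance lives at the Cartesian level)
  shifted <- r1$mapping
  shifted$translation <- shifted$translation + c(0.02, -0.02, 0.01)
  v0 <- derive_kinematics(apply_mapping(r1$mapping, g$trajectory),
                          cutoff = NULL)$magnitudes$linear_velocity
  v1 <- derive_kinematics(apply_mapping(shifted, g$trajectory),
                          cutoff = NULL)$magnitudes$linear_velocity
  expect_lt(max(abs(v0 - v1)), 1e-9)
})

test_that("trajectories exceeding every mapped joint-speed bound are infeasible", {
  rb <- default_robot()
  tool <- default_tool()
  # angular speed alone bounds the wrist: spinning the humerus at ~2x the
  # fastest joint's limit cannot be tracked under any rigid relocation
  rate <- 50; n <- 26
  wmax <- max(rb$velocity_limits)
  spin <- 2 * wmax
  poses <- lapply(seq_len(n), function(k)
    rt(rotation_about_axis(c(1, 0, 0), spin * (k - 1) / rate), c(0.0, 0, 1.2),
       validate = FALSE))
  fast <- pose_trajectory(poses, rate = rate, validate = FALSE)
  r <- optimize_derivative_free(rb, fast, tool, control = list(maxeval = 15))
  expect_false(r$feasible)
})

test_that("gradient-based refinement descends and honors the constraints", {
  rb <- default_robot()
  tool <- default_tool()
  g <- generate_activity("jug_lift", duration = 2, rate = 50, seed = 7,
                         position_scale = 0.6, orientation_scale = 0.4)
  idx <- seq(1, length(g$trajectory$poses), by = 5)
  tdec <- pt_subset(g$trajectory, idx)
  warm <- optimize_derivative_free(rb, tdec, tool, control = list(maxeval = 25))
  expect_true(warm$feasible)
  dt <- 1 / tdec$rate
  obj_of <- function(q) sum(sweep(diff(q) / dt, 2, rb$velocity_limits, "/")^2)
  # same tool: objective never increases
  ref <- optimize_gradient_based(rb, tdec, tool, warm)
  expect_true(ref$feasible)
  expect_lte(ref$objective, obj_of(warm$joint_trajectory$q) + 1e-9)
  # perturbed tool frame (virtual -> physical substitution): re-converges
  tool2 <- rt_compose(tool, rt(rotation_about_axis(c(0, 1, 0), 5 * pi / 180),
                               c(0, 0, 0)))
  ref2 <- optimize_gradient_based(rb, tdec, tool2, warm)
  expect_true(ref2$feasible)
  expect_lt(max(ref2$fk_residual_pos), 1e-6)
  expect_lt(max(ref2$fk_residual_rot), 1e-6)
  # equality constraints hold at every waypoint for the returned solution
  traj_R <- apply_mapping(ref2$mapping, tdec)
  for (k in seq_along(traj_R$poses)) {
    fk <- rt_compose(forward_kinematics(rb, ref2$joint_trajectory$q[k, ]), tool2)
    expect_lt(max_rt_diff(fk, traj_R$poses[[k]]), 1e-6)
  }
})

test_that("full-loop mapping consistency holds for the returned result", {
  rb <- default_robot()
  tool <- default_tool()
  g <- generate_activity("internal_rotation", duration = 1.5, rate = 50,
                         seed = 19, position_scale = 1,
                         orientation_scale = 0.3)
  r <- optimize_derivative_free(rb, g$trajectory, tool,
                                control = list(maxeval = 25))
  expect_true(r$feasible)
  inv_map <- rt_invert(mapping_to_rt(r$mapping))
  for (k in seq_along(g$trajectory$poses)) {
    fk <- rt_compose(forward_kinematics(rb, r$joint_trajectory$q[k, ]), tool)
    back <- rt_compose(inv_map, fk)
    expect_lt(sqrt(sum((back$t - g$trajectory$poses[[k]]$t)^2)), 1e-6)
    expect_lt(rotation_angle(back$R, g$trajectory$poses[[k]]$R), 1e-6)
  }
  # doubling the velocity limits cannot make a feasible trial infeasible
  rb2 <- rb; rb2$velocity_limits <- rb$velocity_limits * 2
  sol2 <- solve_joint_trajectory(rb2, apply_mapping(r$mapping, g$trajectory),
                                 tool, r$joint_trajectory$q[1, ])
  expect_true(check_limits(rb2, sol2$trajectory)$feasible)
})

test_that("virtual tool frame sweep produces 36 frames in 30-degree steps", {
  phys <- default_tool()
  frames <- generate_virtual_tool_frames(phys, humeral_length = 0.30)
  expect_length(frames, 36)
  expect_lt(max_rt_diff(frames[[1]], phys), 1e-15)
  # successive frames at the same clamp differ by 30 deg about the humeral axis
  rel <- rt_compose(rt_invert(frames[[2]]), frames[[3]])
  v <- rotmat_to_rotvec(rel$R)
  expect_equal(sqrt(sum(v^2)), 30 * pi / 180, tolerance = 1e-9)
  expect_equal(abs(v[2]) / sqrt(sum(v^2)), 1, tolerance = 1e-9)  # humeral Y axis
  # 3 distinct clamp translations
  tz <- unique(round(vapply(frames, function(f)
    rt_compose(rt_invert(phys), f)$t[2], numeric(1)), 10))
  expect_length(tz, 3)
})
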