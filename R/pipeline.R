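#' Run the full replication pipeline
#'
#' Chains the stages end-to-end on one humeral trajectory: gravity-
#' consistent mapping into the robot frame and joint space (derivative-free
#' optimization), pose-aware subsampling to waypoints, motion-program
#' emission, execution on the virtual controller, reconstruction of the
#' achieved trajectory, and the kinematic comparison report; optionally
#' also desired-vs-achieved interface loads for the activity's prosthesis
#' model. Deterministic given its inputs.
#'
#' @param traj_MC humeral `pose_trajectory` in the MC frame.
#' @param thorax_pose [rt()] initial thorax pose (reference axes for the
#'   report).
#' @param robot a `robot_model` (default [default_robot()]).
#' @param tool [rt()] humeral tool frame `EE_T_H` (default: identity-like
#'   offset placing the humerus 10 cm off the flange).
#' @param keep_fraction subsampling fraction (default 0.2).
#' @param smoothness program blend value (default 100).
#' @param cutoff verification filter cutoff (Hz, default 8).
#' @param controller virtual controller parameters for
#'   [simulate_execution()].
#' @param activity,arm_length when both given, interface loads are computed
#'   for desired and achieved kinematics and load metrics reported.
#' @param optimizer_control control list for [optimize_derivative_free()].
#' @return list with `mapping_result`, `indices`, `program`, `achieved`
#'   (pose trajectory), `desired_R` (mapped desired trajectory), `report`
#'   (comparison report), and optionally `loads` (list with `desired`,
#'   `achieved`, `nmae_pct`, `error_at_peak_pct` per load variable).
#' @export
run_pipeline <- function(traj_MC, thorax_pose, robot = default_robot(),
                         tool = rt(diag(3), c(0, 0, 0.10)),
                         keep_fraction = 0.2, smoothness = 100, cutoff = 8,
                         controller = list(), activity = NULL,
                         arm_length = NULL, optimizer_control = list()) {
  mr <- optimize_derivative_free(robot, traj_MC, tool,
                                 control = optimizer_control)
  if (!mr$feasible)
    stop("mapping optimization found no feasible joint trajectory")
  desired_R <- apply_mapping(mr$mapping, traj_MC)
  idx <- nonuniform_subsample(desired_R, keep_fraction)
  prog <- emit_motion_program(mr$joint_trajectory, robot, idx, tool = tool,
                              smoothness = smoothness)
  sim <- simulate_execution(prog, robot, tool = tool, controller = controller)
  achieved <- sim$pose_trajectory
  report <- normalized_mae(desired_R, achieved, thorax_pose, cutoff = cutoff)
  out <- list(mapping_result = mr, indices = idx, program = prog,
              achieved = achieved, desired_R = desired_R, report = report)
  if (!is.null(activity) && !is.null(arm_length)) {
    model <- build_prosthesis_model(arm_length, activity)
    offset <- attr(report, "offset")
    ov <- shift_overlap(length(desired_R$poses), length(achieved$poses), offset)
    d_al <- pt_subset(desired_R, ov$d)
    a_al <- pt_subset(achieved, ov$a)
    ld <- rnea_loads(model, d_al, derive_kinematics(d_al, cutoff = cutoff))
    la <- rnea_loads(model, a_al, derive_kinematics(a_al, cutoff = cutoff))
    vars <- c("axial", "torsion", "bending")
    nm <- vapply(vars, function(v) nmae_series(ld[[v]], la[[v]])[["nmae"]],
                 numeric(1))
    ep <- vapply(vars, function(v) error_at_peak(ld[[v]], la[[v]]), numeric(1))
    out$loads <- list(desired = ld, achieved = la, nmae_pct = nm,
                      error_at_peak_pct = ep)
  }
  out
}
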