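#' Serial 6R robot model
#'
#' Standard Denavit-Hartenberg description of a 6-revolute-joint serial
#' manipulator with joint and joint-velocity limits. The per-joint transform
#' is `RotZ(theta_i + offset_i) TransZ(d_i) TransX(a_i) RotX(alpha_i)`.
#'
#' @param dh 6 x 4 matrix with columns `a` (m), `alpha` (rad), `d` (m),
#'   `theta_offset` (rad).
#' @param joint_limits 6 x 2 matrix, per-joint `[min, max]` (rad).
#' @param velocity_limits length-6 vector of max `|qdot|` (rad/s), all > 0.
#' @param base,flange fixed transforms ahead of joint 1 and after joint 6.
#' @param name descriptive label.
#' @return object of class `robot_model`.
#' @export
robot_model <- function(dh, joint_limits, velocity_limits,
                        base = rt_identity(), flange = rt_identity(),
                        name = "robot") {
  dh <- as.matrix(dh)
  joint_limits <- as.matrix(joint_limits)
  if (!all(dim(dh) == c(6L, 4L))) stop("dh must be 6 x 4")
  if (!all(dim(joint_limits) == c(6L, 2L))) stop("joint_limits must be 6 x 2")
  if (any(joint_limits[, 1] >= joint_limits[, 2])) stop("limits need min < max")
  if (length(velocity_limits) != 6L || any(velocity_limits <= 0))
    stop("velocity_limits must be 6 positive values")
  colnames(dh) <- c("a", "alpha", "d", "theta_offset")
  structure(list(dh = dh, joint_limits = joint_limits,
                 velocity_limits = as.numeric(velocity_limits),
                 base = base, flange = flange, name = name),
            class = "robot_model")
}

#' @export
print.robot_model <- function(x, ...) {
  cat(sprintf("<robot model '%s': 6R serial manipulator>\n", x$name))
  print(round(cbind(x$dh, x$joint_limits, qdot_max = x$velocity_limits), 4))
  invisible(x)
}

dh_transform <- function(a, alpha, d, theta) {
  ct <- cos(theta); st <- sin(theta)
  ca <- cos(alpha); sa <- sin(alpha)
  rt(matrix(c(ct, st, 0,
              -st * ca, ct * ca, sa,
              st * sa, -ct * sa, ca), 3, 3),
     c(a * ct, a * st, d), validate = FALSE)
}

fk_frames <- function(robot, q) {
  frames <- vector("list", 7L)
  frames[[1]] <- robot$base
  for (i in 1:6) {
    Ti <- dh_transform(robot$dh[i, 1], robot$dh[i, 2], robot$dh[i, 3],
                       q[i] + robot$dh[i, 4])
    frames[[i + 1]] <- rt_compose(frames[[i]], Ti, validate = FALSE)
  }
  frames
}

#' Forward kinematics
#'
#' Pose of the end-effector (flange) in the robot base frame: the ordered
#' product of the per-joint DH transforms.
#'
#' @param robot a `robot_model`.
#' @param q joint angles, length-6 (rad).
#' @return [rt()] pose of the end-effector.
#' @export
forward_kinematics <- function(robot, q) {
  if (length(q) != 6L || any(!is.finite(q))) stop("q must be 6 finite values")
  rt_compose(fk_frames(robot, q)[[7]], robot$flange, validate = FALSE)
}

#' Geometric Jacobian
#'
#' 6 x 6 Jacobian with linear rows 1-3 and angular rows 4-6, columns the
#' joint screw axes expressed at the end-effector point, all in the base
#' frame: column i is `(z_{i-1} x (p_ee - p_{i-1}); z_{i-1})`.
#'
#' @inheritParams forward_kinematics
#' @return 6 x 6 matrix.
#' @export
geometric_jacobian <- function(robot, q) {
  frames <- fk_frames(robot, q)
  ee <- rt_compose(frames[[7]], robot$flange, validate = FALSE)
  J <- matrix(0, 6, 6)
  for (i in 1:6) {
    z <- frames[[i]]$R[, 3]
    p <- frames[[i]]$t
    J[1:3, i] <- crossprod3(z, ee$t - p)
    J[4:6, i] <- z
  }
  J
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

pose_error_twist <- function(current, target) {
  c(target$t - current$t, rotmat_to_rotvec(target$R %*% t(current$R)))
}

#' Numeric inverse kinematics (damped least squares)
#'
#' Iterative damped-least-squares solve for the joint angles reproducing a
#' target end-effector pose, starting from `q_seed`. The branch returned is
#' the one reached by continuous iteration from the seed, which in
#' trajectory solves (seeded by the previous timepoint) makes the joint
#' trajectory unique and continuous. Adaptive Levenberg damping with a
#' Jacobian-transpose fallback step when a trial step fails to descend.
#'
#' @param robot a `robot_model`.
#' @param target [rt()] target pose of the end-effector in the base frame.
#' @param q_seed starting joint vector (rad).
#' @param tol convergence tolerance on position (m) and orientation (rad)
#'   residual norms (default 1e-10, well inside the 1e-6 contract).
#' @param max_iter iteration budget.
#' @return joint vector (rad). On non-convergence an error of class
#'   `humrep_unreachable` is signalled carrying the best residual in
#'   `data$residual`.
#' @export
inverse_kinematics <- function(robot, target, q_seed, tol = 1e-10,
                               max_iter = 200) {
  q <- as.numeric(q_seed)
  lambda <- 1e-3
  cur <- forward_kinematics(robot, q)
  e <- pose_error_twist(cur, target)
  err <- sqrt(sum(e^2))
  for (it in seq_len(max_iter)) {
    if (err < tol) return(q)
    J <- geometric_jacobian(robot, q)
    dq <- tryCatch(
      as.numeric(t(J) %*% solve(J %*% t(J) + lambda^2 * diag(6), e)),
      error = function(cnd) as.numeric(t(J) %*% e) * 0.1)
    stepn <- sqrt(sum(dq^2))
    if (stepn > 0.5) dq <- dq * 0.5 / stepn
    q_new <- q + dq
    cur_new <- forward_kinematics(robot, q_new)
    e_new <- pose_error_twist(cur_new, target)
    err_new <- sqrt(sum(e_new^2))
    if (err_new < err) {
      q <- q_new; e <- e_new; err <- err_new
      lambda <- max(lambda / 2, 1e-8)
    } else {
      # fallback: Jacobian-transpose step with line search
      alpha <- 0.5
      improved <- FALSE
      for (ls in 1:8) {
        dq_t <- alpha * as.numeric(t(J) %*% e)
        nn <- sqrt(sum(dq_t^2)); if (nn > 0.25) dq_t <- dq_t * 0.25 / nn
        q_try <- q + dq_t
        e_try <- pose_error_twist(forward_kinematics(robot, q_try), target)
        if (sqrt(sum(e_try^2)) < err) {
          q <- q_try; e <- e_try; err <- sqrt(sum(e_try^2)); improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      lambda <- min(lambda * 10, 1e2)
      if (!improved && lambda >= 1e2 && it > 20) break
    }
  }
  if (err < tol) return(q)
  cond <- structure(
    class = c("humrep_unreachable", "error", "condition"),
    list(message = sprintf("IK did not converge (best residual %.3e)", err),
         call = sys.call(-1), data = list(residual = err, q_best = q)))
  stop(cond)
}

#' Joint trajectory container
#'
#' @param q n x 6 matrix of joint angles (rad).
#' @param rate sampling rate (Hz).
#' @param time optional timestamps (s).
#' @return object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(q, rate, time = NULL) {
  q <- as.matrix(q)
  if (ncol(q) != 6L) stop("q must have 6 columns")
  if (is.null(time)) time <- (seq_len(nrow(q)) - 1) / rate
  structure(list(q = q, rate = rate, time = time), class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf("<joint trajectory: %d timepoints @ %g Hz>\n", nrow(x$q), x$rate))
  invisible(x)
}

#' Joint-limit and velocity-limit feasibility report
#'
#' Joint velocities are obtained by central finite differences at the native
#' rate (forward/backward at the endpoints). Velocity utilization of joint i
#' is `max_k |qdot_i(k)| / qdot_i_max`; the trajectory is feasible iff every
#' joint angle is within limits and every utilization is <= 1.
#'
#' @param robot a `robot_model`.
#' @param traj a `joint_trajectory` with uniform timestamps (>= 2 points).
#' @return list with `feasible`, per-joint `utilization`, `q_min`, `q_max`,
#'   logical `within_limits`, and `violations` (character).
#' @export
check_limits <- function(robot, traj) {
  if (nrow(traj$q) < 2L) stop("need at least 2 timepoints")
  qd <- central_diff(traj$q, 1 / traj$rate)
  util <- apply(abs(qd), 2, max) / robot$velocity_limits
  qmin <- apply(traj$q, 2, min); qmax <- apply(traj$q, 2, max)
  within <- qmin >= robot$joint_limits[, 1] & qmax <= robot$joint_limits[, 2]
  viol <- character(0)
  for (i in 1:6) {
    if (!within[i]) viol <- c(viol, sprintf("joint %d exceeds position limits", i))
    if (util[i] > 1) viol <- c(viol, sprintf("joint %d velocity utilization %.2f", i, util[i]))
  }
  list(feasible = all(within) && all(util <= 1), utilization = util,
       q_min = qmin, q_max = qmax, within_limits = within, violations = viol)
}

#' Read a robot definition file
#'
#' YAML schema (lengths in meters, angles in degrees, speeds in degrees/s;
#' parsed to SI): `name`; `dh`: list of 6 rows `[a_m, alpha_deg, d_m,
#' theta_offset_deg]`; `joint_limits_deg`: 6 rows `[min, max]`;
#' `velocity_limits_deg_s`: 6 values; optional `base`/`flange`: `[x_m, y_m,
#' z_m, rx_deg, ry_deg, rz_deg]` (rotation-vector, degrees).
#'
#' @param file path to a YAML robot config.
#' @return [robot_model()].
#' @export
read_robot_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  for (f in c("dh", "joint_limits_deg", "velocity_limits_deg_s"))
    if (is.null(cfg[[f]])) stop("robot config missing field: ", f)
  d2r <- pi / 180
  dh <- do.call(rbind, cfg$dh)
  dh[, 2] <- dh[, 2] * d2r
  dh[, 4] <- dh[, 4] * d2r
  jl <- do.call(rbind, cfg$joint_limits_deg) * d2r
  vl <- as.numeric(cfg$velocity_limits_deg_s) * d2r
  parse_frame <- function(v) {
    if (is.null(v)) return(rt_identity())
    rt(rotvec_to_rotmat(as.numeric(v[4:6]) * d2r), as.numeric(v[1:3]))
  }
  robot_model(dh, jl, vl, base = parse_frame(cfg$base),
              flange = parse_frame(cfg$flange),
              name = if (is.null(cfg$name)) "robot" else cfg$name)
}

#' Built-in robot definitions
#'
#' `default_robot()` loads the approximate M20iA-class 6R model shipped with
#' the package (about 1.8 m reach, vendor-class joint and velocity limits;
#' the true vendor kinematic parameters are not public, so this is a
#' documented approximation loaded from config like any other robot).
#' `planar_test_robot()` is a simple analytic model (two 0.5 m links in a
#' plane) used for hand-checkable kinematics tests.
#'
#' @return [robot_model()].
#' @export
default_robot <- function() {
  read_robot_config(system.file("extdata", "robot_m20ia_like.yaml",
                                package = "humrep", mustWork = TRUE))
}

#' @rdname default_robot
#' @export
planar_test_robot <- function() {
  dh <- cbind(a = c(0.5, 0.5, 0, 0, 0, 0), alpha = 0, d = 0, theta_offset = 0)
  robot_model(dh, cbind(rep(-pi, 6), rep(pi, 6)), rep(pi, 6),
              name = "planar-test")
}
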