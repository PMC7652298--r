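#' Gravity-consistent frame mapping
#'
#' The mapping from the motion-capture frame to the robot frame is
#' restricted to a rotation about the gravitational axis (+Z up in both
#' frames) by `theta` plus a 3-D translation — 4 parameters in total — so
#' that gravitational load directions relative to the motion are preserved.
#'
#' @param theta rotation about the gravity axis (rad).
#' @param translation 3-vector `t_MC->R` (m).
#' @return object of class `frame_mapping`.
#' @export
frame_mapping <- function(theta, translation = c(0, 0, 0)) {
  structure(list(theta = as.numeric(theta),
                 translation = as.numeric(translation)),
            class = "frame_mapping")
}

#' @export
print.frame_mapping <- function(x, ...) {
  cat(sprintf("<frame mapping: theta = %.4f rad, t = (%.4f, %.4f, %.4f) m>\n",
              x$theta, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @rdname frame_mapping
#' @param mapping a `frame_mapping`.
#' @return `mapping_to_rt`: the implied rigid transform `R_T_MC`.
#' @export
mapping_to_rt <- function(mapping) {
  rt(rotation_about_axis(c(0, 0, 1), mapping$theta), mapping$translation,
     validate = FALSE)
}

#' Apply a frame mapping to a trajectory
#'
#' Left-multiplies every pose by the mapping transform, relocating the
#' trajectory from the motion-capture frame to the robot frame. Being a
#' rigid relocation, per-timepoint linear and angular speed magnitudes are
#' unchanged (kinetic preservation).
#'
#' @param mapping a [frame_mapping()].
#' @param traj a `pose_trajectory` in the MC frame.
#' @return `pose_trajectory` in the robot frame (`source_frame = "R"`).
#' @export
apply_mapping <- function(mapping, traj) {
  Tm <- mapping_to_rt(mapping)
  traj$poses <- lapply(traj$poses, function(p) rt_compose(Tm, p, validate = FALSE))
  traj$source_frame <- "R"
  traj
}

yaw_of_rotation <- function(R) {
  # best-fit rotation about +Z: argmax_theta tr(Rz(-theta) R)
  atan2(R[2, 1] - R[1, 2], R[1, 1] + R[2, 2])
}

#' Frame mapping implied by an initial robot configuration
#'
#' Inverts the joint-space constraint at the first timepoint: given the
#' initial joint angles `q0`, the candidate mapping transform is
#' `K(q0) . EE_T_H . (MC_T_H^0)^-1`. Its rotation is projected onto the
#' gravity axis (best-fit yaw); `tilt_residual` is the geodesic angle
#' between the candidate rotation and its gravity-axis projection. The
#' translation is taken as-is.
#'
#' @param robot a `robot_model`.
#' @param q0 initial joint angles (rad).
#' @param tool [rt()] `EE_T_H` humeral tool frame.
#' @param first_pose [rt()] `MC_T_H^0`, first pose of the MC trajectory.
#' @return list with `mapping` ([frame_mapping()]) and `tilt_residual` (rad).
#' @export
implied_mapping_from_initial_joints <- function(robot, q0, tool, first_pose) {
  cand <- rt_compose(rt_compose(forward_kinematics(robot, q0), tool,
                                validate = FALSE),
                     rt_invert(first_pose, validate = FALSE), validate = FALSE)
  theta <- yaw_of_rotation(cand$R)
  Rg <- rotation_about_axis(c(0, 0, 1), theta)
  list(mapping = frame_mapping(theta, cand$t),
       tilt_residual = rotation_angle(cand$R, Rg))
}

#' Sequential joint-space solve of a robot-frame trajectory
#'
#' Solves `K(q(k)) = T_k . (EE_T_H)^-1` timepoint by timepoint, seeding each
#' IK solve with the previous solution (branch continuity).
#'
#' @param robot a `robot_model`.
#' @param traj_R `pose_trajectory` of the humerus in the robot frame.
#' @param tool [rt()] `EE_T_H`.
#' @param q0 seed for the first timepoint.
#' @param stride solve every `stride`-th timepoint (>= 1); used by the
#'   derivative-free optimizer to cheapen candidate evaluation.
#' @return list with `trajectory` ([joint_trajectory()]), `fk_residual_pos`
#'   and `fk_residual_rot` per solved timepoint, and `indices` solved.
#' @export
solve_joint_trajectory <- function(robot, traj_R, tool, q0, stride = 1L) {
  inv_tool <- rt_invert(tool)
  idx <- unique(c(seq(1L, length(traj_R$poses), by = stride), length(traj_R$poses)))
  n <- length(idx)
  q <- matrix(0, n, 6)
  rp <- rr <- numeric(n)
  q_prev <- as.numeric(q0)
  for (j in seq_len(n)) {
    target <- rt_compose(traj_R$poses[[idx[j]]], inv_tool, validate = FALSE)
    q_prev <- inverse_kinematics(robot, target, q_prev)
    q[j, ] <- q_prev
    achieved <- forward_kinematics(robot, q_prev)
    rp[j] <- sqrt(sum((achieved$t - target$t)^2))
    rr[j] <- rotation_angle(achieved$R, target$R)
  }
  dt <- if (n > 1) traj_R$time[idx[2]] - traj_R$time[idx[1]] else 1 / traj_R$rate
  list(trajectory = joint_trajectory(q, rate = 1 / dt, time = traj_R$time[idx]),
       fk_residual_pos = rp, fk_residual_rot = rr, indices = idx)
}

mapping_result <- function(joint_trajectory, mapping, objective, feasible,
                           fk_residual_pos, fk_residual_rot, tool,
                           diagnostics = list()) {
  structure(list(joint_trajectory = joint_trajectory, mapping = mapping,
                 objective = objective, feasible = feasible,
                 fk_residual_pos = fk_residual_pos,
                 fk_residual_rot = fk_residual_rot,
                 tool = tool, diagnostics = diagnostics),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping result: %s, objective (velocity utilization) = %.4f>\n",
              if (x$feasible) "feasible" else "INFEASIBLE", x$objective))
  print(x$mapping)
  cat(sprintf("  max FK residual: %.2e m, %.2e rad\n",
              max(x$fk_residual_pos), max(x$fk_residual_rot)))
  invisible(x)
}

evaluate_candidate <- function(robot, traj_MC, tool, q0, stride = 1L) {
  imp <- implied_mapping_from_initial_joints(robot, q0, tool,
                                             traj_MC$poses[[1]])
  traj_R <- apply_mapping(imp$mapping, traj_MC)
  sol <- tryCatch(
    solve_joint_trajectory(robot, traj_R, tool,
                           inverse_kinematics(robot,
                             rt_compose(traj_R$poses[[1]], rt_invert(tool),
                                        validate = FALSE), q0),
                           stride = stride),
    humrep_unreachable = function(cnd) NULL,
    error = function(cnd) NULL)
  if (is.null(sol)) {
    return(list(ok = FALSE, tilt = imp$tilt_residual, mapping = imp$mapping))
  }
  lim <- check_limits(robot, sol$trajectory)
  list(ok = TRUE, tilt = imp$tilt_residual, mapping = imp$mapping, sol = sol,
       limits = lim, utilization = max(lim$utilization))
}

#' Derivative-free mapping optimization (COBYLA over initial joints)
#'
#' Optimizes the 6 initial joint angles `q(0)` by constrained optimization
#' by linear approximation. Each candidate `q(0)` implies a
#' gravity-consistent mapping ([implied_mapping_from_initial_joints()]);
#' the MC trajectory is mapped into the robot frame and solved sequentially
#' to joint space; the objective is the maximum joint-velocity utilization
#' over joints and time. Constraints: tilt residual <= `tilt_tol`, joint
#' limits, and utilization <= 1.
#'
#' @param robot a `robot_model`.
#' @param traj_MC `pose_trajectory` in the MC frame.
#' @param tool [rt()] `EE_T_H` humeral tool frame.
#' @param seed_q0 starting joint vector; if `NULL`, a feasible-tilt seed is
#'   constructed by IK of the first pose under a zero-yaw mapping placed in
#'   the workspace.
#' @param control list: `maxeval` (default 60), `stride` (candidate
#'   evaluation stride, default 1), `tilt_tol` (rad, default 1e-3),
#'   `rhobeg` (initial COBYLA step, rad, default 0.15).
#' @return [`mapping_result`] (feasible or the best infeasible candidate
#'   with `feasible = FALSE`).
#' @export
optimize_derivative_free <- function(robot, traj_MC, tool, seed_q0 = NULL,
                                     control = list()) {
  ctl <- utils::modifyList(list(maxeval = 60, stride = 1L, tilt_tol = 1e-3,
                                rhobeg = 0.15), control)
  if (is.null(seed_q0)) seed_q0 <- seed_initial_joints(robot, traj_MC, tool)
  best <- new.env(parent = emptyenv())
  best$obj <- Inf; best$cand <- NULL
  evalq0 <- function(q0) {
    cand <- evaluate_candidate(robot, traj_MC, tool, q0, stride = ctl$stride)
    if (!cand$ok) return(list(obj = 10, con = c(ctl$tilt_tol - cand$tilt, rep(-1, 13))))
    lim <- cand$limits
    margins <- c(lim$q_min - robot$joint_limits[, 1],
                 robot$joint_limits[, 2] - lim$q_max)
    con <- c(ctl$tilt_tol - cand$tilt, margins, 1 - cand$utilization)
    feas <- all(con >= 0)
    if (feas && cand$utilization < best$obj) {
      best$obj <- cand$utilization; best$cand <- cand
    }
    list(obj = cand$utilization, con = con)
  }
  cache <- new.env(parent = emptyenv())
  fn <- function(x) {
    key <- paste(signif(x, 12), collapse = ",")
    if (is.null(cache[[key]])) cache[[key]] <- evalq0(x)
    cache[[key]]$obj
  }
  hin <- function(x) {
    key <- paste(signif(x, 12), collapse = ",")
    if (is.null(cache[[key]])) cache[[key]] <- evalq0(x)
    -cache[[key]]$con  # nloptr convention: hin(x) <= 0 feasible
  }
  res <- tryCatch(
    nloptr::cobyla(x0 = seed_q0, fn = fn, hin = hin,
                   lower = robot$joint_limits[, 1],
                   upper = robot$joint_limits[, 2],
                   control = list(maxeval = ctl$maxeval, xtol_rel = 1e-8),
                   deprecatedBehavior = FALSE),
    error = function(cnd) NULL)
  # final full-resolution evaluation of the best feasible candidate (or the
  # COBYLA terminal point if nothing feasible was cached)
  q_final <- if (!is.null(best$cand)) {
    best$cand$sol$trajectory$q[1, ]
  } else if (!is.null(res)) res$par else seed_q0
  cand <- evaluate_candidate(robot, traj_MC, tool, q_final, stride = 1L)
  if (!cand$ok) {
    return(mapping_result(NULL, cand$mapping, Inf, FALSE, Inf, Inf, tool,
                          diagnostics = list(reason = "IK failed on final candidate")))
  }
  feas <- cand$limits$feasible && cand$tilt <= ctl$tilt_tol &&
    max(cand$sol$fk_residual_pos) < 1e-6 && max(cand$sol$fk_residual_rot) < 1e-6
  mapping_result(cand$sol$trajectory, cand$mapping, cand$utilization, feas,
                 cand$sol$fk_residual_pos, cand$sol$fk_residual_rot, tool,
                 diagnostics = list(tilt_residual = cand$tilt,
                                    limits = cand$limits,
                                    evaluations = length(ls(cache))))
}

seed_initial_joints <- function(robot, traj_MC, tool) {
  # place the first mapped pose at a nominal point in front of the robot,
  # preserving orientation up to yaw; among the yaws whose IK succeeds,
  # keep the configuration with the largest normalized joint-limit margin
  first <- traj_MC$poses[[1]]
  reach <- sum(abs(robot$dh[, "a"])) + sum(abs(robot$dh[, "d"]))
  anchor <- c(0.55 * reach, 0, 0.45 * reach)
  q_home <- rowMeans(robot$joint_limits)
  best <- NULL; best_margin <- -Inf
  for (theta in seq(0, 2 * pi - 1e-6, by = pi / 4)) {
    m <- frame_mapping(theta, c(0, 0, 0))
    p0 <- rt_compose(mapping_to_rt(m), first, validate = FALSE)
    m$translation <- anchor - p0$t
    target <- rt_compose(rt_compose(mapping_to_rt(m), first, validate = FALSE),
                         rt_invert(tool), validate = FALSE)
    q0 <- tryCatch(inverse_kinematics(robot, target, q_home),
                   error = function(cnd) NULL)
    if (is.null(q0)) next
    q0 <- wrap_to_limits(q0, robot$joint_limits)
    margin <- min(pmin(q0 - robot$joint_limits[, 1],
                       robot$joint_limits[, 2] - q0) /
                  (robot$joint_limits[, 2] - robot$joint_limits[, 1]))
    if (margin > best_margin) { best <- q0; best_margin <- margin }
  }
  if (is.null(best))
    stop("could not construct a reachable seed configuration for the first pose")
  best
}

# 2*pi-equivalent joint values nearest zero that stay inside the limits
wrap_to_limits <- function(q, limits) {
  for (i in seq_along(q)) {
    cand <- q[i] + 2 * pi * (-2:2)
    cand <- cand[cand >= limits[i, 1] & cand <= limits[i, 2]]
    if (length(cand)) q[i] <- cand[which.min(abs(cand))]
  }
  q
}

#' Gradient-based mapping refinement (SQP over the full joint trajectory)
#'
#' Refines a mapping result by sequential quadratic programming
#' (`nloptr::slsqp`) over the full stacked joint trajectory plus the four
#' mapping parameters `(theta, t)`. Equality constraints impose the
#' joint-space pose constraint at every retained timepoint; joint limits
#' enter as variable bounds and velocity limits as linear inequalities. The
#' objective is the smooth surrogate `sum_k sum_i (qdot_i(k)/qdot_i_max)^2`.
#' After convergence the equality constraints are pinned by re-running the
#' sequential IK at the returned mapping, so the max FK residual is never
#' worse than the initial result's. Typical use: warm start from a
#' derivative-free result obtained with a different (virtual) tool frame,
#' then refine for the physically matched tool frame.
#'
#' @param robot a `robot_model`.
#' @param traj_MC `pose_trajectory` in the MC frame (keep the waypoint count
#'   modest, e.g. <= 60, by decimation before calling; the solve is dense).
#' @param tool [rt()] `EE_T_H` tool frame to refine for.
#' @param initial a [`mapping_result`] warm start (its joint trajectory must
#'   have one row per timepoint of `traj_MC`).
#' @param control list: `maxeval` (default 200), `tol` (default 1e-8).
#' @return refined [`mapping_result`].
#' @export
optimize_gradient_based <- function(robot, traj_MC, tool, initial,
                                    control = list()) {
  ctl <- utils::modifyList(list(maxeval = 200, tol = 1e-8), control)
  n <- length(traj_MC$poses)
  if (is.null(initial$joint_trajectory) || nrow(initial$joint_trajectory$q) != n)
    stop("initial result must carry one joint vector per trajectory timepoint")
  dt <- 1 / traj_MC$rate
  vmax <- robot$velocity_limits
  inv_tool <- rt_invert(tool)
  # target pose of the EE for timepoint k given (theta, t):
  # T_k(theta,t) = [Rz(theta)|t] . MC_T_H^k . inv(tool)
  A_list <- lapply(traj_MC$poses, function(p) rt_compose(p, inv_tool, validate = FALSE))
  pack <- function(q, theta, tr) c(as.numeric(t(q)), theta, tr)
  unpack <- function(x) list(q = matrix(x[1:(6 * n)], n, 6, byrow = TRUE),
                             theta = x[6 * n + 1], tr = x[(6 * n + 2):(6 * n + 4)])
  obj <- function(x) {
    z <- unpack(x)
    dq <- diff(z$q) / dt
    sum(sweep(dq, 2, vmax, "/")^2)
  }
  obj_grad <- function(x) {
    z <- unpack(x)
    dq <- diff(z$q) / dt
    g <- matrix(0, n, 6)
    w <- sweep(dq, 2, vmax^2, "/") * 2 / dt
    g[1:(n - 1), ] <- g[1:(n - 1), ] - w
    g[2:n, ] <- g[2:n, ] + w
    c(as.numeric(t(g)), 0, 0, 0, 0)
  }
  heq <- function(x) {
    z <- unpack(x)
    Rz <- rotation_about_axis(c(0, 0, 1), z$theta)
    out <- numeric(6 * n)
    for (k in seq_len(n)) {
      Ak <- A_list[[k]]
      tgt_t <- as.numeric(Rz %*% Ak$t) + z$tr
      tgt_R <- Rz %*% Ak$R
      fkk <- forward_kinematics(robot, z$q[k, ])
      out[(6 * k - 5):(6 * k)] <- c(tgt_t - fkk$t,
                                    rotmat_to_rotvec(tgt_R %*% t(fkk$R)))
    }
    out
  }
  heq_jac <- function(x) {
    z <- unpack(x)
    Rz <- rotation_about_axis(c(0, 0, 1), z$theta)
    dRz <- skew(c(0, 0, 1)) %*% Rz
    Jm <- matrix(0, 6 * n, 6 * n + 4)
    for (k in seq_len(n)) {
      rows <- (6 * k - 5):(6 * k)
      cols <- (6 * k - 5):(6 * k)
      Jm[rows, cols] <- -geometric_jacobian(robot, z$q[k, ])
      Ak <- A_list[[k]]
      Jm[rows[1:3], 6 * n + 1] <- as.numeric(dRz %*% Ak$t)
      Jm[rows[1:3], (6 * n + 2):(6 * n + 4)] <- diag(3)
      Jm[rows[4:6], 6 * n + 1] <- c(0, 0, 1)  # spatial rate of target rotation
    }
    Jm
  }
  hin <- function(x) {
    z <- unpack(x)
    dq <- diff(z$q) / dt
    as.numeric(t(sweep(abs(dq), 2, vmax, "/") - 1))  # <= 0 feasible
  }
  hin_jac <- function(x) {
    z <- unpack(x)
    dq <- diff(z$q) / dt
    Jm <- matrix(0, 6 * (n - 1), 6 * n + 4)
    for (k in seq_len(n - 1)) {
      for (i in 1:6) {
        r <- 6 * (k - 1) + i
        s <- sign(dq[k, i]) / (dt * vmax[i])
        if (s == 0) s <- 1 / (dt * vmax[i])  # subgradient at zero velocity
        Jm[r, 6 * (k - 1) + i] <- -s
        Jm[r, 6 * k + i] <- s
      }
    }
    Jm
  }
  x0 <- pack(initial$joint_trajectory$q, initial$mapping$theta,
             initial$mapping$translation)
  lower <- c(rep(robot$joint_limits[, 1], times = n), -2 * pi, rep(-Inf, 3))
  upper <- c(rep(robot$joint_limits[, 2], times = n), 2 * pi, rep(Inf, 3))
  res <- nloptr::slsqp(x0 = x0, fn = obj, gr = obj_grad,
                       lower = lower, upper = upper,
                       hin = hin, hinjac = hin_jac,
                       heq = heq, heqjac = heq_jac,
                       control = list(maxeval = ctl$maxeval,
                                      xtol_rel = ctl$tol, ftol_rel = ctl$tol),
                       deprecatedBehavior = FALSE)
  z <- unpack(res$par)
  mapping <- frame_mapping(z$theta, z$tr)
  # pin equality constraints by sequential IK at the refined mapping
  traj_R <- apply_mapping(mapping, traj_MC)
  sol <- solve_joint_trajectory(robot, traj_R, tool, z$q[1, ])
  lim <- check_limits(robot, sol$trajectory)
  qd <- diff(sol$trajectory$q) / dt
  objective <- sum(sweep(qd, 2, vmax, "/")^2)
  feas <- lim$feasible && max(sol$fk_residual_pos) < 1e-6 &&
    max(sol$fk_residual_rot) < 1e-6
  out <- mapping_result(sol$trajectory, mapping, objective, feas,
                        sol$fk_residual_pos, sol$fk_residual_rot, tool,
                        diagnostics = list(slsqp_value = res$value,
                                           slsqp_iter = res$iter,
                                           limits = lim,
                                           max_utilization = max(lim$utilization)))
  # descent guard: when refining for the same tool frame from a feasible
  # start, never return something worse than the warm start
  same_tool <- max(abs(rt_as_matrix(tool) - rt_as_matrix(initial$tool))) < 1e-12
  if (same_tool && isTRUE(initial$feasible)) {
    q0d <- diff(initial$joint_trajectory$q) / dt
    obj0 <- sum(sweep(q0d, 2, vmax, "/")^2)
    if (!feas || objective > obj0 + 1e-12) {
      out <- initial
      out$objective <- obj0
      out$diagnostics$refinement <- "kept warm start (no improvement found)"
    }
  }
  out
}

#' Generate virtual humeral tool frames
#'
#' Starting from the physically digitized tool frame, generates the full
#' sweep of 36 frames (the physical frame plus 35 virtual ones): rotations
#' of the humerus about its long axis in 30 degree increments (12 per clamp
#' position) at 3 clamp positions along the shaft — about 1 inch distal to
#' the humeral head, midshaft, and about 1 inch proximal to the epicondyle
#' midpoint. The physical frame is the 0-degree rotation at the as-clamped
#' position.
#'
#' @param physical [rt()] the digitized `EE_T_H`.
#' @param humeral_length head-to-epicondyle-midpoint distance (m, default 0.30).
#' @param clamp_as which clamp position the physical frame corresponds to
#'   (`"proximal"`, `"midshaft"`, `"distal"`).
#' @return list of 36 [rt()] frames, the first being `physical`.
#' @export
generate_virtual_tool_frames <- function(physical, humeral_length = 0.30,
                                         clamp_as = c("midshaft", "proximal", "distal")) {
  clamp_as <- match.arg(clamp_as)
  inch <- 0.0254
  # humeral frame: origin at head center, superior +Y, shaft towards -Y
  offsets <- c(proximal = -inch, midshaft = -humeral_length / 2,
               distal = -(humeral_length - inch))
  base_off <- offsets[[clamp_as]]
  frames <- list()
  for (pos in names(offsets)) {
    delta <- offsets[[pos]] - base_off
    for (ang in seq(0, 330, by = 30) * pi / 180) {
      Tloc <- rt(rotation_about_axis(c(0, 1, 0), ang), c(0, delta, 0),
                 validate = FALSE)
      frames[[length(frames) + 1]] <- rt_compose(physical, Tloc, validate = FALSE)
    }
  }
  # put the physical frame (as-clamped, 0 deg) first
  k <- which(names(offsets) == clamp_as)
  first <- (k - 1) * 12 + 1
  frames[c(first, setdiff(seq_along(frames), first))]
}
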