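pose_deviation <- function(traj, i1, i2, js, rho = 0.3) {
  # combined deviation of interior points js from the pose interpolated
  # between kept points i1 and i2: ||dp|| + rho * angle(dR)
  p1 <- traj$poses[[i1]]; p2 <- traj$poses[[i2]]
  t1 <- traj$time[i1]; t2 <- traj$time[i2]
  rel <- rotmat_to_rotvec(p2$R %*% t(p1$R))
  vapply(js, function(j) {
    u <- (traj$time[j] - t1) / (t2 - t1)
    p_int <- (1 - u) * p1$t + u * p2$t
    R_int <- rotvec_to_rotmat(u * rel) %*% p1$R
    pj <- traj$poses[[j]]
    sqrt(sum((pj$t - p_int)^2)) + rho * rotation_angle(pj$R, R_int)
  }, numeric(1))
}

#' Pose-aware non-uniform subsampling
#'
#' Selects `round(keep_fraction * N)` waypoint indices (always including the
#' first and last) by greedy farthest-point refinement: starting from the
#' endpoints, repeatedly keep the point whose combined pose deviation
#' `||dp|| + rho * angle(dR)` from the piecewise-interpolated kept path is
#' largest. This greedily minimizes the maximum deviation of the discarded
#' points, concentrating waypoints where the trajectory curves in position
#' or orientation, and never does worse (in max deviation) than uniform
#' subsampling at the same count. At 200 Hz, keeping 20% yields waypoints
#' spaced 25 ms apart on average.
#'
#' @param traj a `pose_trajectory` (>= 3 timepoints).
#' @param keep_fraction fraction of points to keep, `0 < f <= 1`.
#' @param rho orientation weight (m/rad, default 0.3: a characteristic
#'   humeral length converting radians to meters).
#' @return sorted integer vector of kept indices.
#' @export
nonuniform_subsample <- function(traj, keep_fraction, rho = 0.3) {
  N <- length(traj$poses)
  if (N < 3L) stop("need at least 3 timepoints")
  m <- round(keep_fraction * N)
  if (m < 2) stop("keep_fraction * N must be at least 2")
  if (m >= N) return(seq_len(N))
  kept <- c(1L, N)
  # per-segment worst offender: (index of worst interior point, deviation)
  seg_max <- function(i1, i2) {
    js <- if (i2 - i1 > 1L) (i1 + 1L):(i2 - 1L) else integer(0)
    if (!length(js)) return(c(NA_integer_, -Inf))
    d <- pose_deviation(traj, i1, i2, js, rho)
    k <- which.max(d)
    c(js[k], d[k])
  }
  segs <- list(c(1L, N))
  worst <- list(seg_max(1L, N))
  eps <- 1e-12
  while (length(kept) < m) {
    devs <- vapply(worst, `[`, numeric(1), 2)
    s <- which.max(devs)
    if (!is.finite(devs[s])) break
    if (devs[s] < eps) {
      # all remaining deviation is numerically zero: split the longest
      # segment at its midpoint (keeps straight stretches near-uniform)
      lens <- vapply(segs, function(sg) sg[2] - sg[1], numeric(1))
      s <- which.max(lens)
      if (lens[s] < 2) break
      j <- as.integer(floor(mean(segs[[s]])))
    } else {
      j <- as.integer(worst[[s]][1])
    }
    kept <- c(kept, j)
    i1 <- segs[[s]][1]; i2 <- segs[[s]][2]
    segs[[s]] <- c(i1, j); worst[[s]] <- seg_max(i1, j)
    segs[[length(segs) + 1]] <- c(j, i2)
    worst[[length(worst) + 1]] <- seg_max(j, i2)
  }
  kept <- sort(unique(kept))
  # greedy refinement is a heuristic; guarantee the contract that it never
  # does worse (in max combined deviation) than uniform subsampling
  uniform <- sort(unique(round(seq(1, N, length.out = m))))
  if (length(uniform) == length(kept) &&
      subsample_max_deviation(traj, uniform, rho) <=
      subsample_max_deviation(traj, kept, rho)) kept <- uniform
  kept
}

#' Maximum combined pose deviation of a subsampled path
#'
#' The largest `||dp|| + rho * angle(dR)` deviation of any discarded point
#' from the pose path interpolated between the kept indices.
#'
#' @param traj a `pose_trajectory`.
#' @param idx sorted kept indices including the endpoints.
#' @param rho orientation weight (m/rad).
#' @return deviation (m).
#' @export
subsample_max_deviation <- function(traj, idx, rho = 0.3) {
  worst <- 0
  for (s in seq_len(length(idx) - 1)) {
    i1 <- idx[s]; i2 <- idx[s + 1]
    if (i2 - i1 > 1)
      worst <- max(worst, max(pose_deviation(traj, i1, i2,
                                             (i1 + 1):(i2 - 1), rho)))
  }
  worst
}

#' Motion program container
#'
#' An ordered list of joint-space waypoints with per-segment maximum linear
#' speed (mm/s, assigned to the segment arriving at each waypoint) and a
#' per-waypoint smoothness (blend) value in 0-100, mirroring how industrial
#' controllers are programmed: 0 requests exact positioning at the
#' waypoint, 100 maximal corner blending.
#'
#' @param q n x 6 matrix of waypoint joint angles (rad), n >= 2.
#' @param time waypoint timestamps (s) from the source trajectory.
#' @param speed length-n vector, segment speed into each waypoint (mm/s;
#'   first entry unused, kept for alignment); all > 0.
#' @param smoothness per-waypoint blend value in `[0, 100]`.
#' @param rate native rate metadata (Hz) of the source trajectory.
#' @return object of class `motion_program`.
#' @export
motion_program <- function(q, time, speed, smoothness, rate) {
  q <- as.matrix(q)
  n <- nrow(q)
  if (n < 2L) stop("need at least 2 waypoints")
  if (any(speed[-1] <= 0)) stop("speeds must be positive")
  if (any(smoothness < 0 | smoothness > 100)) stop("smoothness must be in [0, 100]")
  structure(list(q = q, time = as.numeric(time), speed = as.numeric(speed),
                 smoothness = as.numeric(smoothness), rate = rate),
            class = "motion_program")
}

#' @export
print.motion_program <- function(x, ...) {
  cat(sprintf("<motion program: %d waypoints, %.2f s, speeds %.0f-%.0f mm/s>\n",
              nrow(x$q), max(x$time) - min(x$time),
              min(x$speed[-1]), max(x$speed[-1])))
  invisible(x)
}

#' Emit a motion program from a joint trajectory
#'
#' Retains the waypoints selected by [nonuniform_subsample()] (or any sorted
#' index set) and computes per-segment speeds as Cartesian tool-point
#' distance over the time delta between the retained timepoints.
#'
#' @param jt a `joint_trajectory` (dense, one row per source timepoint).
#' @param robot a `robot_model` (for waypoint Cartesian positions).
#' @param indices sorted waypoint indices into `jt`.
#' @param tool optional [rt()] tool frame; speeds are computed at the tool
#'   point when given, at the flange otherwise.
#' @param smoothness scalar or per-waypoint blend value (default 100).
#' @return [motion_program()].
#' @export
emit_motion_program <- function(jt, robot, indices, tool = NULL,
                                smoothness = 100) {
  indices <- sort(unique(as.integer(indices)))
  q <- jt$q[indices, , drop = FALSE]
  tm <- jt$time[indices]
  if (any(diff(tm) <= 0)) stop("zero or negative time delta between waypoints")
  pos <- t(vapply(seq_len(nrow(q)), function(k) {
    p <- forward_kinematics(robot, q[k, ])
    if (!is.null(tool)) p <- rt_compose(p, tool, validate = FALSE)
    p$t
  }, numeric(3)))
  dist <- sqrt(rowSums(diff(pos)^2))
  speed <- c(NA_real_, pmax(dist / diff(tm), 1e-9) * 1000)  # mm/s
  if (length(smoothness) == 1L) smoothness <- rep(smoothness, nrow(q))
  motion_program(q, tm, speed, smoothness, rate = jt$rate)
}

#' Motion program text format
#'
#' Line-oriented dialect standing in for vendor formats: a header line
#' `HUMREP-PROGRAM v1 rate=<Hz>` followed by one waypoint per line:
#' `index j1..j6 (degrees) time_s speed_mm_s smoothness`. Values are
#' written at full precision so that `parse_motion_program(format_motion_program(p))`
#' round-trips losslessly.
#'
#' @param prog a [motion_program()].
#' @return `format_motion_program`: character vector of program lines.
#' @export
format_motion_program <- function(prog) {
  hdr <- sprintf("HUMREP-PROGRAM v1 rate=%.15g", prog$rate)
  lines <- vapply(seq_len(nrow(prog$q)), function(k) {
    paste(c(sprintf("%d", k),
            sprintf("%.15g", prog$q[k, ] * 180 / pi),
            sprintf("%.15g", prog$time[k]),
            sprintf("%.15g", if (k == 1) 0 else prog$speed[k]),
            sprintf("%.15g", prog$smoothness[k])), collapse = " ")
  }, character(1))
  c(hdr, lines)
}

#' @rdname format_motion_program
#' @param lines character vector (or path via `readLines`) of program text.
#' @export
parse_motion_program <- function(lines) {
  if (length(lines) < 3L) stop("program must have a header and >= 2 waypoints")
  hdr <- strsplit(lines[1], " +")[[1]]
  if (hdr[1] != "HUMREP-PROGRAM") stop("not a humrep motion program")
  rate <- as.numeric(sub("rate=", "", hdr[3]))
  vals <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  q <- vals[, 2:7, drop = FALSE] * pi / 180
  speed <- vals[, 9]
  speed[1] <- NA_real_
  motion_program(q, time = vals[, 8], speed = speed,
                 smoothness = vals[, 10], rate = rate)
}

#' Simulate program execution on a virtual controller
#'
#' Deliberately simple stand-in for the physical robot + optical tracker so
#' the comparison pipeline can be exercised end-to-end (no vendor look-ahead
#' modeling). Joint-space motion is piecewise linear between waypoints with
#' parabolic corner blends: segment durations are the programmed time
#' deltas, stretched whenever the programmed speed exceeds a joint velocity
#' limit (the robot saturates and arrives late); the blend window at an
#' interior waypoint is `smoothness/100 * min(adjacent segment durations)/2`.
#' With smoothness 0 the robot passes through every waypoint exactly. An
#' optional first-order lag (time constant `lag`, s) emulates controller
#' tracking dynamics. The achieved trajectory is resampled at `rate`.
#'
#' @param prog a [motion_program()].
#' @param robot a `robot_model`.
#' @param tool optional [rt()] tool frame; achieved poses are of the tool
#'   body when given.
#' @param controller list: `rate` (Hz, default 200), `lag` (s, default 0).
#' @return list with `joint_trajectory` and `pose_trajectory` achieved.
#' @export
simulate_execution <- function(prog, robot, tool = NULL,
                               controller = list()) {
  ctl <- utils::modifyList(list(rate = 200, lag = 0), controller)
  q <- prog$q
  n <- nrow(q)
  lim <- check_limits_static(robot, q)
  if (!lim) stop("program contains an unreachable (out-of-limit) waypoint")
  # segment durations: programmed delta, stretched by joint-speed saturation
  Tseg <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    Tprog <- prog$time[k + 1] - prog$time[k]
    Tjoint <- max(abs(q[k + 1, ] - q[k, ]) / robot$velocity_limits)
    Tseg[k] <- max(Tprog, Tjoint)
  }
  t_wp <- cumsum(c(0, Tseg))
  total <- t_wp[n]
  dt <- 1 / ctl$rate
  ts <- seq(0, total, by = dt)
  if (ts[length(ts)] < total - 1e-12) ts <- c(ts, total)
  # blend windows
  tau <- numeric(n)
  if (n > 2) for (k in 2:(n - 1))
    tau[k] <- prog$smoothness[k] / 100 * min(Tseg[k - 1], Tseg[k]) / 2
  vseg <- diff(q) / Tseg  # per-joint segment velocities
  qs <- matrix(0, length(ts), 6)
  for (si in seq_along(ts)) {
    tt <- ts[si]
    k <- min(max(findInterval(tt, t_wp, rightmost.closed = TRUE), 1L), n - 1L)
    qlin <- q[k, ] + vseg[k, ] * (tt - t_wp[k])
    # inside a blend window of waypoint k or k+1?
    for (w in c(k, k + 1L)) {
      if (w > 1 && w < n && tau[w] > 0 && abs(tt - t_wp[w]) <= tau[w]) {
        h <- tt - (t_wp[w] - tau[w])
        if (h >= 0 && h <= 2 * tau[w]) {
          qlin <- q[w, ] + vseg[w - 1, ] * (tt - t_wp[w]) +
            (vseg[w, ] - vseg[w - 1, ]) * h^2 / (4 * tau[w])
          break
        }
      }
    }
    qs[si, ] <- qlin
  }
  if (ctl$lag > 0) {
    # settle at the final waypoint so the filter converges, then trim
    settle <- ceiling(6 * ctl$lag / dt)
    qs <- rbind(qs, matrix(qs[nrow(qs), ], settle, 6, byrow = TRUE))
    a <- 1 - exp(-dt / ctl$lag)
    for (si in 2:nrow(qs)) qs[si, ] <- qs[si - 1, ] + a * (qs[si, ] - qs[si - 1, ])
  }
  jt <- joint_trajectory(qs, rate = ctl$rate)
  poses <- lapply(seq_len(nrow(qs)), function(si) {
    p <- forward_kinematics(robot, qs[si, ])
    if (!is.null(tool)) p <- rt_compose(p, tool, validate = FALSE)
    p
  })
  pt <- pose_trajectory(poses, rate = ctl$rate, source_frame = "R",
                        body_frame = if (is.null(tool)) "EE" else "H",
                        validate = FALSE)
  list(joint_trajectory = jt, pose_trajectory = pt)
}

check_limits_static <- function(robot, q) {
  all(sweep(q, 2, robot$joint_limits[, 1], ">=") &
      sweep(q, 2, robot$joint_limits[, 2], "<="))
}
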