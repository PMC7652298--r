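#' Pose trajectory container
#'
#' A time-stamped sequence of rigid transforms sampled at a uniform rate,
#' with labels naming the frame the poses are expressed in (`source_frame`)
#' and the moving body (`body_frame`).
#'
#' @param poses list of [rt()] objects (>= 2 unless `allow_single`).
#' @param rate sampling rate (Hz).
#' @param time optional timestamps (s); defaults to `(0:(n-1))/rate`.
#' @param source_frame,body_frame frame labels.
#' @param validate check pose validity and sampling uniformity?
#' @return object of class `pose_trajectory`.
#' @export
pose_trajectory <- function(poses, rate, time = NULL,
                            source_frame = "MC", body_frame = "H",
                            validate = TRUE) {
  n <- length(poses)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  if (validate) {
    if (n < 2L) stop("a pose trajectory needs at least 2 timepoints")
    lapply(poses, rt_validate)
    if (n > 1L && max(abs(diff(time) - 1 / rate)) > 1e-9)
      stop("timestamps are not uniform at the stated rate")
  }
  structure(list(poses = poses, rate = rate, time = time,
                 source_frame = source_frame, body_frame = body_frame),
            class = "pose_trajectory")
}

#' @export
print.pose_trajectory <- function(x, ...) {
  cat(sprintf("<pose trajectory: %s in %s, %d timepoints @ %g Hz (%.3f s)>\n",
              x$body_frame, x$source_frame, length(x$poses), x$rate,
              max(x$time) - min(x$time)))
  invisible(x)
}

#' @export
length.pose_trajectory <- function(x) length(x$poses)

#' Translations of a pose trajectory as an n x 3 matrix
#' @param traj a `pose_trajectory`.
#' @return n x 3 matrix (m).
#' @export
pt_translations <- function(traj) {
  do.call(rbind, lapply(traj$poses, function(p) p$t))
}

#' Rotation vectors of a pose trajectory
#'
#' Converts every pose to the rotation-vector formulation and (optionally)
#' unwraps for continuity so consecutive samples differ by less than pi.
#'
#' @param traj a `pose_trajectory`.
#' @param unwrap apply [unwrap_rotvecs()]?
#' @return n x 3 matrix (rad).
#' @export
pt_rotvecs <- function(traj, unwrap = TRUE) {
  v <- do.call(rbind, lapply(traj$poses, function(p) rotmat_to_rotvec(p$R)))
  if (unwrap) v <- unwrap_rotvecs(v)
  v
}

#' Subset a pose trajectory by index
#' @param traj a `pose_trajectory`.
#' @param idx integer indices (sorted).
#' @param rate rate of the result; if the indices are non-uniform the result
#'   keeps the original timestamps and `validate = FALSE` semantics.
#' @return `pose_trajectory`.
#' @export
pt_subset <- function(traj, idx, rate = NULL) {
  time <- traj$time[idx]
  uniform <- length(idx) > 1 && diff(range(diff(time))) < 1e-9
  if (is.null(rate)) rate <- if (uniform) 1 / mean(diff(time)) else traj$rate
  pose_trajectory(traj$poses[idx], rate = rate, time = time,
                  source_frame = traj$source_frame,
                  body_frame = traj$body_frame, validate = FALSE)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order (by default) Butterworth filter applied forwards and
#' backwards (zero phase) with reflection padding to suppress edge
#' transients. DC content is preserved. The squared magnitude response of
#' the bidirectional pass is `1 / (1 + (f/fc)^(2*order))^2`.
#'
#' @param x numeric vector or matrix (columns are channels).
#' @param rate sampling rate (Hz); must exceed `2 * cutoff`.
#' @param cutoff cutoff frequency (Hz).
#' @param order filter order (default 4).
#' @param bidirectional zero-phase two-pass filtering (default TRUE).
#' @return filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, rate, cutoff, order = 4, bidirectional = TRUE) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  b <- as.numeric(bf$b); a <- as.numeric(bf$a)
  zi <- lfilter_zi(b, a)
  filt1 <- function(v) {
    n <- length(v)
    npad <- min(n - 1L, 3L * (length(a) + 1L))
    pre <- 2 * v[1] - v[seq(npad + 1, 2)]
    post <- 2 * v[n] - v[seq(n - 1, n - npad)]
    vv <- c(pre, v, post)
    y <- iir_filter(b, a, vv, zi * vv[1])
    if (bidirectional) {
      yr <- rev(y)
      y <- rev(iir_filter(b, a, yr, zi * yr[1]))
    }
    y[seq(npad + 1, npad + n)]
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}

# steady-state initial filter state (unit-step response fixed point)
lfilter_zi <- function(b, a) {
  n <- length(a)
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -a[-1] / a[1]
  if (n > 2) A[cbind(1:(n - 2), 2:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - A, B)
}

# transposed direct-form II IIR filter with initial state zi
iir_filter <- function(b, a, x, zi) {
  nz <- length(a) - 1L
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1) for (j in seq_len(nz - 1)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nz] <- b[nz + 1] * xi - a[nz + 1] * yi
    y[i] <- yi
  }
  y
}

central_diff <- function(x, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, ncol(x))
  if (n >= 3) d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] -
                                 x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d
}

#' Differentiate a pose trajectory
#'
#' Positions and unwrapped rotation-vector components are (optionally)
#' smoothed with a bidirectional Butterworth filter, then differentiated by
#' central differences at the native rate; a second differentiation yields
#' accelerations. Angular velocity here is the rotation-vector rate, which
#' for the smooth trajectories in scope agrees with body angular velocity to
#' second order (inverse dynamics uses the exact map, see [rnea_loads()]).
#'
#' @param traj a `pose_trajectory` (>= 5 timepoints).
#' @param cutoff low-pass cutoff (Hz), or `NULL` for no filtering.
#' @param order Butterworth order (default 4).
#' @return object of class `kinematic_derivatives`: matrices
#'   `linear_velocity` (m/s), `angular_velocity` (rad/s),
#'   `linear_acceleration` (m/s^2), `angular_acceleration` (rad/s^2),
#'   the filtered `position` and `rotvec` series, and per-timepoint
#'   Euclidean `magnitudes`.
#' @export
derive_kinematics <- function(traj, cutoff = 8, order = 4) {
  n <- length(traj$poses)
  if (n < 5L) stop("need at least 5 timepoints to differentiate")
  dt <- 1 / traj$rate
  p <- pt_translations(traj)
  r <- pt_rotvecs(traj, unwrap = TRUE)
  if (max(sqrt(rowSums(diff(r)^2))) > pi)
    stop("rotation-vector discontinuity exceeds pi after unwrapping")
  if (!is.null(cutoff)) {
    p <- lowpass_filter(p, traj$rate, cutoff, order)
    r <- lowpass_filter(r, traj$rate, cutoff, order)
  }
  lv <- central_diff(p, dt); av <- central_diff(r, dt)
  la <- central_diff(lv, dt); aa <- central_diff(av, dt)
  structure(list(
    time = traj$time, rate = traj$rate,
    position = p, rotvec = r,
    linear_velocity = lv, angular_velocity = av,
    linear_acceleration = la, angular_acceleration = aa,
    magnitudes = list(
      linear_velocity = sqrt(rowSums(lv^2)),
      angular_velocity = sqrt(rowSums(av^2)),
      linear_acceleration = sqrt(rowSums(la^2)),
      angular_acceleration = sqrt(rowSums(aa^2)))),
    class = "kinematic_derivatives")
}

#' Constant-jerk ramp segment
#'
#' Builds an artificial ramp-up (rest to junction) or slow-down (junction to
#' rest) segment as a quartic polynomial per component — position axes and
#' rotation-vector axes relative to the junction orientation — satisfying
#' five boundary conditions: zero velocity and acceleration at the rest end,
#' and matching position, velocity, and acceleration at the junction. The
#' default 30 points at 200 Hz give a 0.15 s ramp.
#'
#' @param junction_pose [rt()] pose at the junction.
#' @param junction_velocity list with `linear` (m/s) and `angular` (rad/s,
#'   rotation-vector rate) 3-vectors.
#' @param junction_acceleration list with `linear` and `angular` 3-vectors.
#' @param n_points number of ramp timepoints (>= 2; default 30).
#' @param rate sampling rate (Hz, default 200).
#' @param direction `"ramp-up"` (ends at the junction) or `"slow-down"`.
#' @return `pose_trajectory` segment of `n_points` samples; for ramp-up the
#'   last sample is one step before the junction (concatenate with the
#'   trajectory to obtain a C1-continuous whole).
#' @export
constant_jerk_ramp <- function(junction_pose, junction_velocity,
                               junction_acceleration, n_points = 30,
                               rate = 200, direction = c("ramp-up", "slow-down")) {
  direction <- match.arg(direction)
  if (n_points < 2) stop("need at least 2 ramp points")
  rt_validate(junction_pose)
  Tdur <- n_points / rate
  # quartic x(s) on [0, T]: x'(0)=x''(0)=0; x(T)=xj, x'(T)=vj, x''(T)=aj
  quartic <- function(xj, vj, aj) {
    # x(s) = c0 + c3 s^3 + c4 s^4  (c1 = c2 = 0 from rest-end conditions)
    A <- rbind(c(1, Tdur^3, Tdur^4),
               c(0, 3 * Tdur^2, 4 * Tdur^3),
               c(0, 6 * Tdur, 12 * Tdur^2))
    solve(A, c(xj, vj, aj))
  }
  eval_q <- function(cf, s) cf[1] + cf[2] * s^3 + cf[3] * s^4
  cp <- lapply(1:3, function(i) quartic(junction_pose$t[i],
                                        junction_velocity$linear[i],
                                        junction_acceleration$linear[i]))
  cr <- lapply(1:3, function(i) quartic(0, junction_velocity$angular[i],
                                        junction_acceleration$angular[i]))
  s <- if (direction == "ramp-up") (seq_len(n_points) - 1) / rate
       else Tdur - seq_len(n_points) / rate  # time-reversed quartic, junction to rest
  poses <- lapply(s, function(si) {
    p <- vapply(cp, eval_q, numeric(1), s = si)
    rv <- vapply(cr, eval_q, numeric(1), s = si)
    rt(rotvec_to_rotmat(rv) %*% junction_pose$R, p, validate = FALSE)
  })
  pose_trajectory(poses, rate = rate, validate = FALSE)
}

#' Normalize a trajectory to its first waypoint
#'
#' Subtracts the first translation from every translation (rotations are
#' untouched), so the first waypoint sits at the origin. Velocities and
#' accelerations — hence the kinetics — are unchanged.
#'
#' @param traj a `pose_trajectory`.
#' @return normalized `pose_trajectory`.
#' @export
normalize_to_first_waypoint <- function(traj) {
  t0 <- traj$poses[[1]]$t
  traj$poses <- lapply(traj$poses, function(p) rt(p$R, p$t - t0, validate = FALSE))
  traj
}

#' Read/write pose trajectory CSV
#'
#' Schema: header row; columns `time_s`, `r11..r33` (row-major rotation),
#' `tx_m`, `ty_m`, `tz_m`; one row per timepoint; UTF-8; '.' decimal.
#' The reader validates orthonormality to 1e-6 and re-orthonormalizes via
#' polar decomposition when within tolerance.
#'
#' @param file path to a CSV file.
#' @param source_frame,body_frame frame labels for the result.
#' @return [pose_trajectory()].
#' @export
read_pose_trajectory <- function(file, source_frame = "MC", body_frame = "H") {
  d <- utils::read.csv(file)
  need <- c("time_s", "r11", "r12", "r13", "r21", "r22", "r23",
            "r31", "r32", "r33", "tx_m", "ty_m", "tz_m")
  if (!all(need %in% names(d))) stop("missing columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  poses <- lapply(seq_len(nrow(d)), function(k) {
    R <- matrix(as.numeric(d[k, c("r11", "r12", "r13", "r21", "r22", "r23",
                                  "r31", "r32", "r33")]), 3, 3, byrow = TRUE)
    rt(orthonormalize(R, tol = 1e-6),
       as.numeric(d[k, c("tx_m", "ty_m", "tz_m")]), validate = FALSE)
  })
  dt <- diff(d$time_s)
  rate <- 1 / stats::median(dt)
  pose_trajectory(poses, rate = rate, time = d$time_s,
                  source_frame = source_frame, body_frame = body_frame,
                  validate = FALSE)
}

#' @rdname read_pose_trajectory
#' @param traj a `pose_trajectory` to write.
#' @export
write_pose_trajectory <- function(traj, file) {
  rows <- lapply(seq_along(traj$poses), function(k) {
    p <- traj$poses[[k]]
    c(traj$time[k], as.numeric(t(p$R)), p$t)
  })
  d <- as.data.frame(do.call(rbind, rows))
  names(d) <- c("time_s", "r11", "r12", "r13", "r21", "r22", "r23",
                "r31", "r32", "r33", "tx_m", "ty_m", "tz_m")
  utils::write.csv(format(d, digits = 15, trim = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}
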