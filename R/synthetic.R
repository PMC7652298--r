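with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

activity_defaults <- function(activity) {
  # per-axis position amplitudes (m), orientation amplitudes (rad),
  # frequencies (Hz), duration (s). Axes are (X anterior, Y lateral-ish,
  # Z vertical) of the MC frame; archetypes emulate the activities'
  # characteristic spans and speeds: jumping jacks are large-elevation
  # oscillations in a compact volume; jogging combines a long anterior
  # excursion with oscillation; jug lifts are slow large bending-plane
  # rotations; internal rotation is fast axial rotation with little
  # translation.
  switch(activity,
    jumping_jack = list(duration = 4, pos_amp = c(0.05, 0.04, 0.12),
                        pos_freq = c(1.0, 1.0, 1.0),
                        rot_amp = c(1.1, 0.15, 0.2), rot_freq = c(0.5, 1.0, 0.5),
                        drift = c(0, 0, 0)),
    jogging = list(duration = 2, pos_amp = c(0.06, 0.05, 0.08),
                   pos_freq = c(1.4, 1.4, 2.8),
                   rot_amp = c(0.45, 0.12, 0.1), rot_freq = c(1.3, 1.3, 1.3),
                   drift = c(0.9, 0, 0)),
    jug_lift = list(duration = 8, pos_amp = c(0.12, 0.03, 0.15),
                    pos_freq = c(0.06, 0.06, 0.06),
                    rot_amp = c(0.60, 0.05, 0.04), rot_freq = c(0.06, 0.06, 0.06),
                    drift = c(0, 0, 0)),
    internal_rotation = list(duration = 2, pos_amp = c(0.006, 0.006, 0.004),
                             pos_freq = c(1.0, 1.0, 1.0),
                             rot_amp = c(0.07, 0.05, 1.0),
                             rot_freq = c(1.0, 1.0, 1.0),
                             drift = c(0, 0, 0)))
}

#' Generate a synthetic activity-archetype humeral trajectory
#'
#' C-infinity smooth pose trajectories built from sums of low-frequency
#' sinusoids with activity-appropriate per-axis position and orientation
#' amplitudes, emulating the four advanced-activities-of-daily-living
#' archetypes: `jumping_jack` (large elevation oscillation, compact
#' translation), `jogging` (long anterior translation plus oscillation),
#' `jug_lift` (slow large bending-plane rotation; peak angular speed stays
#' below 30 deg/s at defaults), `internal_rotation` (fast axial rotation,
#' millimetre-scale translation). Deterministic given `seed` (random
#' phases and mild amplitude jitter).
#'
#' @param activity archetype name.
#' @param duration trial duration (s); default per activity.
#' @param rate sampling rate (Hz, default 200).
#' @param seed integer seed.
#' @param position_scale,orientation_scale multiplicative overrides of the
#'   default amplitudes (useful for desk-scale optimization tests).
#' @return list with `trajectory` (`pose_trajectory` in the MC frame) and
#'   `thorax_pose` ([rt()] initial thorax pose in the MC frame).
#' @export
generate_activity <- function(activity = c("jumping_jack", "jogging",
                                           "jug_lift", "internal_rotation"),
                              duration = NULL, rate = 200, seed = 1,
                              position_scale = 1, orientation_scale = 1) {
  activity <- match.arg(activity)
  par <- activity_defaults(activity)
  if (is.null(duration)) duration <- par$duration
  with_local_seed(seed, {
    n <- round(duration * rate) + 1
    tt <- (seq_len(n) - 1) / rate
    jig <- function() stats::runif(1, 0.9, 1.1)
    ph <- function() stats::runif(1, 0, 2 * pi)
    chan <- function(amp, freq, drift = 0) {
      a1 <- amp * jig(); f1 <- freq * jig(); p1 <- ph()
      # half-amplitude first harmonic keeps the signal smooth but non-trivial
      a1 * sin(2 * pi * f1 * tt + p1) +
        0.25 * a1 * sin(2 * pi * 2 * f1 * tt + ph()) +
        drift * (tt / max(tt) - 0.5)
    }
    pos <- sapply(1:3, function(i) chan(par$pos_amp[i], par$pos_freq[i],
                                        par$drift[i]))
    rot <- sapply(1:3, function(i) chan(par$rot_amp[i], par$rot_freq[i]))
    pos <- sweep(pos, 2, pos[1, ]) # start near the origin
    pos <- pos * position_scale
    rot <- rot * orientation_scale
    # humerus hangs below a shoulder sitting ~1.4 m up
    base_t <- c(0, 0, 1.4)
    poses <- lapply(seq_len(n), function(k)
      rt(rotvec_to_rotmat(rot[k, ]), base_t + pos[k, ], validate = FALSE))
    thorax <- rt(rotvec_to_rotmat(c(0, 0, stats::runif(1, -0.2, 0.2))),
                 base_t + c(-0.05, -0.15, 0.1))
    list(trajectory = pose_trajectory(poses, rate = rate, source_frame = "MC",
                                      body_frame = "H", validate = FALSE),
         thorax_pose = thorax)
  })
}

#' Add optical-tracker noise
#'
#' Emulates tracker measurement noise at the marker level: each pose is
#' re-estimated by least squares (Kabsch/Procrustes) from a virtual marker
#' constellation of radius `constellation_radius` whose world positions are
#' perturbed by isotropic Gaussian noise of SD `sigma` (the tracker's
#' position accuracy, ~0.1 mm). Orientation noise therefore scales as
#' `sigma / constellation_radius`.
#'
#' @param traj a `pose_trajectory`.
#' @param sigma marker position noise SD (m), >= 0.
#' @param seed integer seed.
#' @param constellation_radius virtual rigid-body radius (m, default 0.05).
#' @param n_markers markers in the constellation (default 8).
#' @return noisy `pose_trajectory`.
#' @export
add_optical_noise <- function(traj, sigma, seed = 1,
                              constellation_radius = 0.05, n_markers = 8) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(traj)
  with_local_seed(seed, {
    mk <- marker_constellation(n_markers, constellation_radius)
    traj$poses <- lapply(traj$poses, function(p) {
      world <- rt_apply(p, mk)
      noisy <- world + matrix(stats::rnorm(length(world), 0, sigma),
                              ncol = 3)
      kabsch_fit(mk, noisy)
    })
    traj
  })
}

marker_constellation <- function(n, radius) {
  # quasi-uniform points on a sphere (golden spiral), fixed per (n, radius)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

kabsch_fit <- function(local, world) {
  cl <- colMeans(local); cw <- colMeans(world)
  H <- t(sweep(local, 2, cl)) %*% sweep(world, 2, cw)
  s <- svd(H)
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  rt(R, as.numeric(cw - R %*% cl), validate = FALSE)
}

#' Add isotropic Gaussian noise to points
#' @param points n x 3 matrix (m).
#' @param sigma noise SD (m).
#' @param seed integer seed.
#' @return noisy matrix.
#' @export
add_point_noise <- function(points, sigma, seed = 1) {
  with_local_seed(seed,
    points + matrix(stats::rnorm(length(points), 0, sigma), ncol = 3))
}

#' Synthetic calibration fixture
#'
#' Constructs a [calibration_set()] from known ground-truth transforms:
#' robot poses with rotation axes spanning 3D (exact, per controller
#' repeatability), and tracked poses derived from the ground truth with
#' optional marker-level tracker noise ([add_optical_noise()] model).
#' `A_i X = Z B_i` with `X` the end-effector-to-rigid-body transform and
#' `Z` the (full) robot-to-tracker embedding whose rotation is `R_OT`.
#'
#' @param true_R_OT 3x3 ground-truth tracker-to-robot rotation.
#' @param true_EE_T_HS [rt()] ground-truth end-effector-to-rigid-body.
#' @param n_poses number of pose pairs (>= 3, default 20).
#' @param seed integer seed.
#' @param noise_sigma marker-level tracker noise SD (m, default 0).
#' @param constellation_radius virtual rigid-body radius (m, default 0.05).
#' @return [calibration_set()].
#' @export
make_calibration_fixture <- function(true_R_OT, true_EE_T_HS, n_poses = 20,
                                     seed = 1, noise_sigma = 0,
                                     constellation_radius = 0.05) {
  if (n_poses < 3) stop("need at least 3 poses")
  with_local_seed(seed, {
    t_OT <- c(1.5, 0.5, 0.2)  # arbitrary tracker origin; discarded by design
    Z <- rt(true_R_OT, t_OT)
    Zi <- rt_invert(Z)
    robot_poses <- lapply(seq_len(n_poses), function(i) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- stats::runif(1, 0.4, 2.4)
      rt(rotation_about_axis(ax, th),
         c(stats::runif(1, 0.6, 1.1), stats::runif(1, -0.4, 0.4),
           stats::runif(1, 0.3, 0.9)))
    })
    tracked <- lapply(robot_poses, function(A)
      rt_compose(Zi, rt_compose(A, true_EE_T_HS, validate = FALSE),
                 validate = FALSE))
    if (noise_sigma > 0) {
      mk <- marker_constellation(8, constellation_radius)
      tracked <- lapply(tracked, function(B) {
        world <- rt_apply(B, mk)
        noisy <- world + matrix(stats::rnorm(length(world), 0, noise_sigma),
                                ncol = 3)
        kabsch_fit(mk, noisy)
      })
    }
    calibration_set(robot_poses, tracked)
  })
}
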