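#' Cylinder-segment prosthesis model
#'
#' Rigid chain of uniform solid cylinders representing a transhumeral
#' osseointegrated prosthesis system at the 25% amputation level: the
#' prosthetic connection from the residual bone to the elbow, the forearm,
#' the hand, and (for jug-lift activities) a filled jug. Segment geometry
#' and masses:
#'
#' | segment | length (m) | diameter (m) | mass (kg) |
#' |---|---|---|---|
#' | arm connection | 0.75 x arm length | 0.060 | 0.50823 x 0.75 x arm length + 0.3 |
#' | forearm | 0.2540 | 0.0762 | 1.013 |
#' | hand | 0.1524 | 0.0540 | 0.416 |
#' | jug | 0.2500 | 0.1500 | 3.800 |
#'
#' The elbow is fixed per activity: 90 degrees flexion for jogging and
#' internal rotation, 135 for jumping jacks, 180 (full extension) for jug
#' lifts — so the whole chain moves rigidly with the humerus. Geometry
#' convention (humeral frame: origin at the glenohumeral center, +Y
#' superior, shaft towards -Y, +X anterior): the interface cross-section
#' sits at 25% of arm length below the origin; the connection runs down the
#' shaft; the forearm folds at the elbow in the sagittal (X-Y) plane; the
#' hand is collinear with the forearm; the jug is centered at the hand's
#' distal end with its axis along the forearm direction.
#'
#' @param arm_length subject arm length, glenohumeral center to elbow (m).
#' @param activity one of `"jumping_jack"`, `"jogging"`, `"jug_lift"`,
#'   `"internal_rotation"`.
#' @return object of class `prosthesis_model`: data frame of segments with
#'   masses, centroids and inertia (humeral-frame), `elbow_angle_deg`,
#'   `interface_point` (humeral frame, m).
#' @export
build_prosthesis_model <- function(arm_length, activity) {
  if (arm_length <= 0) stop("arm_length must be positive")
  activity <- match.arg(activity, c("jumping_jack", "jogging", "jug_lift",
                                    "internal_rotation"))
  elbow_deg <- switch(activity, jogging = 90, internal_rotation = 90,
                      jumping_jack = 135, jug_lift = 180)
  has_jug <- activity == "jug_lift"
  conn_len <- 0.75 * arm_length
  conn_mass <- 0.50823 * conn_len + 0.3
  interface <- c(0, -0.25 * arm_length, 0)
  elbow <- c(0, -arm_length, 0)
  flex <- pi - elbow_deg * pi / 180
  dir_f <- c(sin(flex), -cos(flex), 0)  # forearm direction from the elbow
  seg <- function(name, length, diameter, mass, com, axis) {
    list(name = name, length = length, radius = diameter / 2, mass = mass,
         com = com, axis = axis / sqrt(sum(axis^2)))
  }
  segments <- list(
    seg("connection", conn_len, 0.060, conn_mass,
        interface + c(0, -conn_len / 2, 0), c(0, -1, 0)),
    seg("forearm", 0.2540, 0.0762, 1.013, elbow + 0.2540 / 2 * dir_f, dir_f),
    seg("hand", 0.1524, 0.0540, 0.416, elbow + (0.2540 + 0.1524 / 2) * dir_f,
        dir_f))
  if (has_jug)
    segments <- c(segments, list(
      seg("jug", 0.2500, 0.1500, 3.800, elbow + (0.2540 + 0.1524) * dir_f,
          dir_f)))
  # centroidal inertia of a solid cylinder, expressed in the humeral frame
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    Iax <- s$mass * s$radius^2 / 2
    Itr <- s$mass * (3 * s$radius^2 + s$length^2) / 12
    # rotation taking local z to the segment axis
    z <- c(0, 0, 1)
    v <- crossprod3(z, s$axis)
    sv <- sqrt(sum(v^2))
    S <- if (sv < 1e-12) {
      if (sum(z * s$axis) > 0) diag(3) else rotation_about_axis(c(1, 0, 0), pi)
    } else rotation_about_axis(v / sv, atan2(sv, sum(z * s$axis)))
    segments[[i]]$inertia <- S %*% diag(c(Itr, Itr, Iax)) %*% t(S)
  }
  structure(list(segments = segments, elbow_angle_deg = elbow_deg,
                 arm_length = arm_length, activity = activity,
                 interface_point = interface, has_jug = has_jug),
            class = "prosthesis_model")
}

#' @export
print.prosthesis_model <- function(x, ...) {
  cat(sprintf("<prosthesis model: %s, elbow %g deg, arm length %.3f m%s>\n",
              x$activity, x$elbow_angle_deg, x$arm_length,
              if (x$has_jug) ", jug attached" else ""))
  for (s in x$segments)
    cat(sprintf("  %-10s L=%.4f m  m=%.3f kg\n", s$name, s$length, s$mass))
  invisible(x)
}

#' Exact rotation-vector-rate to angular-velocity map
#'
#' `omega = A(r) rdot` with
#' `A = I + (1-cos|r|)/|r|^2 [r]x + (|r|-sin|r|)/|r|^3 [r]x^2`
#' (spatial angular velocity).
#'
#' @param r rotation vector (rad).
#' @param rdot rotation-vector rate (rad/s).
#' @return angular velocity 3-vector (rad/s).
#' @export
rotvec_rate_to_angvel <- function(r, rdot) {
  th <- sqrt(sum(r^2))
  K <- skew(r)
  A <- if (th < 1e-8) diag(3) + K / 2 + K %*% K / 6
       else diag(3) + (1 - cos(th)) / th^2 * K + (th - sin(th)) / th^3 * K %*% K
  as.numeric(A %*% rdot)
}

segment_world_kinematics <- function(model, traj, deriv) {
  n <- length(traj$poses)
  dt <- 1 / traj$rate
  Rs <- lapply(traj$poses, `[[`, "R")
  ts <- pt_translations(traj)
  # true angular velocity from rotvec rates, acceleration by differences
  omega <- t(vapply(seq_len(n), function(k)
    rotvec_rate_to_angvel(deriv$rotvec[k, ], deriv$angular_velocity[k, ]),
    numeric(3)))
  alpha <- central_diff(omega, dt)
  list(n = n, R = Rs, t = ts, omega = omega, alpha = alpha,
       a0 = deriv$linear_acceleration, v0 = deriv$linear_velocity)
}

#' Interface loads by the recursive Newton-Euler algorithm
#'
#' Computes the wrench that the residual bone exerts on the prosthesis at
#' the bone-implant interface (the distal cross-section of the 25% residual
#' humerus) over a humeral trajectory. With the elbow fixed, the segment
#' chain moves rigidly with the humerus: the recursion propagates the
#' humeral angular velocity/acceleration and per-centroid accelerations
#' outward, then sums segment forces and moments inward to the interface.
#' Angular velocity uses the exact rotation-vector-rate map (see
#' [rotvec_rate_to_angvel()]).
#'
#' Projections follow the humeral axis (the body-frame superior axis
#' rotated by the current pose): axial force is the reaction force along
#' the axis, torsional moment the reaction moment along the axis, bending
#' moment the norm of the moment component in the orthogonal plane.
#'
#' @param model a [build_prosthesis_model()] result.
#' @param traj humeral `pose_trajectory` (body frame at the glenohumeral
#'   center, +Y superior).
#' @param deriv matching [derive_kinematics()] result (same length); pass
#'   `cutoff = NULL` there for clean synthetic signals.
#' @param gravity gravity vector in the analysis frame (m/s^2, default
#'   `c(0, 0, -9.81)`).
#' @return object of class `load_trajectory`: data frame with `time`,
#'   `Fx..Mz` (N, N m), `axial`, `torsion` (signed), `bending` (>= 0).
#' @export
rnea_loads <- function(model, traj, deriv, gravity = c(0, 0, -9.81)) {
  if (length(traj$poses) != nrow(deriv$position))
    stop("trajectory and derivatives have different lengths")
  kin <- segment_world_kinematics(model, traj, deriv)
  n <- kin$n
  out <- matrix(0, n, 9)
  for (k in seq_len(n)) {
    R <- kin$R[[k]]; tr <- kin$t[k, ]
    w <- kin$omega[k, ]; al <- kin$alpha[k, ]
    a0 <- kin$a0[k, ]
    P <- as.numeric(R %*% model$interface_point) + tr
    Fsum <- c(0, 0, 0); Nsum <- c(0, 0, 0)
    for (s in model$segments) {
      rc <- as.numeric(R %*% s$com)
      x <- rc + tr
      a_c <- a0 + crossprod3(al, rc) + crossprod3(w, crossprod3(w, rc))
      Fi <- s$mass * (a_c - gravity)
      Iw <- R %*% s$inertia %*% t(R)
      Ni <- as.numeric(Iw %*% al) + crossprod3(w, as.numeric(Iw %*% w))
      Fsum <- Fsum + Fi
      Nsum <- Nsum + Ni + crossprod3(x - P, Fi)
    }
    axis <- as.numeric(R %*% c(0, 1, 0))
    pr <- project_loads(list(force = Fsum, moment = Nsum), axis)
    out[k, ] <- c(Fsum, Nsum, pr$axial, pr$torsion, pr$bending)
  }
  d <- as.data.frame(out)
  names(d) <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz", "axial", "torsion", "bending")
  d <- cbind(time = traj$time, d)
  class(d) <- c("load_trajectory", "data.frame")
  d
}

#' Project an interface wrench onto the humeral axis
#'
#' @param wrench list with `force` (N) and `moment` (N m) 3-vectors.
#' @param humeral_axis unit 3-vector (checked to 1e-6).
#' @return list with `axial` (N, signed), `torsion` (N m, signed),
#'   `bending` (N m, norm of the orthogonal moment component).
#' @export
project_loads <- function(wrench, humeral_axis) {
  if (abs(sqrt(sum(humeral_axis^2)) - 1) > 1e-6)
    stop("humeral_axis must be a unit vector")
  axial <- sum(wrench$force * humeral_axis)
  torsion <- sum(wrench$moment * humeral_axis)
  bending <- sqrt(max(sum(wrench$moment^2) - torsion^2, 0))
  list(axial = axial, torsion = torsion, bending = bending)
}

#' Gravitational share of the bending moment
#'
#' Runs the inverse dynamics twice — once with the full kinematics and once
#' with all velocities and accelerations zeroed (gravity only) — and
#' reports the ratio of gravity-only to full bending moment per timepoint
#' and at the timepoint of peak full bending. For a slow jug lift the
#' gravitational share at peak exceeds 90%: the jug's weight, not inertia,
#' drives the bone bending moment.
#'
#' @inheritParams rnea_loads
#' @param floor bending moments below this (N m) give `NA` fractions.
#' @return list with `fraction` (per timepoint), `at_peak`, `peak_index`,
#'   and the two `load_trajectory` objects (`full`, `gravity_only`).
#' @export
gravitational_fraction <- function(model, traj, deriv,
                                   gravity = c(0, 0, -9.81), floor = 1e-9) {
  full <- rnea_loads(model, traj, deriv, gravity)
  dz <- deriv
  for (f in c("linear_velocity", "angular_velocity", "linear_acceleration",
              "angular_acceleration"))
    dz[[f]][] <- 0
  gonly <- rnea_loads(model, traj, dz, gravity)
  frac <- ifelse(abs(full$bending) > floor, gonly$bending / full$bending, NA_real_)
  pk <- which.max(abs(full$bending))
  at_peak <- if (abs(full$bending[pk]) > floor) frac[pk] else NA_real_
  list(fraction = frac, at_peak = at_peak, peak_index = pk,
       full = full, gravity_only = gonly)
}

#' Write a load trajectory CSV
#' @param loads a `load_trajectory`.
#' @param file output path.
#' @export
write_load_trajectory <- function(loads, file) {
  utils::write.csv(format(as.data.frame(loads), digits = 15, trim = TRUE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
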