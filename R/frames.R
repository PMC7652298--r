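#' Least-squares sphere fit
#'
#' Algebraic (linear) least-squares fit of a sphere to >= 4 non-coplanar
#' points: `|x|^2 = 2 c . x + (r^2 - |c|^2)` is linear in the center `c`
#' and the offset term. Used to locate the humeral head center from points
#' digitized on the articular surface.
#'
#' @param points n x 3 matrix of points (m), n >= 4, non-coplanar.
#' @return list with `center` (3-vector, m), `radius` (m), `rms` residual
#'   of point-to-sphere distances (m).
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4L) stop("degenerate (coplanar) point configuration")
  sol <- qr.coef(qrA, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  d <- sqrt(rowSums(sweep(points, 2, center)^2)) - radius
  list(center = unname(center), radius = unname(radius),
       rms = sqrt(mean(d^2)))
}

#' Humeral anatomical frame from landmarks
#'
#' Builds the humeral coordinate system used throughout: origin at the
#' glenohumeral (humeral head) center; superior axis Y is the unit vector
#' from the epicondyle midpoint to the head center (the ISB humeral long
#' axis); anterior axis X is perpendicular to the plane spanned by the
#' epicondyle line and Y (so the medial-lateral epicondyle line lies in the
#' frontal plane); lateral axis Z completes the right-handed triad. Only
#' the long axis enters downstream load projections.
#'
#' @param head_center glenohumeral rotation center (3-vector, m).
#' @param medial_epicondyle,lateral_epicondyle landmark points (m).
#' @return [rt()] pose of the humeral frame in the landmark frame
#'   (e.g. `HS -> H` when landmarks are digitized in the hemisphere frame).
#' @export
build_humeral_frame <- function(head_center, medial_epicondyle,
                                lateral_epicondyle) {
  head_center <- as.numeric(head_center)
  mid <- (as.numeric(medial_epicondyle) + as.numeric(lateral_epicondyle)) / 2
  y <- head_center - mid
  ny <- sqrt(sum(y^2))
  z0 <- as.numeric(lateral_epicondyle) - as.numeric(medial_epicondyle)
  if (ny < 1e-9 || sqrt(sum(crossprod3(y, z0)^2)) < 1e-12 * ny)
    stop("collinear or coincident landmarks")
  y <- y / ny
  x <- crossprod3(y, z0); x <- x / sqrt(sum(x^2))
  z <- crossprod3(x, y)
  rt(cbind(x, y, z), head_center)
}

#' Calibration pose-pair set
#'
#' Pairs of simultaneously observed poses: the robot end-effector pose read
#' from the controller (`robot_poses`, exact to repeatability) and the
#' tracked rigid-body pose from the optical tracker (`tracked_poses`).
#'
#' @param robot_poses,tracked_poses lists of [rt()], equal length >= 3.
#' @return object of class `calibration_set`.
#' @export
calibration_set <- function(robot_poses, tracked_poses) {
  if (length(robot_poses) != length(tracked_poses))
    stop("pose lists must have equal length")
  if (length(robot_poses) < 3L) stop("need at least 3 pose pairs")
  structure(list(robot_poses = robot_poses, tracked_poses = tracked_poses),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration set: %d pose pairs>\n", length(x$robot_poses)))
  invisible(x)
}

calib_identifiable <- function(calib, tol = 1e-6) {
  A <- calib$robot_poses
  axes <- NULL
  for (i in seq_along(A)[-1]) {
    Rrel <- t(A[[1]]$R) %*% A[[i]]$R
    v <- rotmat_to_rotvec(Rrel)
    th <- sqrt(sum(v^2))
    if (th > 1e-6) axes <- rbind(axes, v / th)
  }
  !is.null(axes) && nrow(axes) >= 2 &&
    svd(axes)$d[2] > tol * max(svd(axes)$d[1], 1)
}

#' Identify tracker-to-robot rotation and end-effector-to-rigid-body transform
#'
#' Solves the AX = ZB hand-eye/base calibration from paired poses
#' `A_i = R_T_EE^i` (robot controller) and `B_i = OT_T_HS^i` (tracker),
#' for `X = EE_T_HS` and `Z = R_T_OT`:
#' separable linear least squares on the rotations (Kronecker/null-space
#' formulation over all pairs) followed by linear least squares on the
#' translations. The translation of `Z` is estimated internally but
#' discarded — only the rotation `R_OT` is needed downstream, because the
#' comparison metrics are invariant to a common translation.
#'
#' @param calib a [calibration_set()] whose relative robot rotations span at
#'   least two independent axes.
#' @return list with `R_OT` (3x3 rotation, tracker frame in robot frame),
#'   `EE_T_HS` ([rt()]), `rotation_rms` (rad) and `translation_rms` (m)
#'   pose-discrepancy residuals.
#' @export
identify_frames <- function(calib) {
  if (!calib_identifiable(calib))
    stop("calibration poses are not identifiable: relative rotations span fewer than 2 axes")
  A <- calib$robot_poses
  B <- calib$tracked_poses
  n <- length(A)
  # rotations: R_Ai R_X = R_Z R_Bi  ->  (I (x) R_Ai) vecX - (R_Bi' (x) I) vecZ = 0
  M <- matrix(0, 9 * n, 18)
  for (i in seq_len(n)) {
    rows <- (9 * (i - 1) + 1):(9 * i)
    M[rows, 1:9] <- diag(3) %x% A[[i]]$R
    M[rows, 10:18] <- -(t(B[[i]]$R) %x% diag(3))
  }
  v <- svd(M)$v[, 18]
  MX <- matrix(v[1:9], 3, 3)
  MZ <- matrix(v[10:18], 3, 3)
  if (det(MX) < 0) { MX <- -MX; MZ <- -MZ }
  proj <- function(m) { s <- svd(m); s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v) }
  RX <- proj(MX); RZ <- proj(MZ)
  # translations: R_Ai tX - tZ_part:  R_Ai tX + t_Ai = R_Z t_Bi + tZ
  L <- matrix(0, 3 * n, 6)
  rhs <- numeric(3 * n)
  for (i in seq_len(n)) {
    rows <- (3 * (i - 1) + 1):(3 * i)
    L[rows, 1:3] <- A[[i]]$R
    L[rows, 4:6] <- -diag(3)
    rhs[rows] <- as.numeric(RZ %*% B[[i]]$t) - A[[i]]$t
  }
  tsol <- qr.coef(qr(L), rhs)
  tX <- as.numeric(tsol[1:3]); tZ <- as.numeric(tsol[4:6])
  # residuals of A_i X vs Z B_i
  X <- rt(RX, tX); Z <- rt(RZ, tZ)
  rot_err <- tra_err <- numeric(n)
  for (i in seq_len(n)) {
    lhs <- rt_compose(A[[i]], X, validate = FALSE)
    rhs_i <- rt_compose(Z, B[[i]], validate = FALSE)
    rot_err[i] <- rotation_angle(lhs$R, rhs_i$R)
    tra_err[i] <- sqrt(sum((lhs$t - rhs_i$t)^2))
  }
  list(R_OT = RZ, EE_T_HS = X,
       rotation_rms = sqrt(mean(rot_err^2)),
       translation_rms = sqrt(mean(tra_err^2)))
}

#' Compose the humeral tool frame
#'
#' `EE_T_H = EE_T_HS . HS_T_H`: the humerus pose relative to the robot
#' end-effector, from the end-effector-to-hemisphere and
#' hemisphere-to-humerus transforms.
#'
#' @param EE_T_HS,HS_T_H [rt()] transforms.
#' @return [rt()] `EE_T_H`.
#' @export
compose_tool_frame <- function(EE_T_HS, HS_T_H) rt_compose(EE_T_HS, HS_T_H)
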