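#' Rigid transforms and rotation representations
#'
#' A rigid transform is stored as a list with a 3x3 orthonormal rotation
#' matrix `R` (dimensionless) and a 3-vector translation `t` (meters).
#' All internal units are SI (m, s, rad); degrees appear only at file and
#' report boundaries. Frames are right-handed and gravity is taken along -Z
#' of both the motion-capture and robot frames (a data contract required for
#' the gravity-axis mapping to be meaningful).
#'
#' @param R 3x3 orthonormal rotation matrix.
#' @param t translation 3-vector (m).
#' @param validate check orthonormality and determinant (tolerance 1e-9)?
#' @return An object of class `rt`.
#' @export
rt <- function(R = diag(3), t = c(0, 0, 0), validate = TRUE) {
  R <- unname(as.matrix(R))
  t <- as.numeric(t)
  if (!all(dim(R) == c(3L, 3L))) stop("rotation must be 3x3")
  if (length(t) != 3L) stop("translation must be length 3")
  out <- structure(list(R = R, t = t), class = "rt")
  if (validate) rt_validate(out)
  out
}

#' Validate a rigid transform
#'
#' Checks `R %*% t(R) = I` and `det(R) = +1` within `tol`.
#'
#' @param x an `rt` object.
#' @param tol numeric tolerance (default 1e-9).
#' @return `x`, invisibly; errors if invalid.
#' @export
rt_validate <- function(x, tol = 1e-9) {
  if (!inherits(x, "rt")) stop("not an rt object")
  if (max(abs(x$R %*% t(x$R) - diag(3))) > tol)
    stop("rotation matrix is not orthonormal within tolerance")
  if (abs(det(x$R) - 1) > tol)
    stop("rotation matrix determinant is not +1 within tolerance")
  if (any(!is.finite(x$t))) stop("translation is not finite")
  invisible(x)
}

#' Identity transform
#' @return identity `rt`.
#' @export
rt_identity <- function() rt(diag(3), c(0, 0, 0), validate = FALSE)

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` maps coordinates through `b` then `a`, i.e. the 4x4
#' homogeneous product `a %*% b`.
#'
#' @param a,b `rt` objects.
#' @param validate validate inputs first?
#' @return composed `rt`.
#' @export
rt_compose <- function(a, b, validate = TRUE) {
  if (validate) { rt_validate(a); rt_validate(b) }
  rt(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t, validate = FALSE)
}

#' Invert a rigid transform
#' @param x an `rt` object.
#' @param validate validate input first?
#' @return inverse `rt`.
#' @export
rt_invert <- function(x, validate = TRUE) {
  if (validate) rt_validate(x)
  Rt <- t(x$R)
  rt(Rt, as.numeric(-Rt %*% x$t), validate = FALSE)
}

#' Apply a rigid transform to points
#' @param x an `rt` object.
#' @param p 3-vector or n x 3 matrix of points.
#' @return transformed points, same shape as `p`.
#' @export
rt_apply <- function(x, p) {
  if (is.matrix(p)) t(x$R %*% t(p) + x$t) else as.numeric(x$R %*% p) + x$t
}

#' Convert to/from 4x4 homogeneous matrix
#' @param x an `rt` object.
#' @return 4x4 matrix.
#' @export
rt_as_matrix <- function(x) {
  m <- diag(4)
  m[1:3, 1:3] <- x$R
  m[1:3, 4] <- x$t
  m
}

#' @rdname rt_as_matrix
#' @param m 4x4 homogeneous matrix.
#' @export
rt_from_matrix <- function(m) rt(m[1:3, 1:3], m[1:3, 4])

#' @export
print.rt <- function(x, ...) {
  cat("<rigid transform>\n")
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(NULL, c("R1", "R2", "R3", "t"))
  print(round(m, 6))
  invisible(x)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

unskew <- function(m) c(m[3, 2], m[1, 3], m[2, 1])

#' Rodrigues rotation about an axis
#'
#' @param axis unit 3-vector (checked to 1e-9).
#' @param theta angle (rad).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero-length axis")
  if (abs(n - 1) > 1e-9) stop("axis must be a unit vector")
  K <- skew(axis)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation matrix to rotation vector
#'
#' Returns the axis-angle 3-vector with norm in `[0, pi]`. At angle exactly
#' pi the two antipodal representatives are equivalent; the one whose largest
#' magnitude component is non-negative is returned (trajectory code resolves
#' the ambiguity by continuity with the previous sample instead).
#'
#' @param R 3x3 orthonormal rotation matrix.
#' @return rotation vector (rad).
#' @export
rotmat_to_rotvec <- function(R) {
  tr <- sum(diag(R))
  cth <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cth)
  if (theta < 1e-10) {
    # first-order: R ~ I + [v]x
    return(0.5 * unskew(R - t(R)))
  }
  if (theta > pi - 1e-6) {
    # near pi: acos loses precision; recover the angle from the sine part
    st <- sqrt(sum((unskew(R - t(R)) / 2)^2))
    theta <- pi - asin(min(1, st))
    # axis from the symmetric part, sign fixed by convention
    B <- (R + diag(3)) / 2      # = axis outer product at exactly pi
    axis <- sqrt(pmax(diag(B), 0))
    # recover relative signs from off-diagonal terms
    i <- which.max(axis)
    if (axis[i] > 0) {
      for (j in seq_len(3)) if (j != i) axis[j] <- B[i, j] / axis[i]
    }
    axis <- axis / sqrt(sum(axis^2))
    # fix overall sign using the skew part if informative, else convention
    sk <- unskew(R - t(R)) / 2
    if (sqrt(sum(sk^2)) > 1e-8) {
      if (sum(axis * sk) < 0) axis <- -axis
    } else if (axis[which.max(abs(axis))] < 0) axis <- -axis
    return(axis * theta)
  }
  axis <- unskew(R - t(R)) / (2 * sin(theta))
  axis * theta
}

#' Rotation vector to rotation matrix
#' @param v rotation 3-vector (rad).
#' @return 3x3 rotation matrix.
#' @export
rotvec_to_rotmat <- function(v) {
  v <- as.numeric(v)
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) {
    K <- skew(v)
    return(diag(3) + K + K %*% K / 2)
  }
  rotation_about_axis(v / theta, theta)
}

#' Geodesic angle between two rotations
#' @param Ra,Rb 3x3 rotation matrices.
#' @return angle in `[0, pi]` (rad).
#' @export
rotation_angle <- function(Ra, Rb = diag(3)) {
  R <- t(Rb) %*% Ra
  ct <- (sum(diag(R)) - 1) / 2
  st <- sqrt(sum((unskew(R - t(R)) / 2)^2))
  atan2(st, ct)  # atan2 form keeps full precision at small angles
}

#' Re-orthonormalize a near-rotation matrix (polar decomposition)
#'
#' @param R near-orthonormal 3x3 matrix.
#' @param tol maximum allowed departure from orthonormality (default 1e-6).
#' @return closest rotation matrix (Frobenius norm).
#' @export
orthonormalize <- function(R, tol = 1e-6) {
  if (max(abs(R %*% t(R) - diag(3))) > tol)
    stop("matrix departs from orthonormality by more than tolerance")
  s <- svd(R)
  U <- s$u; V <- s$v
  d <- sign(det(U %*% t(V)))
  U %*% diag(c(1, 1, d)) %*% t(V)
}

#' Unwrap a sequence of rotation vectors for continuity
#'
#' Successive rows are replaced by the antipodal-equivalent representative
#' (`v - 2*pi*v/|v|` steps) closest to the previous row, so consecutive
#' samples of a smooth trajectory differ by less than pi.
#'
#' @param v n x 3 matrix of rotation vectors.
#' @return n x 3 unwrapped matrix.
#' @export
unwrap_rotvecs <- function(v) {
  v <- as.matrix(v)
  n <- nrow(v)
  if (n < 2L) return(v)
  for (k in 2:n) {
    cur <- v[k, ]
    th <- sqrt(sum(cur^2))
    if (th > 1e-12) {
      axis <- cur / th
      # candidate equivalent representatives th + 2*pi*m along +/- axis
      best <- cur
      bestd <- sum((cur - v[k - 1, ])^2)
      for (m in c(-2, -1, 1, 2)) {
        cand <- axis * (th + 2 * pi * m)
        d <- sum((cand - v[k - 1, ])^2)
        if (d < bestd) { best <- cand; bestd <- d }
      }
      v[k, ] <- best
    }
  }
  v
}
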