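# shared fixtures, built in code at test time

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_about_axis(ax, stats::runif(1, 0, pi - 0.1))
}

random_rt <- function() rt(random_rotation(), stats::rnorm(3, sd = 0.3))

# independent 4x4 homogeneous product oracle
compose_oracle <- function(a, b) {
  m <- rt_as_matrix(a) %*% rt_as_matrix(b)
  list(R = m[1:3, 1:3], t = m[1:3, 4])
}

# quaternion-based rotation construction oracle
quat_rotation_oracle <- function(axis, theta) {
  q <- c(cos(theta / 2), sin(theta / 2) * axis)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

max_rt_diff <- function(a, b) max(abs(rt_as_matrix(a) - rt_as_matrix(b)))

# constant-pose trajectory
constant_trajectory <- function(pose, n = 10, rate = 200) {
  pose_trajectory(rep(list(pose), n), rate = rate, validate = FALSE)
}

# smooth sinusoidal test trajectory with known analytic content
sinusoid_trajectory <- function(n = 201, rate = 100, pos_amp = c(0.05, 0.03, 0.04),
                                rot_amp = c(0.3, 0.2, 0.1), freq = 0.5,
                                base = c(0.0, 0.0, 1.2)) {
  tt <- (seq_len(n) - 1) / rate
  poses <- lapply(seq_len(n), function(k) {
    p <- base + pos_amp * sin(2 * pi * freq * tt[k] + c(0, 1, 2))
    r <- rot_amp * sin(2 * pi * freq * tt[k] + c(1, 2, 0))
    rt(rotvec_to_rotmat(r), p, validate = FALSE)
  })
  pose_trajectory(poses, rate = rate, validate = FALSE)
}

default_tool <- function() rt(rotation_about_axis(c(1, 0, 0), 0.3), c(0, 0, 0.10))

# momentum-theorem inverse-dynamics oracle: interface wrench from finite
# differences of summed segment momenta (independent of the RNEA recursion)
momentum_oracle <- function(model, traj, gravity = c(0, 0, -9.81)) {
  n <- length(traj$poses)
  dt <- 1 / traj$rate
  Rs <- lapply(traj$poses, `[[`, "R")
  ts <- lapply(traj$poses, `[[`, "t")
  masses <- vapply(model$segments, `[[`, numeric(1), "mass")
  # angular velocity from rotation-matrix finite differences
  omega <- matrix(0, n, 3)
  for (k in 2:(n - 1)) {
    Rdot <- (Rs[[k + 1]] - Rs[[k - 1]]) / (2 * dt)
    W <- Rdot %*% t(Rs[[k]])
    omega[k, ] <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
  }
  coms <- lapply(seq_len(n), function(k)
    lapply(model$segments, function(s) as.numeric(Rs[[k]] %*% s$com) + ts[[k]]))
  # linear momentum and angular momentum about the world origin
  P <- matrix(0, n, 3); L <- matrix(0, n, 3)
  for (k in 2:(n - 1)) {
    for (i in seq_along(model$segments)) {
      v <- (coms[[k + 1]][[i]] - coms[[k - 1]][[i]]) / (2 * dt)
      P[k, ] <- P[k, ] + masses[i] * v
      Iw <- Rs[[k]] %*% model$segments[[i]]$inertia %*% t(Rs[[k]])
      L[k, ] <- L[k, ] + as.numeric(Iw %*% omega[k, ]) +
        cross3(coms[[k]][[i]], masses[i] * v)
    }
  }
  res <- matrix(NA_real_, n, 6)
  for (k in 3:(n - 2)) {
    Pdot <- (P[k + 1, ] - P[k - 1, ]) / (2 * dt)
    Ldot <- (L[k + 1, ] - L[k - 1, ]) / (2 * dt)
    Fg <- colSums(do.call(rbind, lapply(seq_along(masses), function(i)
      masses[i] * gravity)))
    Tg <- colSums(do.call(rbind, lapply(seq_along(masses), function(i)
      cross3(coms[[k]][[i]], masses[i] * gravity))))
    Fi <- Pdot - Fg
    Pk <- as.numeric(Rs[[k]] %*% model$interface_point) + ts[[k]]
    Mi <- Ldot - Tg - cross3(Pk, Fi)
    res[k, ] <- c(Fi, Mi)
  }
  res
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
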