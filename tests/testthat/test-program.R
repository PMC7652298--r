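test_that("subsampling keeps the exact budget with endpoint anchoring", {
  traj <- sinusoid_trajectory(n = 500, rate = 200)
  idx <- nonuniform_subsample(traj, 0.2)
  expect_length(idx, 100)
  expect_equal(idx[1], 1)
  expect_equal(idx[length(idx)], 500)
  # f = 1 is the identity
  expect_equal(nonuniform_subsample(traj, 1), 1:500)
  expect_error(nonuniform_subsample(pt_subset(traj, 1:4), 0.2), "at least 2")
})

test_that("constant-velocity lines subsample near-uniformly", {
  n <- 200
  poses <- lapply(seq_len(n), function(k)
    rt(diag(3), c(0.002 * (k - 1), 0, 0.5), validate = FALSE))
  line <- pose_trajectory(poses, rate = 200, validate = FALSE)
  idx <- nonuniform_subsample(line, 0.2)
  gaps <- diff(idx)
  expect_lt(max(gaps) / min(gaps), 1.5 + 1e-9)
})

test_that("curved sections attract waypoint density", {
  # straight, then a 90-degree arc, then straight, at constant speed
  n_straight <- 120; n_arc <- 61; r <- 0.05
  step <- r * (pi / 2) / (n_arc - 1)
  p1 <- lapply(seq_len(n_straight), function(k) c(step * (k - 1), 0, 0.5))
  x0 <- step * (n_straight - 1)
  p2 <- lapply(seq_len(n_arc), function(k) {
    th <- (k - 1) / (n_arc - 1) * pi / 2
    c(x0 + r * sin(th), r * (1 - cos(th)), 0.5)
  })
  e <- p2[[n_arc]]
  p3 <- lapply(seq_len(n_straight), function(k) c(e[1], e[2] + step * k, 0.5))
  pts <- c(p1, p2, p3)
  corner <- pose_trajectory(lapply(pts, function(p) rt(diag(3), p, validate = FALSE)),
                            rate = 200, validate = FALSE)
  n <- length(pts)
  idx <- nonuniform_subsample(corner, 0.1)
  arc_range <- (n_straight + 1):(n_straight + n_arc)
  density_arc <- sum(idx %in% arc_range) / n_arc
  density_straight <- sum(!(idx %in% arc_range)) / (n - n_arc)
  expect_gt(density_arc, density_straight)
})

test_that("greedy subsampling never exceeds uniform subsampling's deviation", {
  set.seed(59)
  for (rep in 1:3) {
    traj <- sinusoid_trajectory(n = 240, rate = 200,
                                pos_amp = stats::runif(3, 0.02, 0.08),
                                rot_amp = stats::runif(3, 0.1, 0.4),
                                freq = stats::runif(1, 0.5, 1.5))
    m <- 48
    idx_g <- nonuniform_subsample(traj, m / 240)
    idx_u <- unique(round(seq(1, 240, length.out = m)))
    expect_lte(subsample_max_deviation(traj, idx_g),
               subsample_max_deviation(traj, idx_u) + 1e-12)
  }
})

test_that("motion programs carry segment speeds and round-trip as text", {
  rb <- default_robot()
  # two waypoints 0.1 m apart, 0.5 s apart -> 200 mm/s
  q1 <- c(0.1, 0.35, -0.2, 0.3, 0.6, 0.1)
  fk1 <- forward_kinematics(rb, q1)
  q2 <- inverse_kinematics(rb, rt(fk1$R, fk1$t + c(0.1, 0, 0)), q1)
  jt <- joint_trajectory(rbind(q1, q2), rate = 2)
  prog <- emit_motion_program(jt, rb, 1:2, smoothness = 50)
  expect_equal(prog$speed[2], 200, tolerance = 1e-6)
  # parser(emitter(P)) = P, including on random programs
  set.seed(61)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    p0 <- motion_program(matrix(stats::runif(6 * n, -1, 1), n, 6),
                         time = cumsum(stats::runif(n, 0.05, 0.3)),
                         speed = c(NA, stats::runif(n - 1, 10, 900)),
                         smoothness = sample(0:100, n, replace = TRUE),
                         rate = 200)
    p1 <- parse_motion_program(format_motion_program(p0))
    expect_equal(p1$q, p0$q, tolerance = 1e-12)
    expect_equal(p1$time, p0$time, tolerance = 1e-12)
    expect_equal(p1$speed[-1], p0$speed[-1], tolerance = 1e-12)
    expect_equal(p1$smoothness, p0$smoothness)
    expect_equal(p1$rate, p0$rate)
  }
  # monotone timestamps preserved; zero time delta rejected
  expect_error(emit_motion_program(joint_trajectory(rbind(q1, q2), rate = 2,
                                                    time = c(0, 0)), rb, 1:2),
               "time delta")
})

test_that("the virtual controller honors fine positioning and speed requests", {
  rb <- default_robot()
  set.seed(67)
  q0 <- c(0.1, 0.3, -0.2, 0.2, 0.5, 0)
  qs <- rbind(q0, q0 + c(0.1, 0.05, -0.04, 0.08, 0.06, 0.1),
              q0 + c(0.2, -0.02, 0.03, -0.05, 0.12, 0.2))
  jt <- joint_trajectory(qs, rate = 2)
  prog <- emit_motion_program(jt, rb, 1:3, smoothness = 0)
  sim <- simulate_execution(prog, rb, controller = list(rate = 200))
  # smoothness 0: achieved passes through every waypoint
  for (k in 1:3) {
    tk <- prog$time[k] - prog$time[1]
    si <- which.min(abs(sim$joint_trajectory$time - tk))
    expect_lt(max(abs(sim$joint_trajectory$q[si, ] - qs[k, ])), 1e-9)
  }
  # endpoints coincide exactly
  expect_lt(max(abs(sim$joint_trajectory$q[1, ] - qs[1, ])), 1e-12)
  nlast <- nrow(sim$joint_trajectory$q)
  expect_lt(max(abs(sim$joint_trajectory$q[nlast, ] - qs[3, ])), 1e-9)
  # single in-limit segment: achieved mean Cartesian speed within 5% of request
  prog2 <- emit_motion_program(joint_trajectory(qs[1:2, ], rate = 2), rb, 1:2)
  sim2 <- simulate_execution(prog2, rb, controller = list(rate = 400))
  pos <- pt_translations(sim2$pose_trajectory)
  dur <- max(sim2$joint_trajectory$time)
  mean_speed <- sum(sqrt(rowSums(diff(pos)^2))) / dur * 1000
  expect_equal(mean_speed, prog2$speed[2], tolerance = 0.05)
  # a request beyond joint capability saturates and arrives late
  fast <- motion_program(qs[1:2, ], time = c(0, 0.01),
                         speed = c(NA, 1e5), smoothness = c(0, 0), rate = 200)
  sim3 <- simulate_execution(fast, rb, controller = list(rate = 1000))
  dur3 <- max(sim3$joint_trajectory$time)
  expect_gt(dur3, 0.01)  # lag
  qd <- abs(diff(sim3$joint_trajectory$q)) * 1000
  expect_lte(max(sweep(qd, 2, rb$velocity_limits, "/")), 1 + 1e-6)
  # out-of-limit waypoints are rejected
  bad <- motion_program(rbind(q0, q0 + c(0, 0, 0, 0, 0, 10)),
                        time = c(0, 1), speed = c(NA, 100),
                        smoothness = c(0, 0), rate = 200)
  expect_error(simulate_execution(bad, rb), "unreachable|out-of-limit")
})
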