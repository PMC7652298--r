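test_that("prosthesis models follow the published segment table", {
  m <- build_prosthesis_model(0.30, "jug_lift")
  conn <- m$segments[[1]]
  expect_equal(conn$length, 0.225)
  expect_equal(conn$mass, 0.50823 * 0.225 + 0.3, tolerance = 1e-12)
  expect_equal(m$elbow_angle_deg, 180)
  expect_true(m$has_jug)
  expect_equal(m$segments[[4]]$mass, 3.800)
  expect_equal(m$segments[[2]]$length, 0.2540)
  expect_equal(m$segments[[3]]$mass, 0.416)
  mj <- build_prosthesis_model(0.30, "jogging")
  expect_equal(mj$elbow_angle_deg, 90)
  expect_false(mj$has_jug)
  expect_length(mj$segments, 3)
  expect_equal(build_prosthesis_model(0.3, "jumping_jack")$elbow_angle_deg, 135)
  expect_error(build_prosthesis_model(0.3, "swimming"), "arg")
  expect_error(build_prosthesis_model(-1, "jogging"), "positive")
  # interface at the 25% amputation level
  expect_equal(m$interface_point, c(0, -0.075, 0))
})

test_that("load projections decompose the wrench Pythagoreanly", {
  expect_equal(project_loads(list(force = c(0, 0, -50), moment = c(0, 0, 0)),
                             c(0, 0, 1))$axial, -50)
  pr <- project_loads(list(force = c(0, 0, 0), moment = c(3, 4, 0)), c(0, 0, 1))
  expect_equal(pr$torsion, 0)
  expect_equal(pr$bending, 5)
  set.seed(71)
  for (i in 1:20) {
    f <- stats::rnorm(3); mm <- stats::rnorm(3)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    p <- project_loads(list(force = f, moment = mm), ax)
    inplane <- sqrt(sum(f^2) - p$axial^2)
    expect_equal(p$axial^2 + inplane^2, sum(f^2), tolerance = 1e-9)
    expect_equal(p$torsion^2 + p$bending^2, sum(mm^2), tolerance = 1e-9)
  }
  expect_error(project_loads(list(force = 1:3, moment = 1:3), c(0, 0, 2)),
               "unit")
})

test_that("static and free-fall cases match first principles", {
  m <- build_prosthesis_model(0.30, "jug_lift")
  # stationary pose, zero gravity: zero wrench
  traj <- constant_trajectory(rt(rotvec_to_rotmat(c(0.1, 0.2, 0)), c(0, 0, 1)),
                              n = 11, rate = 200)
  d <- derive_kinematics(traj, cutoff = NULL)
  l0 <- rnea_loads(m, traj, d, gravity = c(0, 0, 0))
  expect_lt(max(abs(as.matrix(l0[, 2:7]))), 1e-9)
  # free fall: equivalence principle gives zero wrench
  poses <- lapply(0:20, function(k)
    rt(diag(3), c(0, 0, -0.5 * 9.81 * (k / 200)^2), validate = FALSE))
  trf <- pose_trajectory(poses, rate = 200, validate = FALSE)
  lf <- rnea_loads(m, trf, derive_kinematics(trf, cutoff = NULL))
  expect_lt(max(abs(as.matrix(lf[3:19, 2:7]))), 1e-9)
  # horizontal arm statics: moment = sum of m_i g d_i
  R <- cbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # humeral +Y -> world +X
  trh <- constant_trajectory(rt(R, c(0, 0, 1)), n = 11, rate = 200)
  lh <- rnea_loads(m, trh, derive_kinematics(trh, cutoff = NULL))
  g <- 9.81
  P <- as.numeric(R %*% m$interface_point)
  Ms <- sum(vapply(m$segments, function(s) {
    x <- as.numeric(R %*% s$com)
    s$mass * g * sqrt(sum(((x - P) * c(1, 1, 0))^2))
  }, numeric(1)))
  Fz <- sum(vapply(m$segments, `[[`, numeric(1), "mass")) * g
  expect_equal(as.numeric(lh$Fz[1]), Fz, tolerance = 1e-9)
  expect_equal(sqrt(sum(lh[1, c("Mx", "My", "Mz")]^2)), Ms, tolerance = 1e-9)
  # horizontal arm: pure bending, no torsion, no axial force
  expect_equal(lh$bending[1], Ms, tolerance = 1e-9)
  expect_lt(abs(lh$torsion[1]), 1e-9)
  expect_lt(abs(lh$axial[1]), 1e-9)
})

test_that("RNEA agrees with the momentum-derivative oracle within 1%", {
  for (act in c("jug_lift", "jumping_jack")) {
    m <- build_prosthesis_model(0.28, act)
    g <- generate_activity(act, duration = 1.5, rate = 200, seed = 73,
                           position_scale = 0.6, orientation_scale = 0.5)
    d <- derive_kinematics(g$trajectory, cutoff = NULL)
    loads <- rnea_loads(m, g$trajectory, d)
    oracle <- momentum_oracle(m, g$trajectory)
    i <- 5:(length(g$trajectory$poses) - 4)
    got <- as.matrix(loads[i, 2:7])
    want <- oracle[i, ]
    scale <- max(abs(want))
    expect_lt(max(abs(got - want)) / scale, 0.01)
  }
})

test_that("interface loads are linear in segment masses", {
  m <- build_prosthesis_model(0.30, "jumping_jack")
  m2 <- m
  for (i in seq_along(m2$segments)) {
    m2$segments[[i]]$mass <- 2 * m2$segments[[i]]$mass
    m2$segments[[i]]$inertia <- 2 * m2$segments[[i]]$inertia
  }
  g <- generate_activity("jumping_jack", duration = 1, rate = 100, seed = 79)
  d <- derive_kinematics(g$trajectory, cutoff = NULL)
  l1 <- rnea_loads(m, g$trajectory, d)
  l2 <- rnea_loads(m2, g$trajectory, d)
  expect_equal(as.matrix(l2[, 2:7]), 2 * as.matrix(l1[, 2:7]), tolerance = 1e-9)
})

test_that("gravity dominates the bending moment of slow jug lifts", {
  m <- build_prosthesis_model(0.30, "jug_lift")
  g <- generate_activity("jug_lift", seed = 2)
  d <- derive_kinematics(g$trajectory, cutoff = NULL)
  # generator contract: slow activity, peak angular speed <= 30 deg/s
  expect_lte(max(d$magnitudes$angular_velocity), 30 * pi / 180)
  gf <- gravitational_fraction(m, g$trajectory, d)
  expect_gte(gf$at_peak, 0.90)
  # stationary trajectory: fraction 1 everywhere it is defined
  trs <- constant_trajectory(rt(rotvec_to_rotmat(c(0.4, 0, 0)), c(0, 0, 1)),
                             n = 11, rate = 200)
  ds <- derive_kinematics(trs, cutoff = NULL)
  gfs <- gravitational_fraction(m, trs, ds)
  expect_equal(gfs$at_peak, 1, tolerance = 1e-9)
  # no gravity: fraction 0 once motion exists
  gfn <- gravitational_fraction(m, g$trajectory, d, gravity = c(0, 0, 0))
  expect_true(all(gfn$fraction == 0, na.rm = TRUE))
})
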