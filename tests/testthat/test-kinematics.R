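test_that("flapping angles follow the closed-form kinematics", {
  kin <- wing_kinematics()   # fruit-fly defaults, phi_e0 = 10 deg
  a0 <- euler_angles(kin, 0)
  expect_equal(a0$positional, 70 * cos(10 * pi / 180), tolerance = 1e-12)
  expect_equal(a0$feathering, 0, tolerance = 1e-12)
  expect_equal(a0$elevation, 10 * cos(-10 * pi / 180) + 10, tolerance = 1e-12)
  # hand values: 68.94 and 19.85 degrees
  expect_equal(a0$positional, 68.937, tolerance = 1e-4)
  expect_equal(a0$elevation, 19.848, tolerance = 1e-4)

  # closed-form oracle over a grid of times
  f <- kin$frequency
  tt <- seq(0, 2 / f, length.out = 97)
  ang <- euler_angles(kin, tt)
  d2r <- pi / 180
  expect_equal(ang$positional, 70 * cos(2 * pi * f * tt + 10 * d2r))
  expect_equal(ang$feathering, 70 * sin(2 * pi * f * tt))
  expect_equal(ang$elevation, 10 * cos(4 * pi * f * tt - 10 * d2r) + 10)

  # elevation oscillates at 2f: theta_e(t) == theta_e(t + T/2)
  expect_equal(euler_angles(kin, tt)$elevation,
               euler_angles(kin, tt + 0.5 / f)$elevation, tolerance = 1e-9)
})

test_that("zero elevation amplitude gives the planar motion", {
  kin <- wing_kinematics(amp_elevation = 0, phase_elevation = 0)
  expect_false(kin$figure_eight)
  tt <- seq(0, 1 / kin$frequency, length.out = 33)
  expect_equal(euler_angles(kin, tt)$elevation, rep(0, 33))
  tr <- tip_trajectory(kin, n = 64)
  expect_equal(max(abs(tr$elevation)), 0)
})

test_that("wing transform is a proper rotation, periodic, and mirror-symmetric", {
  kin <- wing_kinematics()
  geom_r <- plate_geometry(side = "right")
  geom_l <- plate_geometry(side = "left")
  T <- 1 / kin$frequency
  set.seed(42)
  for (t in runif(25, 0, 3 * T)) {
    for (side in c("right", "left")) {
      R <- wing_transform(kin, t, side)$R
      expect_equal(det(R), 1, tolerance = 1e-10)
      expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
    }
    # period closure
    expect_equal(wing_transform(kin, t, "right")$R,
                 wing_transform(kin, t + T, "right")$R, tolerance = 1e-8)
    # left wing is the y-z mirror image of the right wing
    pr <- flapwing:::wing_points_lab(kin, t, geom_r, cbind(geom_r$span, 0.3))
    pl <- flapwing:::wing_points_lab(kin, t, geom_l, cbind(geom_l$span, 0.3))
    expect_equal(as.numeric(pl), as.numeric(pr) * c(-1, 1, 1),
                 tolerance = 1e-10)
  }
  # all angles zero -> identity
  kin0 <- wing_kinematics(amp_positional = 0, amp_feathering = 0,
                          amp_elevation = 0, phase_positional = 0,
                          phase_elevation = 0)
  expect_equal(wing_transform(kin0, 0.123, "right")$R, diag(3),
               tolerance = 1e-12)
})

test_that("wall velocity matches an independent finite-difference of position", {
  kin <- wing_kinematics()
  geom <- plate_geometry()
  pts <- rbind(c(geom$span, 0), c(1.2, 0.3), c(0, 0))
  h <- 1e-9 / kin$frequency * 1e3        # much finer independent step
  for (t in c(0.11, 0.47, 0.93) / kin$frequency) {
    v <- wall_velocity(kin, geom, t, pts)
    v_ref <- (flapwing:::wing_points_lab(kin, t + h, geom, pts) -
              flapwing:::wing_points_lab(kin, t - h, geom, pts)) / (2 * h)
    expect_equal(v, v_ref, tolerance = 1e-5)
  }
  # root with zero offset does not move
  expect_equal(max(abs(wall_velocity(kin, geom, 0.2 / 218, cbind(0, 0)))), 0,
               tolerance = 1e-6)
  # static plate
  kin0 <- wing_kinematics(amp_positional = 0, amp_feathering = 0,
                          amp_elevation = 0, phase_positional = 0,
                          phase_elevation = 0)
  expect_equal(max(abs(wall_velocity(kin0, geom, 0.3 / 218, pts))), 0,
               tolerance = 1e-9)
})

test_that("cycle-mean tip speed reproduces the configured mean tip speed", {
  kin <- wing_kinematics()
  # metre-scale geometry: fruit-fly wing length
  geom <- plate_geometry(chord = 0.78e-3, span = 2.39e-3)
  v <- tip_speed_mean(kin, geom)
  expect_lt(abs(v - 2.58) / 2.58, 0.05)
})

test_that("tip trajectories classify as U-shaped or figure-eight by phi_e0", {
  # the 10-degree positional phase leaves a vestigial shallow crossing at
  # the stroke reversal of the U-shaped cases; classification therefore
  # ignores crossings shallower than 0.25 rad (see ?count_self_intersections)
  count_proj <- function(phi) {
    kin <- wing_kinematics(phase_elevation_initial = phi)
    tr <- tip_trajectory(kin, n = 256)
    count_self_intersections(tr$positional, tr$elevation, min_angle = 0.25)
  }
  expect_equal(count_proj(0), 0)      # U-shape
  expect_equal(count_proj(180), 0)    # U-shape
  expect_equal(count_proj(45), 1)     # figure-eight
  expect_equal(count_proj(90), 1)
  expect_equal(count_proj(225), 1)
  expect_error(tip_trajectory(wing_kinematics(), n = 4), "coarse")
})

test_that("halving the frequency rescales time but not the trajectory shape", {
  k1 <- wing_kinematics()
  k2 <- wing_kinematics(frequency = 218 / 2)
  t1 <- tip_trajectory(k1, n = 128)
  t2 <- tip_trajectory(k2, n = 128)
  expect_equal(t1[c("x", "y", "z")], t2[c("x", "y", "z")], tolerance = 1e-10)
  expect_equal(max(t2$t), 2 * max(t1$t))
})

test_that("Reynolds number follows utip * Cm / nu", {
  expect_equal(reynolds_number(2.58, 0.78e-3, 1.5e-5), 134.16, tolerance = 1e-3)
  expect_equal(reynolds_number(0.645, 0.78e-3, 1.5e-5), 33.54, tolerance = 1e-3)
  expect_equal(reynolds_number(2 * 2.58, 0.78e-3, 1.5e-5),
               2 * reynolds_number(2.58, 0.78e-3, 1.5e-5))
  expect_error(reynolds_number(-1, 1, 1), "positive")
  w <- physical_wing()
  expect_equal(w$re, 134.16, tolerance = 1e-3)
  expect_error(physical_wing(mean_chord = 0), "positive")
})
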