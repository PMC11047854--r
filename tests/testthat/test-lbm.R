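test_that("the 27-velocity lattice has the required moment structure", {
  lat <- d3q27()
  expect_equal(sum(lat$w), 1)
  expect_equal(as.numeric(colSums(lat$w * lat$e)), c(0, 0, 0))
  # second moment c^2/3 * delta_ij
  M2 <- t(lat$e) %*% (lat$w * lat$e)
  expect_equal(M2, diag(3) / 3, tolerance = 1e-14, ignore_attr = TRUE)
  # weight classes per speed
  spd <- rowSums(abs(lat$e))
  expect_equal(sort(unique(lat$w[spd == 0])), 8 / 27)
  expect_equal(sort(unique(lat$w[spd == 1])), 2 / 27)
  expect_equal(sort(unique(lat$w[spd == 2])), 1 / 54)
  expect_equal(sort(unique(lat$w[spd == 3])), 1 / 216)
  # opposite pairs
  expect_equal(lat$e[lat$opp, ], -lat$e, ignore_attr = TRUE)
})

test_that("equilibrium distributions satisfy the moment identities", {
  lat <- d3q27()
  # rest state: p weighted by w
  eq0 <- equilibrium(0.7, c(0, 0, 0), lat)
  expect_equal(as.numeric(eq0), 0.7 * lat$w)
  set.seed(7)
  p <- runif(20, 0.2, 0.5)
  u <- matrix(runif(60, -0.05, 0.05), 20, 3)
  eq <- equilibrium(p, u, lat)
  expect_equal(rowSums(eq), p)                       # zeroth moment
  # first moment: sum e p_eq = rho0 cs^2 u (computed by brute-force sum)
  expect_equal(eq %*% lat$e, u / 3, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("macroscopics invert the equilibrium and see shifted pressure only", {
  lat <- d3q27()
  set.seed(8)
  u <- matrix(runif(15, -0.04, 0.04), 5, 3)
  p <- runif(5, 0.3, 0.4)
  m <- macroscopics(equilibrium(p, u, lat), lat)
  expect_equal(m$p, p)
  expect_equal(m$u, u, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(m$Pi_neq)), 1e-14)
  # adding the same constant to every direction moves p, not u
  pd <- equilibrium(p, u, lat) + 0.01
  m2 <- macroscopics(pd, lat)
  expect_equal(m2$p, p + 27 * 0.01)
  expect_equal(m2$u, u, tolerance = 1e-12, ignore_attr = TRUE)
  # Pi_neq symmetric for arbitrary distributions
  pd3 <- matrix(runif(27, 0, 0.05), 1)
  P3 <- macroscopics(pd3, lat)$Pi_neq[, , 1]
  expect_equal(P3, t(P3))
})

test_that("relaxation time is the BGK form and rejects tau <= 1/2", {
  expect_equal(relaxation_time(1 / 6), 1)
  expect_equal(relaxation_time(0.05), 0.65)
  # linearity of tau - 1/2 in nu
  expect_equal(relaxation_time(0.2) - 0.5, 2 * (relaxation_time(0.1) - 0.5))
  expect_error(relaxation_time(0), "unstable|unphysical")
  expect_error(relaxation_time(-0.1), "unstable|unphysical")
})

test_that("uniform equilibrium is a fixed point and pressure is conserved", {
  b <- fluid_block(10, 8, 6, tau = 0.8)
  set_fields(b, 0.37, c(0.02, -0.01, 0.015))
  f0 <- b$f + 0
  for (s in 1:5) collide_stream(b)
  expect_equal(b$f, f0, tolerance = 1e-13)
  # global pressure conservation in a periodic box with a random state
  set.seed(11)
  set_fields(b, 1 / 3 + runif(b$N, -0.01, 0.01),
             matrix(runif(3 * b$N, -0.02, 0.02), b$N, 3))
  ptot0 <- sum(b$f)
  for (s in 1:20) collide_stream(b)
  expect_equal(sum(b$f), ptot0, tolerance = 1e-12)
})

test_that("tau = 1 collision projects straight onto equilibrium", {
  lat <- d3q27()
  b <- fluid_block(6, 6, 6, tau = 1)
  set.seed(3)
  p0 <- 1 / 3 + runif(b$N, -0.005, 0.005)
  u0 <- matrix(runif(3 * b$N, -0.02, 0.02), b$N, 3)
  set_fields(b, p0, u0)
  # perturb off equilibrium
  b$f <- b$f * (1 + 1e-3 * sin(seq_along(b$f)))
  update_macroscopics(b)
  pe <- equilibrium(b$p, matrix(b$u, b$N, 3), lat)
  collide_stream(b)
  # post-streaming values must be pure equilibria of the pre-step state:
  # stream back and compare
  f1 <- matrix(b$f, b$N, 27)
  co <- expand.grid(i = 0:5, j = 0:5, k = 0:5)
  for (a in c(1, 5, 14, 23, 27)) {
    src <- ((co$i - lat$e[a, 1]) %% 6) + 6 * ((co$j - lat$e[a, 2]) %% 6) +
      36 * ((co$k - lat$e[a, 3]) %% 6) + 1
    expect_equal(f1[, a], pe[src, a], tolerance = 1e-14)
  }
})

test_that("Taylor-Green kinetic energy decays at the analytic viscous rate", {
  tg <- taylor_green(32, nu = 0.04, u0 = 0.02)
  b <- tg$block
  for (s in 1:80) collide_stream(b)
  e1 <- kinetic_energy(b)
  for (s in 1:80) collide_stream(b)
  e2 <- kinetic_energy(b)
  rate <- log(e1 / e2) / 80
  expect_lt(abs(rate / (4 * tg$nu * tg$k^2) - 1), 0.01)
  # pointwise solution error stays small
  a <- tg$analytic(160)
  update_macroscopics(b)
  err <- sqrt(sum((as.numeric(block_array(b, "ux")) - a$u[, 1])^2) /
              sum(a$u[, 1]^2))
  expect_lt(err, 0.05)
})

test_that("divergence is reported as an error, not silent NaNs", {
  b <- fluid_block(6, 6, 6, tau = 0.8)
  b$f[1:10] <- NaN
  expect_error(for (s in 1:10) collide_stream(b), "diverged")
})
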