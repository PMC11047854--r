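test_that("layouts nest with ratio-2 spacing and reject impossible wings", {
  lay <- build_layout(domain = 40, resolution = 32, tiers = 4)
  expect_equal(nrow(lay), 4)
  expect_equal(lay$dx, c(1, 2, 4, 8) / 32)   # coarsest 8x the finest
  expect_equal(lay$x_hi[4], 20)
  # strictly nested with clearance
  for (k in 1:3) {
    expect_lt(lay$x_hi[k], lay$x_hi[k + 1])
    expect_lt(lay$z_hi[k], lay$z_hi[k + 1])
  }
  # finest tier contains the wing sweep
  expect_gte(lay$x_hi[1], 2.39 / 0.78 + 1)
  # resolution 32: finest dx = L/32, coarsest L/4
  expect_equal(lay$dx[1], 1 / 32)
  expect_equal(lay$dx[4], 1 / 4)
  expect_error(build_layout(domain = 6, resolution = 16, tiers = 2,
                            wing_reach = 10),
               "not contained|nest")
  # single-tier degenerate layout still builds
  l1 <- build_layout(domain = 12, resolution = 8, tiers = 1, wing_reach = 4)
  expect_equal(nrow(l1), 1)
  # spacing-ratio guard on hand-built tiers
  b1 <- fluid_block(8, 8, 8, 0.7, dx_lab = 1)
  b3 <- fluid_block(8, 8, 8, 0.7, dx_lab = 3)
  expect_error(multiblock_sim(list(b1, b3)), "ratio")
})

test_that("exchange transfers uniform equilibrium and linear fields exactly", {
  # coarse periodic parent, fine child in the middle
  pa <- fluid_block(16, 16, 8, tau = relaxation_time(0.01), dx_lab = 2)
  ch <- fluid_block(13, 13, 9, tau = relaxation_time(0.02), dx_lab = 1,
                    x0 = c(9, 9, 3), ghost = 1L, periodic = rep(FALSE, 3))
  sim <- multiblock_sim(list(ch, pa))
  # uniform equilibrium: exchange is the identity
  set_fields(pa, 0.35, c(0.01, 0, -0.005))
  set_fields(ch, 0.35, c(0.01, 0, -0.005))
  f0 <- ch$f + 0
  exchange(sim, 1)
  expect_equal(ch$f, f0, tolerance = 1e-13)
  # a linear velocity field is reproduced exactly by trilinear interpolation
  lin <- function(b) {
    co <- flapwing:::block_coords(b)
    cbind(1e-3 * co[, 1], -5e-4 * co[, 2], 2e-4 * co[, 3] + 1e-4 * co[, 1])
  }
  set_fields(pa, 1 / 3, lin(pa))
  set_fields(ch, 1 / 3, lin(ch))
  exchange(sim, 1)
  update_macroscopics(ch)
  expect_equal(matrix(ch$u, ch$N, 3), lin(ch), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("two-tier Taylor-Green matches the uniform-grid solution within 1%", {
  nu1 <- 0.02; u0 <- 0.02
  D <- 64; Dz <- 16
  tg <- taylor_green(D, nu1, u0, nz = Dz)
  bu <- tg$block
  bc <- fluid_block(D / 2, D / 2, Dz / 2, tau = relaxation_time(nu1 / 2),
                    dx_lab = 2)
  bf <- fluid_block(35, 35, 11, tau = relaxation_time(nu1), dx_lab = 1,
                    x0 = c(15, 15, 3), ghost = 1L, periodic = rep(FALSE, 3))
  k <- 2 * pi / D
  init_tg <- function(b) {
    co <- flapwing:::block_coords(b)
    x <- k * co[, 1]; y <- k * co[, 2]
    u <- cbind(u0 * cos(x) * sin(y), -u0 * sin(x) * cos(y), 0)
    p <- 1 / 3 - (u0^2 / 4) * (cos(2 * x) + cos(2 * y))
    gu <- matrix(0, b$N, 9)
    gu[, 1] <- -u0 * k * sin(x) * sin(y) * b$dx_lab
    gu[, 2] <- -u0 * k * cos(x) * cos(y) * b$dx_lab
    gu[, 4] <-  u0 * k * cos(x) * cos(y) * b$dx_lab
    gu[, 5] <-  u0 * k * sin(x) * sin(y) * b$dx_lab
    set_fields(b, p, u, gu)
  }
  init_tg(bc); init_tg(bf)
  sim <- multiblock_sim(list(bf, bc))
  nst <- 400
  advance_steps(sim, nst)
  for (s in 1:nst) collide_stream(bu)
  update_macroscopics(bf); update_macroscopics(bu)
  co <- flapwing:::block_coords(bf)
  int <- which(co[, 1] >= 16 & co[, 1] <= 48 & co[, 2] >= 16 & co[, 2] <= 48 &
               co[, 3] >= 4 & co[, 3] <= 12)
  av <- function(b, what) as.numeric(block_array(b, what, interior = FALSE))
  iu <- co[, 1] + D * co[, 2] + D * D * co[, 3] + 1
  d2 <- (av(bf, "ux")[int] - av(bu, "ux")[iu[int]])^2 +
        (av(bf, "uy")[int] - av(bu, "uy")[iu[int]])^2
  r2 <- av(bu, "ux")[iu[int]]^2 + av(bu, "uy")[iu[int]]^2
  expect_lt(sqrt(sum(d2) / sum(r2)), 0.01)
})

test_that("outer boundaries hold a quiescent state and anchor the pressure", {
  b <- fluid_block(14, 14, 14, tau = 0.7, ghost = 1L,
                   periodic = rep(FALSE, 3))
  sim <- multiblock_sim(list(b), fixed_face = "y_hi")
  advance_steps(sim, 500)
  update_macroscopics(b)
  expect_lt(max(abs(b$u)), 1e-12)
  expect_equal(range(b$p), c(1, 1) / 3, tolerance = 1e-12)
  # an offset pressure relaxes towards the fixed-face value
  set_fields(b, 1 / 3 + 5e-3, c(0, 0, 0))
  advance_steps(sim, 3000)
  update_macroscopics(b)
  expect_lt(abs(mean(b$p) - 1 / 3), 1e-3)
  # Neumann ghosts copy the adjacent interior state exactly
  outer_boundary(sim)
  pa <- array(b$p, c(14, 14, 14))
  expect_equal(pa[1, 5:10, 5:10], pa[2, 5:10, 5:10], tolerance = 1e-12)
})

test_that("dt/dx is tier-invariant so lattice velocities carry across tiers", {
  lay <- build_layout(domain = 16, resolution = 8, tiers = 3)
  blocks <- flapwing:::layout_blocks(lay, 0.01)
  # nu_lattice halves per tier: tau_k - 1/2 = (tau_1 - 1/2) / 2^(k-1)
  taus <- sapply(blocks, function(b) b$tau)
  expect_equal(taus[2] - 0.5, (taus[1] - 0.5) / 2)
  expect_equal(taus[3] - 0.5, (taus[1] - 0.5) / 4)
})
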