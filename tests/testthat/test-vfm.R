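test_that("plate descriptors validate their geometry", {
  expect_error(vfm_plate(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), 2, 1),
               "orthogonal")
  expect_error(vfm_plate(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 0, 1),
               "degenerate")
  pl <- vfm_plate(c(1, 2, 3), c(2, 0, 0), c(0, 3, 0), 4, 5)
  expect_equal(pl[1, 4:6], c(1, 0, 0))   # normalized span direction
})

test_that("crossing enumeration agrees with an independent ray-rectangle oracle", {
  b <- fluid_block(16, 16, 16, tau = 0.8)
  lat <- d3q27()
  set.seed(21)
  for (trial in 1:5) {
    # random orientation through the block centre
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    tmp <- rnorm(3); cx <- tmp - sum(tmp * ax) * ax; cx <- cx / sqrt(sum(cx^2))
    o <- c(4, 4, 4) + runif(3)
    span <- 6.3; chord <- 4.1
    pl <- vfm_plate(o, ax, cx, span, chord)
    cr <- locate_intersections(b, pl)
    expect_gt(nrow(cr), 0)
    # oracle: solve the 3x3 system independently for every record
    nrm <- pracma::cross(ax, cx)
    for (r in sample(nrow(cr), min(nrow(cr), 40))) {
      X <- c(cr$i[r], cr$j[r], cr$k[r]) - 1
      e <- lat$e[cr$alpha[r], ]
      A <- cbind(ax, cx, -e)
      sol <- as.numeric(solve(A, X - o))
      expect_gte(sol[1], -1e-9); expect_lte(sol[1], span + 1e-9)
      expect_gte(sol[2], -1e-9); expect_lte(sol[2], chord + 1e-9)
      expect_equal(sol[3], cr$a[r], tolerance = 1e-12)
      xvb <- X + sol[3] * e
      expect_equal(xvb, c(cr$xvb_x[r], cr$xvb_y[r], cr$xvb_z[r]),
                   tolerance = 1e-10, ignore_attr = TRUE)
      # crossing point on the rectangle within 1e-12 of a cell
      d <- sum((xvb - o) * nrm)
      expect_lt(abs(d), 1e-10)
      # the signed normal points towards the fluid node
      expect_gt(sum((X - xvb) * c(cr$n_x[r], cr$n_y[r], cr$n_z[r])), 0)
    }
    expect_equal(cr$a + cr$b, rep(1, nrow(cr)))
  }
  # plate outside the block: empty set
  far <- vfm_plate(c(100, 100, 100), c(1, 0, 0), c(0, 1, 0), 3, 3)
  expect_equal(nrow(locate_intersections(b, far)), 0)
})

test_that("an axis-aligned plate midway between nodes cuts links at a = 1/2", {
  b <- fluid_block(12, 12, 12, tau = 0.8)
  pl <- vfm_plate(c(2, 2, 5.5), c(1, 0, 0), c(0, 1, 0), 7, 7)
  cr <- locate_intersections(b, pl)
  perp <- cr[abs(cr$n_z) == 1 & cr$alpha %in% which(d3q27()$e[, 1] == 0 &
                                                    d3q27()$e[, 2] == 0), ]
  expect_gt(nrow(perp), 0)
  expect_equal(perp$a, rep(0.5, nrow(perp)))
})

test_that("wall-pressure extrapolation is consistent with dp/dn = 0", {
  expect_equal(boundary_pressure(0.4, 0.4, 1, 2), 0.4)     # constant field
  expect_equal(boundary_pressure(1, 4, 1, 2), 0)           # hand arithmetic
  # even quadratic field p(h) = a0 + b0 h^2 is reproduced exactly at the wall
  a0 <- 0.31; b0 <- -0.07
  h1 <- sqrt(3); h2 <- 2 * sqrt(3)
  expect_equal(boundary_pressure(a0 + b0 * h1^2, a0 + b0 * h2^2, h1, h2), a0)
  expect_error(boundary_pressure(1, 2, 1.5, 1.5), "singular")
})

test_that("a resting plate in uniform fluid leaves the state exactly uniform", {
  b <- fluid_block(20, 20, 20, tau = 0.7)
  pl <- vfm_plate(c(5.2, 6.1, 9.7), c(1, 0.15, 0), c(-0.15, 1, 0.2), 8, 5)
  for (s in 1:40) collide_stream(b, pl)
  update_macroscopics(b)
  expect_lt(max(abs(b$u)), 1e-13)
  expect_equal(range(b$p), c(1, 1) / 3, tolerance = 1e-13)
})

test_that("reconstruction follows the internal-ratio extrapolation rule", {
  # a = b = 1/2 must give  p*_eq = 2 p_eq(vb) - p_eq(D)  for the cut link
  lat <- d3q27()
  n <- 10
  b <- fluid_block(n, n, n, tau = 0.8)
  set.seed(5)
  p0 <- 1 / 3 + runif(b$N, -0.01, 0.01)
  set_fields(b, p0, c(0, 0, 0))
  uw <- c(2e-3, -1e-3, 5e-4)
  pl <- vfm_plate(c(-2, -2, 4.5), c(1, 0, 0), c(0, 1, 0), n + 4, n + 4,
                  v0 = uw)
  update_macroscopics(b)
  pfld <- b$p + 0
  fold <- matrix(b$f + 0, b$N, 27)
  reconstruct_boundary_links(b, pl)
  fnew <- matrix(b$f, b$N, 27)
  # check the straight-down link of an interior node just above the plate
  aup <- which(lat$e[, 1] == 0 & lat$e[, 2] == 0 & lat$e[, 3] == 1)
  adn <- which(lat$e[, 1] == 0 & lat$e[, 2] == 0 & lat$e[, 3] == -1)
  id <- 5 + n * 5 + n * n * 5 + 1            # node (5,5,5) 0-based, z=5, a=1/2
  h1 <- sqrt(3); h2 <- 2 * sqrt(3)
  # independent computation of the reconstructed value
  interp_p <- function(z) {
    z0 <- floor(z)
    (1 - (z - z0)) * pfld[5 + n * 5 + n * n * z0 + 1] +
      (z - z0) * pfld[5 + n * 5 + n * n * (z0 + 1) + 1]
  }
  pvb <- boundary_pressure(interp_p(4.5 + h1), interp_p(4.5 + h2), h1, h2)
  eq_dir <- function(a, p, u) {
    eu <- sum(lat$e[a, ] * u)
    lat$w[a] * (p + eu + 1.5 * eu^2 - 0.5 * sum(u^2))
  }
  feq_vb <- eq_dir(aup, pvb, uw)
  feq_D <- eq_dir(aup, pfld[id], c(0, 0, 0))
  fneq_D <- fold[id, aup] - feq_D
  expected <- (2 * feq_vb - feq_D) + (1 - 1 / 0.8) * fneq_D
  expect_equal(fnew[id, aup], expected, tolerance = 1e-12)
  # directions not cut by the plate are untouched
  expect_equal(fnew[id, adn], fold[id, adn])
})

test_that("steady Couette between virtual-flux walls is linear to 1e-8 at tau = 1", {
  n <- 18
  b <- fluid_block(n, n, n, tau = 1, ghost = 1L, periodic = rep(FALSE, 3))
  uw <- 1e-4
  mkpl <- function(z, u) vfm_plate(c(-3, -3, z), c(1, 0, 0), c(0, 1, 0),
                                   span = n + 6, chord = n + 6,
                                   v0 = c(u, 0, 0))
  plates <- rbind(mkpl(4.5, 0), mkpl(12.5, uw))
  sim <- multiblock_sim(list(b), plates_fn = function(tf) plates,
                        fixed_face = "none")
  advance_steps(sim, 6000)
  update_macroscopics(b)
  ux <- block_array(b, "ux", interior = FALSE)
  prof <- apply(ux[5:14, 5:14, ], 3, mean)
  zz <- 0:(n - 1)
  lin <- uw * (zz - 4.5) / 8
  inside <- zz >= 5 & zz <= 12
  expect_lt(max(abs(prof[inside] - lin[inside])), 1e-8)
})

test_that("a closed plate pair holds a pressure difference without leaking", {
  # stationary walls separating two reservoirs at different pressures
  n <- 16
  b <- fluid_block(n, n, n, tau = 0.8, ghost = 1L, periodic = rep(FALSE, 3))
  co <- flapwing:::block_coords(b)
  dp <- 2e-3
  p0 <- ifelse(co[, 3] > 7.5, 1 / 3 + dp, 1 / 3 - dp)
  set_fields(b, p0, c(0, 0, 0))
  pl <- vfm_plate(c(-3, -3, 7.5), c(1, 0, 0), c(0, 1, 0), n + 6, n + 6)
  sim <- multiblock_sim(list(b), plates_fn = function(tf) pl,
                        fixed_face = "none")
  advance_steps(sim, 1000)
  update_macroscopics(b)
  expect_lt(max(abs(b$u)), 1e-6)
  pa <- block_array(b, "p", interior = FALSE)
  expect_gt(mean(pa[, , 12:15]) - mean(pa[, , 2:5]), 1.2 * dp)
})

test_that("momentum exchange equals the exact momentum balance in a periodic box", {
  n <- 24
  b <- fluid_block(n, n, n, tau = 0.8)
  pl <- vfm_plate(c(7, 8, 11.5), c(1, 0, 0), c(0, 1, 0), 9, 7,
                  v0 = c(0, 0, 0.02))
  for (s in 1:50) collide_stream(b, pl)
  lat <- d3q27()
  mom <- function(b) 3 * colSums(matrix(b$f, b$N, 27) %*% lat$e)
  m0 <- mom(b)
  fme <- momentum_exchange_force(b, pl)
  collide_stream(b, pl)
  expect_equal(-fme, mom(b) - m0, tolerance = 1e-10)
})
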