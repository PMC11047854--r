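test_that("cycle averaging is a trapezoidal mean over one period", {
  tt <- seq(0, 3, by = 1 / 200)
  ser <- tibble::tibble(t = tt, a = rep(0.7, length(tt)), b = sin(2 * pi * tt))
  m1 <- cycle_average(ser, 2)
  expect_equal(m1[["a"]], 0.7)
  expect_equal(m1[["b"]], 0, tolerance = 1e-12)   # sinusoid over a period
  expect_error(cycle_average(ser, 5), "cover")
  expect_error(cycle_average(ser[1:2, ], 1), "cover|incomplete")
})

test_that("published per-cycle lift means stabilize by the fifth cycle", {
  cl <- ref_cycle_lift()
  expect_lt(abs(cl$CL_bar[6] - cl$CL_bar[5]) / cl$CL_bar[5], 0.01)
  expect_lt(abs(cl$CL_bar[7] - cl$CL_bar[6]) / cl$CL_bar[6], 0.01)
})

test_that("the ellipse fit recovers exact ellipses", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  # unit circle: AR = 1
  f1 <- ellipse_fit(cos(th), sin(th))
  expect_equal(f1$AR, 1, tolerance = 1e-8)
  expect_equal(f1$centre, c(0, 0), tolerance = 1e-10)
  # axis-aligned ellipse, semi-axes 2 and 1
  f2 <- ellipse_fit(2 * cos(th) + 0.5, sin(th) - 1)
  expect_equal(f2$AR, 2, tolerance = 1e-8)
  expect_equal(f2$theta_el %% 180, 0, tolerance = 1e-6)
  expect_equal(f2$centre, c(0.5, -1), tolerance = 1e-8)
  # rotated + noiseless: parameters to 1e-6 relative
  rot <- 37 * pi / 180
  ll <- 0.21; ls <- 0.07; ctr <- c(0.45, 0.40)
  x <- ctr[1] + ll * cos(th) * cos(rot) - ls * sin(th) * sin(rot)
  y <- ctr[2] + ll * cos(th) * sin(rot) + ls * sin(th) * cos(rot)
  f3 <- ellipse_fit(x, y)
  expect_equal(f3$ll, ll, tolerance = 1e-6)
  expect_equal(f3$ls, ls, tolerance = 1e-6)
  expect_equal(f3$theta_el, 37, tolerance = 1e-4)
  expect_equal(f3$centre, ctr, tolerance = 1e-6)
  expect_error(ellipse_fit(1:10, 2 * (1:10) + 3), "degenerate|elliptical|singular")
  expect_error(ellipse_fit(1:4, c(2, 1, 3, 2)), "at least 6")
  # tidy/glance accessors
  td <- tidy(f3)
  expect_equal(td$estimate[td$term == "AR"], f3$AR)
  expect_equal(glance(f3)$n, 8)
})

test_that("origin-tangency maximizing CL/CPWR matches elementary geometry", {
  # circle centred (2, 0), radius 1: tangency at (1.5, sqrt(3)/2), slope 1/sqrt(3)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  f <- ellipse_fit(2 + cos(th), sin(th))
  sweep <- tibble::tibble(phi_e0 = seq(0, 330, by = 30),
                          CPWR_bar = 2 + cos(th), CL_bar = sin(th),
                          figure_eight = TRUE)
  res <- most_efficient_phase(f, sweep)
  expect_equal(res$slope, 1 / sqrt(3), tolerance = 1e-6)
  expect_equal(unname(res$point), c(1.5, sqrt(3) / 2), tolerance = 1e-6)
  # the tangency lies at parameter 120 deg; phases were laid out at 30 deg
  # per parameter step, so the mapped phase must be near 120
  expect_lt(abs(res$phi_e0 - 120), 15)
  # origin inside the ellipse: no tangent
  f2 <- ellipse_fit(0.2 * cos(th), 0.2 * sin(th))
  expect_error(most_efficient_phase(f2, sweep), "inside")
})

test_that("dimensionalization reproduces the printed force and power identities", {
  w <- physical_wing()
  ref <- ref_dimensional()
  cmp <- ref_sweep_coefficients()
  wo <- cmp[!cmp$figure_eight, ]
  for (i in seq_len(nrow(ref))) {
    row <- wo[wo$re == ref$re[i], ]
    d <- dimensionalize(row$CL_bar, row$CPWR_bar, w, utip = ref$utip[i])
    expect_equal(d$Fz_uN, ref$Fz_uN[i], tolerance = 0.01)
    expect_equal(d$P_uW, ref$P_uW[i], tolerance = 0.012)
    expect_equal(d$Fz_over_P, ref$Fz_over_P[i], tolerance = 0.01)
  }
  expect_equal(dimensionalize(0, 0.3, w)$Fz_uN, 0)
})

test_that("the published sweep table is internally consistent", {
  sw <- ref_sweep_coefficients()
  expect_equal(sw$CL_bar / sw$CPWR_bar, sw$ratio, tolerance = 1e-12)
  # the most efficient motion: phi_e0 = 90 deg at the lowest Reynolds
  # number, 45 deg above it
  best <- sw |>
    dplyr::filter(.data$figure_eight) |>
    dplyr::group_by(.data$re) |>
    dplyr::slice_max(.data$ratio, n = 1)
  expect_equal(best$phi_e0[best$re == 33.5], 90)
  expect_true(all(best$phi_e0[best$re > 33.5] == 45))
  # small initial phases beat the planar motion everywhere
  for (rey in unique(sw$re)) {
    wo <- sw$ratio[!sw$figure_eight & sw$re == rey]
    w8 <- sw[sw$figure_eight & sw$re == rey & sw$phi_e0 <= 90, ]
    expect_true(all(w8$ratio > wo))
  }
})

test_that("ellipse parameters of the published sweeps match the printed fits", {
  sw <- ref_sweep_coefficients()
  ref <- ref_ellipse()
  for (i in seq_len(nrow(ref))) {
    pts <- sw[sw$figure_eight & sw$re == ref$re[i], ]
    f <- ellipse_fit(pts$CPWR_bar, pts$CL_bar)
    expect_lt(abs(f$AR - ref$AR[i]) / ref$AR[i], 0.07)
    expect_lt(abs(f$theta_el - ref$theta_el[i]), 3)
    expect_lt(abs(f$ll - ref$ll[i]) / ref$ll[i], 0.06)
    expect_lt(abs(f$ls - ref$ls[i]) / ref$ls[i], 0.06)
    expect_lt(max(abs(f$centre - c(ref$centre_x[i], ref$centre_y[i]))), 0.01)
  }
})

test_that("the most efficient phase drifts towards zero as Reynolds number grows", {
  sw <- ref_sweep_coefficients()
  phis <- sapply(unique(sw$re), function(rey) {
    pts <- sw[sw$figure_eight & sw$re == rey, ]
    f <- ellipse_fit(pts$CPWR_bar, pts$CL_bar)
    ph <- most_efficient_phase(f, pts)$phi_e0
    # phases near 360 are small negative phases
    if (ph > 180) ph - 360 else ph
  })
  expect_true(all(diff(phis) < 0))
  expect_true(all(phis >= 0 & phis <= 90))
})
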