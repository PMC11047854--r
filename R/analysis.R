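#' Mean of a time series over one flapping cycle
#'
#' Trapezoidal mean over `t` in `[cycle - 1, cycle]` (cycle counting from 1).
#' The default reporting cycle of the study protocol is the sixth of seven;
#' pass `cycle` explicitly for scaled-down runs.
#'
#' @param series tibble with a time column `t` in cycle units (e.g. the
#'   `$forces` element of a [simulate_flapping()] run) and numeric value
#'   columns.
#' @param cycle which cycle to average (1-based).
#' @param vars columns to average (default: every numeric column but `t`).
#' @return named numeric vector of cycle means.
#' @export
cycle_average <- function(series, cycle = 6, vars = NULL) {
  stopifnot(is.data.frame(series), "t" %in% names(series))
  t0 <- cycle - 1
  t1 <- cycle
  dt <- stats::median(diff(series$t))
  if (!is.finite(dt)) dt <- 0
  if (max(series$t) < t1 - 2 * dt - 1e-9 || min(series$t) > t0 + 1e-9)
    stop("series does not cover cycle ", cycle)
  sel <- series[series$t >= t0 - 1e-9 & series$t <= t1 + 1e-9, , drop = FALSE]
  if (nrow(sel) < 4) stop("incomplete cycle: too few samples")
  if (is.null(vars))
    vars <- setdiff(names(sel)[vapply(sel, is.numeric, logical(1))], "t")
  tt <- sel$t
  w <- diff(tt)
  vapply(vars, function(v) {
    y <- sel[[v]]
    sum(w * (y[-1] + y[-length(y)]) / 2) / sum(w)
  }, numeric(1))
}

#' Compare motions with and without the figure-eight elevation
#'
#' Runs the solver twice -- once with the oscillating elevation angle and
#' once with `theta_e = 0` -- and tabulates cycle-averaged lift, thrust and
#' power coefficients plus the lift-to-power ratio.
#'
#' @param config a [flapwing_config()].
#' @param cycle reporting cycle (defaults to the run's last cycle).
#' @param ... overrides passed to [simulate_flapping()] (resolution, domain,
#'   tiers, cycles, reynolds, ...).
#' @return tibble shaped like the study's motion-comparison table, plus the
#'   run objects as an attribute `runs`.
#' @export
run_comparison <- function(config = flapwing_config(), cycle = NULL, ...) {
  with8 <- simulate_flapping(config, figure_eight = TRUE, ...)
  without <- simulate_flapping(config, figure_eight = FALSE, ...)
  cyc <- cycle %||% with8$cycles
  rows <- lapply(list(with_figure_eight = with8,
                      without_figure_eight = without), function(r) {
    cm <- cycle_average(r$forces, cycle = cyc, vars = c("CL", "CT", "CPWR"))
    tibble::tibble(CL_bar = cm[["CL"]], CT_bar = cm[["CT"]],
                   CPWR_bar = cm[["CPWR"]],
                   ratio = cm[["CL"]] / cm[["CPWR"]])
  })
  out <- dplyr::bind_rows(rows, .id = "motion")
  attr(out, "runs") <- list(with8 = with8, without = without)
  out
}

#' Sweep the elevation initial phase and Reynolds number
#'
#' Runs the solver over a grid of `phi_e0` values (plus the planar
#' without-figure-eight motion) and Reynolds numbers, reporting cycle
#' averages per run.
#'
#' @param config a [flapwing_config()].
#' @param phi_e0 phases in degrees (default: the experiment block).
#' @param re Reynolds numbers (default: the experiment block).
#' @param include_without also run the planar motion at each `re`?
#' @param cycle reporting cycle (default: last).
#' @param ... overrides passed to [simulate_flapping()].
#' @return tibble of class `sweep_result` with columns `phi_e0`, `re`,
#'   `figure_eight`, `CL_bar`, `CT_bar`, `CPWR_bar`, `ratio`.
#' @export
sweep_phases <- function(config = flapwing_config(), phi_e0 = NULL, re = NULL,
                         include_without = TRUE, cycle = NULL, ...) {
  phi_e0 <- phi_e0 %||% config$experiment$phi_e0
  re <- re %||% config$experiment$re
  grid <- tidyr::expand_grid(re = re, phi_e0 = phi_e0)
  one <- function(phi, rey, fig8) {
    run <- simulate_flapping(config, phi_e0 = if (fig8) phi else NULL,
                             figure_eight = fig8, reynolds = rey, ...)
    cm <- cycle_average(run$forces, cycle = cycle %||% run$cycles,
                        vars = c("CL", "CT", "CPWR"))
    tibble::tibble(phi_e0 = if (fig8) phi else NA_real_, re = rey,
                   figure_eight = fig8,
                   CL_bar = cm[["CL"]], CT_bar = cm[["CT"]],
                   CPWR_bar = cm[["CPWR"]], ratio = cm[["CL"]] / cm[["CPWR"]])
  }
  rows <- purrr::pmap(grid, function(re, phi_e0) one(phi_e0, re, TRUE))
  if (include_without)
    rows <- c(rows, lapply(re, function(rey) one(NA, rey, FALSE)))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Direct least-squares ellipse fit
#'
#' Algebraic conic fit constrained to an ellipse (numerically stable
#' variant of the direct least-squares method), applied to the cloud of
#' `(CPWR_bar, CL_bar)` points of the eight figure-eight motions.  Returns
#' the centre, the semi-axis lengths `ll >= ls`, the inclination of the
#' long axis from the x (power) axis, and the aspect ratio `AR = ll / ls`.
#'
#' @param x,y point coordinates (at least 6 points), or `x` a two-column
#'   matrix / data frame (columns `CPWR_bar`, `CL_bar` or the first two).
#' @return object of class `ellipse_fit`.
#' @export
ellipse_fit <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.data.frame(x)
    if (all(c("CPWR_bar", "CL_bar") %in% names(x))) {
      y <- x$CL_bar; x <- x$CPWR_bar
    } else {
      y <- x[[2]]; x <- x[[1]]
    }
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 6) stop("need at least 6 points for a conic fit")
  # centre and scale for conditioning
  mx <- mean(x); my <- mean(y); sc <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(sc) || sc == 0) stop("degenerate point set")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T2 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate/collinear points: conic fit is singular"))
  M <- S1 + S2 %*% T2
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  ok <- which(apply(Re(ev$vectors), 2, function(v)
    4 * v[1] * v[3] - v[2]^2 > 0))
  if (length(ok) == 0) stop("no elliptical solution for these points")
  a1 <- Re(ev$vectors[, ok[1]])
  coef_s <- c(a1, as.numeric(T2 %*% a1))       # A B C D E F (scaled frame)
  # undo the normalization: substitute xs = (x - mx)/sc etc.
  A <- coef_s[1] / sc^2
  B <- coef_s[2] / sc^2
  C <- coef_s[3] / sc^2
  D <- coef_s[4] / sc - 2 * A * mx - B * my
  E <- coef_s[5] / sc - 2 * C * my - B * mx
  F <- coef_s[6] + A * mx^2 + B * mx * my + C * my^2 -
    coef_s[4] * mx / sc - coef_s[5] * my / sc
  conic <- c(A = A, B = B, C = C, D = D, E = E, F = F)
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E))
  Q2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  M0 <- matrix(c(F, D / 2, E / 2, D / 2, A, B / 2, E / 2, B / 2, C), 3, 3)
  eg <- eigen(Q2, symmetric = TRUE)
  axis_len <- sqrt(pmax(0, -det(M0) / (det(Q2) * eg$values)))
  iM <- which.max(axis_len)
  ll <- axis_len[iM]; ls <- min(axis_len)
  vM <- eg$vectors[, iM]
  th <- atan2(vM[2], vM[1]) * 180 / pi
  th <- th %% 180
  structure(list(centre = as.numeric(ctr), ll = ll, ls = ls,
                 theta_el = th, AR = ll / ls, conic = conic,
                 n = length(x), points = cbind(x = x, y = y)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit: centre (%.3f, %.3f), ll=%.4f ls=%.4f, theta=%.1f deg, AR=%.3f>\n",
    x$centre[1], x$centre[2], x$ll, x$ls, x$theta_el, x$AR))
  invisible(x)
}

#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    term = c("centre_x", "centre_y", "ll", "ls", "theta_el", "AR"),
    estimate = c(x$centre, x$ll, x$ls, x$theta_el, x$AR))
}

#' @export
glance.ellipse_fit <- function(x, ...) {
  tibble::tibble(AR = x$AR, theta_el = x$theta_el, n = x$n)
}

# eccentric-anomaly parameter of points relative to a fitted ellipse
ellipse_parameter <- function(fit, x, y) {
  th <- fit$theta_el * pi / 180
  xr <- cos(th) * (x - fit$centre[1]) + sin(th) * (y - fit$centre[2])
  yr <- -sin(th) * (x - fit$centre[1]) + cos(th) * (y - fit$centre[2])
  atan2(yr / fit$ls, xr / fit$ll)
}

#' Most efficient elevation phase from the ellipse tangency
#'
#' The most efficient motion maximizes `CL_bar / CPWR_bar`, i.e. the slope
#' of the line from the origin; on the fitted ellipse this is the upper
#' tangent line through the origin.  The tangency point is mapped to an
#' elevation phase by interpolating (proportionally in the ellipse
#' parameter) between the two nearest swept phases.
#'
#' @param fit an [ellipse_fit()] of the `(CPWR_bar, CL_bar)` points.
#' @param sweep data with `phi_e0`, `CPWR_bar`, `CL_bar` for the swept
#'   figure-eight motions (e.g. a `sweep_result` at one Reynolds number).
#' @return list with `phi_e0` (deg), the tangency `point`, and the maximal
#'   `slope`.
#' @export
most_efficient_phase <- function(fit, sweep) {
  cf <- fit$conic
  A <- cf[["A"]]; B <- cf[["B"]]; C <- cf[["C"]]
  D <- cf[["D"]]; E <- cf[["E"]]; F <- cf[["F"]]
  # tangency of y = m x:  (E^2 - 4 F C) m^2 + (2 D E - 4 F B) m + D^2 - 4 F A = 0
  qa <- E^2 - 4 * F * C
  qb <- 2 * D * E - 4 * F * B
  qc <- D^2 - 4 * F * A
  disc <- qb^2 - 4 * qa * qc
  if (disc < 0 || abs(qa) < 1e-300)
    stop("origin lies inside the fitted ellipse: no tangent line exists")
  mr <- sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
  m <- mr[2]                                   # greatest slope
  xt <- -(D + E * m) / (2 * (A + B * m + C * m^2))
  yt <- m * xt
  tt <- ellipse_parameter(fit, xt, yt)
  keep <- !is.na(sweep$phi_e0)
  if (!is.null(sweep$figure_eight)) keep <- keep & sweep$figure_eight
  sw <- sweep[keep, , drop = FALSE]
  tp <- ellipse_parameter(fit, sw$CPWR_bar, sw$CL_bar)
  # bracket tt between adjacent swept parameters on the circle
  dif <- (tp - tt + pi) %% (2 * pi) - pi
  i1 <- which.min(abs(dif))
  opp <- dif * dif[i1] < 0
  if (!any(opp)) {
    phi <- sw$phi_e0[i1]
  } else {
    i2 <- which(opp)[which.min(abs(dif[opp]))]
    w <- abs(dif[i1]) / (abs(dif[i1]) + abs(dif[i2]))
    dphi <- ((sw$phi_e0[i2] - sw$phi_e0[i1] + 180) %% 360) - 180
    phi <- (sw$phi_e0[i1] + w * dphi) %% 360
  }
  list(phi_e0 = as.numeric(phi), point = c(x = xt, y = yt), slope = m)
}

#' Dimensional lift force and power from cycle-averaged coefficients
#'
#' Inverts the coefficient definitions with the combined two-wing reference
#' area `S = 2 Cm R`: `Fz = CL q S`, `P = CPWR q utip S` with
#' `q = rho utip^2 / 2`, and `Fz / P = (CL / CPWR) / utip`.
#'
#' @param CL_bar,CPWR_bar cycle-averaged lift and power coefficients.
#' @param wing a [physical_wing()].
#' @param utip tip speed override (m/s), e.g. when sweeping Reynolds number
#'   at fixed geometry; defaults to the wing's mean tip speed.
#' @return tibble with `Fz_uN` (micro-newtons), `P_uW` (micro-watts) and
#'   `Fz_over_P`.
#' @export
dimensionalize <- function(CL_bar, CPWR_bar, wing = physical_wing(),
                           utip = NULL) {
  utip <- utip %||% wing$mean_tip_speed
  q <- 0.5 * wing$air_density * utip^2 * wing$area_ref
  tibble::tibble(
    Fz_uN = CL_bar * q * 1e6,
    P_uW = CPWR_bar * q * utip * 1e6,
    Fz_over_P = ifelse(CPWR_bar == 0, NA_real_, (CL_bar / CPWR_bar) / utip))
}
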