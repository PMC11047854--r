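#' Aerodynamic surface loads on plates
#'
#' Traction integration over both faces of each plate: the pressure part
#' uses the same two-probe wall-pressure extrapolation as the boundary
#' condition, the viscous part a one-sided quadratic fit of the tangential
#' velocity through the wall value and the two probes.  Power is
#' `sum(f_local . u_local)` with `u_local` the wall velocity at each panel.
#'
#' @param b a [fluid_block()] with current macroscopic fields.
#' @param plates plate matrix ([vfm_plate()] rows) in node coordinates.
#' @param h1,h2 probe distances (cells).
#' @param pref reference pressure subtracted before integration.
#' @return tibble, one row per plate: pressure/viscous force components,
#'   power, and no-slip residual diagnostics (lattice units).
#' @export
surface_forces <- function(b, plates, h1 = sqrt(3), h2 = 2 * sqrt(3),
                           pref = 1 / 3) {
  if (is.null(plates) || nrow(plates) == 0) {
    warning("no plates inside the block: zero force record")
    return(tibble::tibble(plate = integer(), Fx = numeric()))
  }
  update_macroscopics(b)
  nu <- (b$tau - 0.5) / 3
  m <- .cpp_plate_forces(b$p, b$u, b$nx, b$ny, b$nz, plates, h1, h2, pref, nu)
  tibble::tibble(
    plate = seq_len(nrow(m)),
    Fx = m[, 1] + m[, 4], Fy = m[, 2] + m[, 5], Fz = m[, 3] + m[, 6],
    Fx_p = m[, 1], Fy_p = m[, 2], Fz_p = m[, 3],
    Fx_tau = m[, 4], Fy_tau = m[, 5], Fz_tau = m[, 6],
    power = m[, 7], resid_mean = m[, 8], resid_max = m[, 9],
    n_panels = as.integer(m[, 10])
  )
}

#' Aerodynamic coefficients from a force record
#'
#' `CL = Fz / (q S)`, `CT = Fy / (q S)`, `CPWR = P / (q U S)` with dynamic
#' pressure `q = rho u_tip^2 / 2` and `S` the combined planform area of both
#' wings (`2 Cm R`).  Works in any consistent unit system; pass lattice
#' forces with lattice references or physical forces with physical
#' references.
#'
#' @param Fz,Fy,power force components and aerodynamic power (power is the
#'   work done on the fluid, positive in normal operation).
#' @param u_tip reference (mean tip) speed.
#' @param area combined reference area of both wings.
#' @param rho fluid density (1 in lattice units).
#' @return tibble with `CL`, `CT`, `CPWR`.
#' @export
coefficients <- function(Fz, Fy, power, u_tip, area, rho = 1) {
  if (any(u_tip <= 0)) stop("u_tip must be positive")
  q <- 0.5 * rho * u_tip^2 * area
  tibble::tibble(CL = Fz / q, CT = Fy / q, CPWR = power / (q * u_tip))
}

#' Velocity-gradient, vorticity and strain tensors of a block
#'
#' Central differences in the interior, one-sided at block edges; the
#' decomposition `D = Omega + S` with `Omega = (D - D^T)/2` (antisymmetric)
#' and `S = (D + D^T)/2` (symmetric) is exact by construction.
#'
#' @param b a [fluid_block()].
#' @return list of class `flow_diagnostics` with the interior dimensions
#'   `dim`, arrays `D` (i, j slot as `D[[i]][[j]]` = `d u_j / d x_i`),
#'   velocity arrays `u`, vorticity components `omega`, and the tensor
#'   norms needed for the Q-criterion.
#' @export
velocity_gradients <- function(b) {
  update_macroscopics(b)
  ua <- list(block_array(b, "ux"), block_array(b, "uy"), block_array(b, "uz"))
  dn <- dim(ua[[1]])
  d1 <- function(a, axis) {
    n <- dim(a)[axis]
    if (n < 2) return(array(0, dim(a)))
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    idx <- function(v) switch(axis,
      a[v, , , drop = FALSE], a[, v, , drop = FALSE], a[, , v, drop = FALSE])
    hs <- array((ip - im)[slice.index(a, axis)], dn)  # 2 inside, 1 at edges
    array((idx(ip) - idx(im)) / hs, dn)
  }
  D <- lapply(1:3, function(i) lapply(1:3, function(j) d1(ua[[j]], i)))
  omega <- list(D[[2]][[3]] - D[[3]][[2]],
                D[[3]][[1]] - D[[1]][[3]],
                D[[1]][[2]] - D[[2]][[1]])
  structure(list(dim = dn, u = ua, D = D, omega = omega, dx = b$dx_lab),
            class = "flow_diagnostics")
}

#' Q-criterion and normalized helicity density
#'
#' `Q = (||Omega||^2 - ||S||^2) / 2` (positive in vortex cores), normalized
#' as `Q* = Q / (U/L)^2`; helicity density `hd = u . omega` normalized as
#' `hd* = u . omega / (|u| |omega|)` in `[-1, 1]`, reported as 0 (with a
#' mask) where `|u| |omega| = 0`.
#'
#' @param diag a [velocity_gradients()] result.
#' @param U,L reference speed and length in the same units as the block
#'   fields (lattice velocity and cells by default).
#' @param eps magnitude threshold below which `hd*` is masked.
#' @return list with arrays `Q`, `Q_star`, `hd`, `hd_star` and the logical
#'   `hd_mask` (TRUE where `hd*` is defined).
#' @export
q_and_helicity <- function(diag, U = 1, L = 1, eps = 1e-12) {
  D <- diag$D
  n2o <- n2s <- array(0, diag$dim)
  for (i in 1:3) for (j in 1:3) {
    o <- (D[[i]][[j]] - D[[j]][[i]]) / 2
    s <- (D[[i]][[j]] + D[[j]][[i]]) / 2
    n2o <- n2o + o^2
    n2s <- n2s + s^2
  }
  Q <- (n2o - n2s) / 2
  hd <- diag$u[[1]] * diag$omega[[1]] + diag$u[[2]] * diag$omega[[2]] +
    diag$u[[3]] * diag$omega[[3]]
  mag <- sqrt(diag$u[[1]]^2 + diag$u[[2]]^2 + diag$u[[3]]^2) *
    sqrt(diag$omega[[1]]^2 + diag$omega[[2]]^2 + diag$omega[[3]]^2)
  mask <- mag > eps
  hds <- array(0, diag$dim)
  hds[mask] <- hd[mask] / mag[mask]
  list(Q = Q, Q_star = Q / (U / L)^2, hd = hd, hd_star = hds, hd_mask = mask)
}
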