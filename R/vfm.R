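#' Describe a rigid rectangular plate for the virtual flux method
#'
#' The plate lives in a block's node-index coordinates (grid spacing 1):
#' `x(s, c) = origin + s * span_hat + c * chord_hat`, `s` in `[0, span]`,
#' `c` in `[0, chord]`.  Wall velocity of a material point is
#' `u(x) = v0 + W (x - origin)` in lattice units (cells per step).
#'
#' @param origin length-3 position of the (root, leading-corner) of the
#'   rectangle in node coordinates.
#' @param span_hat,chord_hat unit vectors along the two sides.
#' @param span,chord side lengths in cells.
#' @param v0 translational velocity of the origin (cells/step).
#' @param W 3 x 3 angular-velocity matrix (1/step), `u = v0 + W (x - origin)`.
#' @return a 1 x 23 numeric matrix; rows from several calls can be
#'   `rbind()`-ed into a plate set.
#' @export
vfm_plate <- function(origin, span_hat, chord_hat, span, chord,
                      v0 = c(0, 0, 0), W = matrix(0, 3, 3)) {
  span_hat <- span_hat / sqrt(sum(span_hat^2))
  chord_hat <- chord_hat / sqrt(sum(chord_hat^2))
  if (abs(sum(span_hat * chord_hat)) > 1e-8)
    stop("span_hat and chord_hat must be orthogonal")
  if (span <= 0 || chord <= 0) stop("degenerate plate (zero area)")
  matrix(c(origin, span_hat, chord_hat, span, chord, v0, t(W)), nrow = 1)
}

#' Locate lattice links cut by plates
#'
#' Every node pair along any of the 26 nonzero lattice directions whose
#' segment crosses a finite rectangle yields one record per side of the
#' plate; `a` is the distance fraction from the fluid node to the crossing
#' and the normal is signed towards that node's side.
#'
#' @param b a [fluid_block()].
#' @param plates plate matrix ([vfm_plate()] rows).
#' @return tibble with node index/coordinates, direction, internal ratio
#'   `a` (and `b = 1 - a`), crossing point `xvb_*`, signed normal `n_*` and
#'   wall velocity `uvb_*`.
#' @export
locate_intersections <- function(b, plates) {
  m <- .cpp_vfm_crossings(plates, b$nx, b$ny, b$nz)
  id0 <- as.integer(m[, 1]) - 1L
  tibble::tibble(
    node = as.integer(m[, 1]),
    i = id0 %% b$nx + 1L,
    j = (id0 %/% b$nx) %% b$ny + 1L,
    k = id0 %/% (b$nx * b$ny) + 1L,
    alpha = as.integer(m[, 2]),
    a = m[, 3], b = 1 - m[, 3],
    xvb_x = m[, 4], xvb_y = m[, 5], xvb_z = m[, 6],
    n_x = m[, 7], n_y = m[, 8], n_z = m[, 9],
    uvb_x = m[, 10], uvb_y = m[, 11], uvb_z = m[, 12]
  )
}

#' Wall pressure from two normal probes
#'
#' Second-order extrapolation consistent with a zero normal pressure
#' gradient at the wall:
#' `p_vb = (h2^2 p1 - h1^2 p2) / (h2^2 - h1^2)`.
#'
#' @param p1,p2 pressures interpolated at distances `h1`, `h2` along the
#'   wall normal.
#' @param h1,h2 probe distances (`h1 != h2`).
#' @export
boundary_pressure <- function(p1, p2, h1, h2) {
  if (any(h1 == h2)) stop("h1 = h2: extrapolation is singular")
  (h2^2 * p1 - h1^2 * p2) / (h2^2 - h1^2)
}

#' Rebuild distributions at boundary-cut links
#'
#' Applies the virtual-flux reconstruction to the block's current
#' distributions: for each cut link the equilibrium at the crossing point is
#' formed from the no-slip wall velocity and the extrapolated wall pressure,
#' extrapolated linearly past the wall (internal ratio `a:b`), and combined
#' with the nonequilibrium part copied from the fluid-side anchor node (the
#' next node inward when `a < 1/2`).  Normally this runs inside
#' [collide_stream()]; calling it directly is useful for steady-state or
#' diagnostic work.
#'
#' @inheritParams collide_stream
#' @return number of link reconstructions applied, invisibly.
#' @export
reconstruct_boundary_links <- function(b, plates, h1 = sqrt(3),
                                       h2 = 2 * sqrt(3), pref = 1 / 3) {
  update_macroscopics(b)
  cr <- .cpp_vfm_crossings(plates, b$nx, b$ny, b$nz)
  n <- .cpp_vfm_apply(b$f, b$f, b$p, b$u, b$nx, b$ny, b$nz, b$tau,
                      plates, cr, h1, h2, pref)
  invisible(n)
}

#' Momentum-exchange force over one trial step
#'
#' Independent force estimate: the momentum transferred across all cut links
#' during one collide-stream-reconstruct step, summed in lattice units.  The
#' block is not modified (the step runs on copies).  Serves as a
#' cross-check of the traction integration in [surface_forces()].
#'
#' @inheritParams collide_stream
#' @return length-3 force vector (lattice units).
#' @export
momentum_exchange_force <- function(b, plates, h1 = sqrt(3), h2 = 2 * sqrt(3),
                                    pref = 1 / 3) {
  f_old <- b$f + 0          # force copies
  f_new <- b$f + 0
  p <- b$p + 0; u <- b$u + 0
  cr <- .cpp_vfm_crossings(plates, b$nx, b$ny, b$nz)
  .cpp_step(f_old, f_new, p, u, b$nx, b$ny, b$nz, b$tau, b$periodic)
  .cpp_vfm_apply(f_old, f_new, p, u, b$nx, b$ny, b$nz, b$tau,
                 plates, cr, h1, h2, pref)
  as.numeric(.cpp_momentum_exchange(f_old, f_new, p, u, b$nx, b$ny, b$nz,
                                    b$tau, plates, pref))
}
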