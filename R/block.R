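#' Create one Cartesian fluid block
#'
#' A block is a mutable environment holding the 27 pressure-distribution
#' planes, the macroscopic pressure/velocity fields of the most recent
#' pre-step state, its relaxation time and its placement in the lab frame.
#' Distributions are stored in the block's own lattice units
#' (`dx = dt = c = 1`); `dx_lab` records the physical cell size in units of
#' the reference length so tiers of different spacing can be nested.
#'
#' @param nx,ny,nz number of nodes per axis (including any ghost shell).
#' @param tau BGK relaxation time (> 1/2).
#' @param dx_lab cell size in lab units (reference chord lengths).
#' @param x0 lab coordinates of node (1,1,1).
#' @param ghost ghost-shell width in cells (0 for fully periodic blocks).
#' @param periodic logical length 3.
#' @param p0 initial uniform pressure (defaults to `1/3 = rho0 cs^2`).
#' @return an environment of class `fluid_block`.
#' @export
fluid_block <- function(nx, ny, nz, tau, dx_lab = 1, x0 = c(0, 0, 0),
                        ghost = 0L, periodic = c(TRUE, TRUE, TRUE),
                        p0 = 1 / 3) {
  stopifnot(nx >= 2, ny >= 2, nz >= 2, tau > 0.5)
  if (!all(periodic) && ghost < 1L)
    stop("non-periodic blocks need a ghost shell (ghost >= 1)")
  b <- new.env(parent = emptyenv())
  b$nx <- as.integer(nx); b$ny <- as.integer(ny); b$nz <- as.integer(nz)
  b$N <- b$nx * b$ny * b$nz
  b$tau <- tau
  b$dx_lab <- dx_lab
  b$x0 <- x0
  b$ghost <- as.integer(ghost)
  b$periodic <- periodic
  b$lattice <- d3q27()
  w <- b$lattice$w
  b$f <- rep(w * p0, each = b$N)        # uniform rest state
  b$f_alt <- b$f + 0
  b$p <- rep(p0, b$N)
  b$u <- numeric(3 * b$N)
  b$steps <- 0L
  class(b) <- "fluid_block"
  b
}

#' @export
print.fluid_block <- function(x, ...) {
  cat(sprintf("<fluid_block %d x %d x %d, tau = %.5f, dx = %g, ghost = %d>\n",
              x$nx, x$ny, x$nz, x$tau, x$dx_lab, x$ghost))
  invisible(x)
}

# lab coordinates of every node, as an N x 3 matrix (ordered i fastest)
block_coords <- function(b) {
  g <- expand.grid(i = seq_len(b$nx), j = seq_len(b$ny), k = seq_len(b$nz))
  cbind(b$x0[1] + (g$i - 1) * b$dx_lab,
        b$x0[2] + (g$j - 1) * b$dx_lab,
        b$x0[3] + (g$k - 1) * b$dx_lab)
}

#' Set the macroscopic state of a block
#'
#' Distributions are rebuilt at equilibrium; when the velocity-gradient
#' tensor is supplied the first-order nonequilibrium part
#' `p_a^neq = -3 tau w_a (e_a e_a : grad u)` is added, which removes the
#' startup transient of an analytically initialized flow.
#'
#' @param b a [fluid_block()].
#' @param p pressure per node (length N or scalar).
#' @param u velocity per node (N x 3 matrix, or length-3 vector recycled).
#' @param grad_u optional N x 9 matrix of `d u_j / d x_i` (column order
#'   11,21,31,12,22,32,13,23,33) in lattice units.
#' @export
set_fields <- function(b, p, u, grad_u = NULL) {
  N <- b$N
  p <- rep_len(p, N)
  if (is.null(dim(u))) u <- matrix(u, nrow = N, ncol = 3, byrow = TRUE)
  f <- equilibrium(p, u, b$lattice)
  if (!is.null(grad_u)) {
    e <- b$lattice$e
    E9 <- matrix(0, 27, 9)
    m <- 0
    for (j in 1:3) for (i in 1:3) { m <- m + 1; E9[, m] <- e[, i] * e[, j] }
    fneq <- -3 * b$tau * sweep(grad_u %*% t(E9), 2, b$lattice$w, `*`)
    f <- f + fneq
  }
  b$f <- as.numeric(f)                  # column-major => direction planes
  b$f_alt <- b$f + 0
  b$p <- p
  b$u <- as.numeric(u)
  invisible(b)
}

#' Advance a block one lattice step (BGK collide + stream)
#'
#' Collision uses `p_a(t+dt, x+e_a) = p_a^eq + (1 - 1/tau) p_a^neq`; the
#' macroscopic fields of the pre-step state are cached on the block.  When
#' `plates` is given, links cut by the plates are rebuilt with the virtual
#' flux method after streaming (see [vfm_plate()]).
#'
#' @param b a [fluid_block()].
#' @param plates optional plate matrix from [vfm_plate()] (rows bound
#'   together), in the block's node coordinates.
#' @param h1,h2 normal probe distances in cells for the wall-pressure
#'   extrapolation.
#' @param pref reference pressure subtracted in force evaluation.
#' @return the block, invisibly.
#' @export
collide_stream <- function(b, plates = NULL, h1 = sqrt(3), h2 = 2 * sqrt(3),
                           pref = 1 / 3) {
  .cpp_step(b$f, b$f_alt, b$p, b$u, b$nx, b$ny, b$nz, b$tau, b$periodic)
  if (!is.null(plates) && nrow(plates) > 0) {
    b$crossings <- .cpp_vfm_crossings(plates, b$nx, b$ny, b$nz)
    .cpp_vfm_apply(b$f, b$f_alt, b$p, b$u, b$nx, b$ny, b$nz, b$tau,
                   plates, b$crossings, h1, h2, pref)
  }
  tmp <- b$f; b$f <- b$f_alt; b$f_alt <- tmp
  b$steps <- b$steps + 1L
  if (!is.finite(b$f[b$N %/% 2 + 1L]))
    stop("solver diverged (non-finite distribution) at step ", b$steps)
  invisible(b)
}

#' Refresh the cached macroscopic fields from the current distributions
#' @param b a [fluid_block()].
#' @export
update_macroscopics <- function(b) {
  .cpp_macro(b$f, b$p, b$u, b$nx, b$ny, b$nz)
  invisible(b)
}

#' Extract a macroscopic field as an array
#'
#' @param b a [fluid_block()].
#' @param what `"p"`, `"ux"`, `"uy"`, `"uz"`, or `"speed"`.
#' @param interior drop the ghost shell?
#' @return 3-D numeric array.
#' @export
block_array <- function(b, what = c("p", "ux", "uy", "uz", "speed"),
                        interior = TRUE) {
  what <- match.arg(what)
  N <- b$N
  v <- switch(what,
    p = b$p,
    ux = b$u[seq_len(N)],
    uy = b$u[N + seq_len(N)],
    uz = b$u[2 * N + seq_len(N)],
    speed = sqrt(b$u[seq_len(N)]^2 + b$u[N + seq_len(N)]^2 +
                 b$u[2 * N + seq_len(N)]^2)
  )
  a <- array(v, c(b$nx, b$ny, b$nz))
  if (interior && b$ghost > 0) {
    g <- b$ghost
    a <- a[(g + 1):(b$nx - g), (g + 1):(b$ny - g), (g + 1):(b$nz - g),
           drop = FALSE]
  }
  a
}

#' Decaying Taylor-Green vortex fixture
#'
#' A planar Taylor-Green vortex embedded in a periodic cube:
#' `u = u0 (cos kx sin ky, -sin kx cos ky, 0)` with
#' `p = p0 - (u0^2/4)(cos 2kx + cos 2ky) exp(-4 nu k^2 t)`.  This is an exact
#' Navier-Stokes solution; kinetic energy decays as `exp(-4 nu k^2 t)`.
#'
#' @param n nodes per side in x and y.
#' @param nu lattice viscosity.
#' @param u0 velocity amplitude in lattice units.
#' @param nz nodes along z (the solution is z-invariant).
#' @return list with the initialized periodic `block`, the wavenumber `k`,
#'   and `analytic(t)` returning the exact fields at lattice time `t`.
#' @export
taylor_green <- function(n, nu, u0 = 0.02, nz = 4L) {
  tau <- relaxation_time(nu)
  b <- fluid_block(n, n, nz, tau)
  k <- 2 * pi / n
  co <- block_coords(b)
  x <- k * co[, 1]; y <- k * co[, 2]
  analytic <- function(t) {
    d <- exp(-2 * nu * k^2 * t)
    list(
      u = cbind(u0 * d * cos(x) * sin(y), -u0 * d * sin(x) * cos(y), 0),
      p = 1 / 3 - (u0^2 / 4) * (cos(2 * x) + cos(2 * y)) * d^2,
      decay = d
    )
  }
  a0 <- analytic(0)
  # velocity gradients of the initial field, for a transient-free start
  gu <- matrix(0, b$N, 9)
  gu[, 1] <- -u0 * k * sin(x) * sin(y)        # du/dx
  gu[, 2] <- -u0 * k * cos(x) * cos(y)        # dv/dx
  gu[, 4] <-  u0 * k * cos(x) * cos(y)        # du/dy
  gu[, 5] <-  u0 * k * sin(x) * sin(y)        # dv/dy
  set_fields(b, a0$p, a0$u, grad_u = gu)
  list(block = b, k = k, nu = nu, u0 = u0, analytic = analytic)
}

#' Kinetic energy of a block (lattice units, interior nodes)
#' @param b a [fluid_block()].
#' @export
kinetic_energy <- function(b) {
  update_macroscopics(b)
  ux <- block_array(b, "ux"); uy <- block_array(b, "uy")
  uz <- block_array(b, "uz")
  0.5 * sum(ux^2 + uy^2 + uz^2)
}
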