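#' The D3Q27 lattice model
#'
#' Twenty-seven discrete velocities on the unit cube: the rest particle,
#' 6 face, 12 edge and 8 corner directions, with weights 8/27, 2/27, 1/54 and
#' 1/216.  The lattice speed is `c = 1` and the sound speed `cs = c / sqrt(3)`.
#'
#' @return A list of class `lattice_model` with elements `e` (27 x 3 integer
#'   matrix of velocities), `w` (27 weights), `opp` (index of the opposite
#'   direction), `c` and `cs`.
#' @examples
#' lat <- d3q27()
#' colSums(lat$w * lat$e)   # first moment vanishes
#' @export
d3q27 <- function() {
  tab <- .cpp_lattice_tables()
  structure(
    list(e = tab$e, w = as.numeric(tab$w), opp = as.integer(tab$opp),
         c = 1, cs = 1 / sqrt(3)),
    class = "lattice_model"
  )
}

#' Equilibrium pressure distributions
#'
#' Incompressible-formulation equilibria
#' `p_a^eq = w_a * (p + e.u + 3 (e.u)^2 / (2 c^2) - u^2 / 2)` with reference
#' density 1.  `sum_a p_a^eq = p` and `sum_a e_a p_a^eq = cs^2 u` hold by the
#' lattice moment identities.
#'
#' @param p numeric vector of pressures (length n).
#' @param u numeric matrix n x 3 of velocities in lattice units (or length-3
#'   vector for a single node).
#' @param lattice a [d3q27()] model.
#' @return n x 27 matrix of equilibrium values.
#' @export
equilibrium <- function(p, u, lattice = d3q27()) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  stopifnot(length(p) == nrow(u))
  eu <- u %*% t(lattice$e)                    # n x 27
  usq <- rowSums(u^2)
  sweep(p + eu + 1.5 * eu^2 - 0.5 * usq, 2, lattice$w, `*`)
}

#' Macroscopic fields from pressure distributions
#'
#' `p = sum_a p_a`, `u = (1 / (rho0 cs^2)) sum_a e_a p_a`, and the
#' nonequilibrium second moment `Pi^neq = sum_a e_a e_a (p_a - p_a^eq)`.
#'
#' @param pdist n x 27 matrix of distributions (or length-27 vector).
#' @param lattice a [d3q27()] model.
#' @return list with `p` (n), `u` (n x 3) and `Pi_neq` (3 x 3 x n array).
#' @export
macroscopics <- function(pdist, lattice = d3q27()) {
  if (is.null(dim(pdist))) pdist <- matrix(pdist, nrow = 1)
  stopifnot(ncol(pdist) == 27L)
  p <- rowSums(pdist)
  u <- 3 * (pdist %*% lattice$e)              # 1 / cs^2 = 3
  fneq <- pdist - equilibrium(p, u, lattice)
  n <- nrow(pdist)
  Pi <- array(0, c(3, 3, n))
  for (i in 1:3)
    for (j in 1:3)
      Pi[i, j, ] <- fneq %*% (lattice$e[, i] * lattice$e[, j])
  list(p = p, u = u, Pi_neq = Pi)
}

#' BGK relaxation time
#'
#' `tau = 3 nu / (c dx) + 1/2` with `dt = dx / c`; `tau <= 1/2` is rejected as
#' unphysical (zero or negative viscosity).
#'
#' @param nu kinematic viscosity in lattice units.
#' @param c lattice speed (default 1).
#' @param dx grid spacing (default 1).
#' @export
relaxation_time <- function(nu, c = 1, dx = 1) {
  stopifnot(is.numeric(nu), length(nu) == 1L, c > 0, dx > 0)
  tau <- 3 * nu / (c * dx) + 0.5
  if (tau <= 0.5) {
    stop("relaxation time tau = ", tau,
         " <= 1/2: non-positive viscosity is unstable/unphysical")
  }
  tau
}
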