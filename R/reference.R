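#' Published full-resolution reference values
#'
#' Cycle-averaged results of the full-scale hovering study (40 L domain,
#' 32 cells per chord, sixth of seven cycles) that serve as inputs to the
#' desk-scale analysis steps: the efficiency-ellipse fit, the
#' dimensionalization identities, and regression tests.  All values are
#' printed study outputs, not quantities this package computes at full
#' scale.
#'
#' @name reference_tables
NULL

#' @describeIn reference_tables Cycle-averaged lift coefficient and
#'   lift-to-power ratio for the eight elevation-phase motions (figure-eight
#'   family) and the planar motion, at five Reynolds numbers.
#' @export
ref_sweep_coefficients <- function() {
  phi <- c(0, 45, 90, 135, 180, 225, 270, 315)
  re <- c(33.5, 67, 134, 268, 536)
  cl <- rbind(
    c(0.270, 0.303, 0.354, 0.396, 0.421),
    c(0.350, 0.398, 0.463, 0.522, 0.558),
    c(0.401, 0.458, 0.520, 0.581, 0.613),
    c(0.383, 0.448, 0.516, 0.572, 0.589),
    c(0.296, 0.363, 0.417, 0.460, 0.483),
    c(0.203, 0.252, 0.312, 0.341, 0.336),
    c(0.177, 0.202, 0.246, 0.274, 0.278),
    c(0.202, 0.226, 0.265, 0.294, 0.310))
  ratio <- rbind(
    c(0.509, 0.726, 0.961, 1.165, 1.335),
    c(0.613, 0.849, 1.075, 1.246, 1.358),
    c(0.624, 0.838, 1.019, 1.159, 1.223),
    c(0.542, 0.733, 0.895, 1.014, 1.069),
    c(0.413, 0.594, 0.741, 0.851, 0.922),
    c(0.306, 0.463, 0.637, 0.757, 0.803),
    c(0.306, 0.447, 0.623, 0.766, 0.864),
    c(0.384, 0.558, 0.768, 0.956, 1.116))
  without <- tibble::tibble(
    phi_e0 = NA_real_, figure_eight = FALSE, re = re,
    CL_bar = c(0.220, 0.251, 0.302, 0.350, 0.379),
    ratio = c(0.429, 0.623, 0.857, 1.065, 1.207))
  with8 <- tidyr::expand_grid(phi_e0 = phi, re = re) |>
    dplyr::mutate(figure_eight = TRUE,
                  CL_bar = as.numeric(t(cl)),
                  ratio = as.numeric(t(ratio)))
  dplyr::bind_rows(with8, without) |>
    dplyr::mutate(CPWR_bar = .data$CL_bar / .data$ratio)
}

#' @describeIn reference_tables Cycle-averaged coefficients of the
#'   figure-eight (`phi_e0 = 10` deg) and planar motions at Re = 134.
#' @export
ref_motion_comparison <- function() {
  tibble::tibble(
    motion = c("with_figure_eight", "without_figure_eight"),
    CL_bar = c(0.382, 0.302),
    CT_bar = c(3.45e-3, 2.54e-2),
    CPWR_bar = c(0.380, 0.352),
    ratio = c(1.005, 0.857))
}

#' @describeIn reference_tables Cycle-averaged dimensional lift force
#'   (micro-newtons), power (micro-watts) and their ratio for the planar
#'   motion at each Reynolds number.
#' @export
ref_dimensional <- function() {
  tibble::tibble(
    re = c(33.5, 67, 134, 268, 536),
    utip = c(0.645, 1.29, 2.58, 5.16, 10.32),
    frequency = c(54.5, 109, 218, 436, 872),
    Fz_uN = c(0.205, 0.933, 4.495, 20.84, 90.32),
    P_uW = c(0.308, 1.932, 13.53, 101.0, 772.3),
    Fz_over_P = c(0.665, 0.483, 0.332, 0.206, 0.117))
}

#' @describeIn reference_tables Elliptic-approximation parameters (centre,
#'   long/short side, inclination in degrees, aspect ratio) per Reynolds
#'   number.
#' @export
ref_ellipse <- function() {
  tibble::tibble(
    re = c(33.5, 67, 134, 268, 536),
    centre_x = c(0.623, 0.511, 0.468, 0.437, 0.415),
    centre_y = c(0.284, 0.329, 0.385, 0.429, 0.446),
    ll = c(0.131, 0.154, 0.176, 0.197, 0.208),
    ls = c(0.079, 0.073, 0.068, 0.068, 0.071),
    theta_el = c(54, 54, 53, 53, 53),
    AR = c(1.658, 2.110, 2.588, 2.897, 2.930))
}

#' @describeIn reference_tables Cycle-averaged lift coefficient per cycle in
#'   the seven-cycle convergence test (Re = 134, 32 cells per chord).
#' @export
ref_cycle_lift <- function() {
  tibble::tibble(cycle = 1:7,
                 CL_bar = c(0.484, 0.379, 0.390, 0.387, 0.383, 0.382, 0.383))
}

#' @describeIn reference_tables Grid-independence results: cycle-averaged
#'   lift and its pressure/viscous split at 16/32/64 cells per chord.
#' @export
ref_resolution <- function() {
  tibble::tibble(resolution = c(16, 32, 64),
                 CL_bar = c(0.373, 0.382, 0.392),
                 CLp_bar = c(0.408, 0.427, 0.442),
                 CLtau_bar = c(0.038, 0.048, 0.052))
}
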