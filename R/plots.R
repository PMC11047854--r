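#' Plot the coefficient time history of a run
#'
#' Lift, thrust and power coefficients against time in cycles.
#'
#' @param object a `flapping_run`.
#' @param vars coefficient columns to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.flapping_run <- function(object, vars = c("CL", "CT", "CPWR"), ...) {
  long <- tidyr::pivot_longer(object$forces[, c("t", vars)],
                              dplyr::all_of(vars),
                              names_to = "coefficient")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     colour = .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t / T (cycles)", y = NULL,
                  title = sprintf("Re = %.1f, %d cells/chord",
                                  object$reynolds, object$resolution)) +
    ggplot2::theme_minimal()
}

#' Plot a phase/Reynolds sweep in the power-lift plane
#'
#' Each figure-eight motion as a point in the
#' (`CPWR_bar`, `CL_bar`) plane, the planar motion's origin line
#' ("without-8 line") dashed, and optionally the fitted ellipse.
#'
#' @param object a `sweep_result`.
#' @param fit optional [ellipse_fit()] to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sweep_result <- function(object, fit = NULL, ...) {
  w8 <- object[object$figure_eight, , drop = FALSE]
  wo <- object[!object$figure_eight, , drop = FALSE]
  gg <- ggplot2::ggplot(w8, ggplot2::aes(.data$CPWR_bar, .data$CL_bar)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$phi_e0))) +
    ggplot2::facet_wrap(~re, scales = "free") +
    ggplot2::labs(x = "cycle-averaged power coefficient",
                  y = "cycle-averaged lift coefficient",
                  colour = "phi_e0 (deg)") +
    ggplot2::theme_minimal()
  if (nrow(wo))
    gg <- gg + ggplot2::geom_abline(
      data = wo, ggplot2::aes(slope = .data$ratio, intercept = 0),
      linetype = "dashed")
  if (!is.null(fit)) {
    th <- seq(0, 2 * pi, length.out = 181)
    rot <- fit$theta_el * pi / 180
    ell <- tibble::tibble(
      CPWR_bar = fit$centre[1] + fit$ll * cos(th) * cos(rot) -
        fit$ls * sin(th) * sin(rot),
      CL_bar = fit$centre[2] + fit$ll * cos(th) * sin(rot) +
        fit$ls * sin(th) * cos(rot))
    gg <- gg + ggplot2::geom_path(data = ell, colour = "grey40")
  }
  gg
}

#' Plot a wing-tip trajectory
#'
#' Projections of the closed tip path over one period; the
#' (stroke angle, elevation) projection makes the figure-eight or U shape
#' visible.
#'
#' @param kin a [wing_kinematics()].
#' @param geom a [plate_geometry()].
#' @param n samples along the period.
#' @return a ggplot of the projected trajectory.
#' @export
plot_tip_trajectory <- function(kin, geom = plate_geometry(), n = 512) {
  tr <- tip_trajectory(kin, geom, n)
  ggplot2::ggplot(tr, ggplot2::aes(.data$positional, .data$elevation)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "positional angle (deg)",
                  y = "elevation angle (deg)") +
    ggplot2::theme_minimal()
}
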