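# Shared scaled-down hovering runs for the acceptance checks.
#
# Protocol (see the methods vignette): 4 cells per chord, 16 L domain,
# 3 grid tiers, lattice tip speed 0.08, one flapping cycle, first-cycle
# averages.  Runs are cached so several test blocks can share them.

.scaled_cache <- new.env(parent = emptyenv())

scaled_config <- function() {
  cfg <- flapwing_config()
  cfg$solver$u_lattice <- 0.08
  cfg
}

scaled_run_means <- function(phi_e0 = NULL, figure_eight = TRUE,
                             reynolds = 134) {
  key <- paste0("phi", ifelse(is.null(phi_e0), "none", phi_e0),
                "_f", figure_eight, "_re", reynolds)
  if (!is.null(.scaled_cache[[key]])) return(.scaled_cache[[key]])
  run <- simulate_flapping(scaled_config(), phi_e0 = phi_e0,
                           figure_eight = figure_eight, reynolds = reynolds,
                           cycles = 1, resolution = 4, domain = 16, tiers = 3)
  cm <- cycle_average(run$forces, 1,
                      c("CL", "CT", "CPWR", "resid_mean", "CL_traction"))
  out <- tibble::tibble(phi_e0 = ifelse(is.null(phi_e0), NA_real_, phi_e0),
                        figure_eight = figure_eight, re = reynolds,
                        CL_bar = cm[["CL"]], CT_bar = cm[["CT"]],
                        CPWR_bar = cm[["CPWR"]],
                        ratio = cm[["CL"]] / cm[["CPWR"]],
                        resid_mean = cm[["resid_mean"]],
                        CL_traction = cm[["CL_traction"]])
  .scaled_cache[[key]] <- out
  out
}

scaled_phase_sweep <- function(reynolds) {
  dplyr::bind_rows(lapply(seq(0, 315, by = 45), function(phi)
    scaled_run_means(phi, TRUE, reynolds)))
}
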