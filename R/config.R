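#' Assemble a run configuration
#'
#' Defaults reproduce the hovering fruit-fly study conditions: Table-style
#' morphology ([physical_wing()] defaults), three-angle kinematics with
#' amplitudes 70/70/10 degrees and phases 10/0/10 degrees, elevation initial
#' phase 10 degrees, 218 Hz; a `40 L` domain on four grid tiers at 32 cells
#' per chord, lattice tip speed `U = 0.04`, seven flapping cycles with the
#' sixth used for reporting.
#'
#' @param wing,kinematics,solver,layout,vfm,experiment named lists merged
#'   over the defaults; unknown keys are an error.
#' @return nested list of class `flapwing_config`.
#' @export
flapwing_config <- function(wing = list(), kinematics = list(),
                            solver = list(), layout = list(), vfm = list(),
                            experiment = list()) {
  def <- list(
    wing = list(body_length = 2.78e-3, mean_chord = 0.78e-3,
                wing_length = 2.39e-3, mean_tip_speed = 2.58,
                frequency = 218, air_kinematic_viscosity = 1.5e-5,
                air_density = 1.2, root_separation = 0.5),
    kinematics = list(amp_positional = 70, amp_feathering = 70,
                      amp_elevation = 10, phase_positional = 10,
                      phase_feathering = 0, phase_elevation = 10,
                      phase_elevation_initial = 10, frequency = 218),
    solver = list(resolution = 32, u_lattice = 0.04, cycles = 7,
                  report_cycle = 6, reynolds = NULL),
    layout = list(domain = 40, tiers = 4),
    vfm = list(h1 = sqrt(3), h2 = 2 * sqrt(3)),
    experiment = list(phi_e0 = seq(0, 315, by = 45),
                      re = c(33.5, 67, 134, 268, 536))
  )
  user <- list(wing = wing, kinematics = kinematics, solver = solver,
               layout = layout, vfm = vfm, experiment = experiment)
  errs <- character()
  for (blk in names(def)) {
    unknown <- setdiff(names(user[[blk]]), names(def[[blk]]))
    if (length(unknown))
      errs <- c(errs, paste0("unknown key(s) in '", blk, "': ",
                             paste(unknown, collapse = ", ")))
    for (key in intersect(names(user[[blk]]), names(def[[blk]])))
      def[[blk]][[key]] <- user[[blk]][[key]]
  }
  cfg <- structure(def, class = "flapwing_config")
  errs <- c(errs, validate_config(cfg))
  if (length(errs)) stop(paste(errs, collapse = "\n  "))
  cfg
}

validate_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  w <- cfg$wing
  chk(all(unlist(w) > 0), "wing: all physical properties must be positive")
  k <- cfg$kinematics
  chk(k$amp_positional >= 0 && k$amp_feathering >= 0 && k$amp_elevation >= 0,
      "kinematics: amplitudes must be >= 0")
  chk(k$frequency > 0, "kinematics: frequency must be positive")
  s <- cfg$solver
  chk(is.numeric(s$resolution) && s$resolution > 0,
      "solver: resolution must be a positive number of cells per chord")
  chk(s$u_lattice > 0 && s$u_lattice < 0.3,
      "solver: lattice tip speed must be in (0, 0.3)")
  chk(s$cycles >= 1, "solver: need at least one cycle")
  chk(is.null(s$reynolds) || s$reynolds > 0,
      "solver: reynolds must be positive")
  l <- cfg$layout
  chk(l$domain > 0, "layout: domain must be positive")
  chk(l$tiers >= 1 && l$tiers == round(l$tiers),
      "layout: tiers must be a positive integer")
  v <- cfg$vfm
  chk(v$h1 > 0 && v$h2 > v$h1, "vfm: need 0 < h1 < h2")
  errs
}

#' Read a configuration file
#'
#' YAML key-value blocks (`wing:`, `kinematics:`, `solver:`, `layout:`,
#' `vfm:`, `experiment:`); missing blocks and keys fall back to the
#' defaults of [flapwing_config()], unknown keys or out-of-range values give
#' an itemized error.  An empty file yields the full default configuration.
#'
#' @param path file path.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("wing", "kinematics", "solver", "layout", "vfm", "experiment")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "))
  do.call(flapwing_config, raw[intersect(names(raw), known)])
}

#' Write a configuration file
#'
#' Round-trips losslessly through [load_config()] (up to key ordering).
#'
#' @param config a [flapwing_config()].
#' @param path file path.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$solver$reynolds <- cfg$solver$reynolds %||% NULL
  cfg$kin_run <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
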