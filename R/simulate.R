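#' Lattice steps per flapping cycle
#'
#' The finest-tier step count per period is the cycle tip-path length in
#' finest cells divided by the lattice tip speed,
#' `round(Ptip / (U dx))`, rounded up to a multiple of `2^(tiers-1)` so the
#' coarsest tier advances an integer number of steps per cycle.
#'
#' @param config a [flapwing_config()].
#' @return integer steps per cycle on the finest tier.
#' @export
steps_per_cycle <- function(config) {
  kin <- config_kinematics(config)
  geom <- config_geometry(config, "right")
  path_L <- tip_speed_mean(kin, geom) / kin$frequency   # L per cycle
  cells <- path_L * config$solver$resolution
  m <- 2L^(config$layout$tiers - 1L)
  max(m, as.integer(m * round(cells / config$solver$u_lattice / m)))
}

# helpers pulling typed objects out of a config list
config_kinematics <- function(config, phi_e0 = NULL, figure_eight = TRUE) {
  k <- config$kinematics
  wing_kinematics(
    amp_positional = k$amp_positional,
    amp_feathering = k$amp_feathering,
    amp_elevation = if (figure_eight) k$amp_elevation else 0,
    phase_positional = k$phase_positional,
    phase_feathering = k$phase_feathering,
    phase_elevation = if (figure_eight) k$phase_elevation else 0,
    phase_elevation_initial = if (is.null(phi_e0)) k$phase_elevation_initial
                              else phi_e0,
    frequency = k$frequency
  )
}

config_geometry <- function(config, side) {
  w <- config$wing
  sep <- w$root_separation %||% 0
  plate_geometry(chord = 1, span = w$wing_length / w$mean_chord,
                 root_offset = c(sep / 2, 0, 0), side = side)
}

# Plate matrix for both wings at fine-step time tf, in tier-1 node
# coordinates.  Wall velocities come from central differences of the pose
# over dt/10.
flapping_plates_fn <- function(config, tier1, spc) {
  kin_r <- config$kin_run
  geoms <- list(right = config_geometry(config, "right"),
                left = config_geometry(config, "left"))
  f <- kin_r$frequency
  dt_sec <- (1 / f) / spc
  dx <- tier1$dx_lab
  x0 <- tier1$x0
  res <- 1 / dx
  function(tf) {
    t_sec <- (tf / spc) / f
    h <- dt_sec / 10
    rows <- lapply(geoms, function(g) {
      corners <- function(tt) {
        # origin corner (s=0, c=-chord/2), plus the two edge directions
        wing_points_lab(kin_r, tt, g,
                        rbind(c(0, -g$chord / 2), c(g$span, -g$chord / 2),
                              c(0, g$chord / 2)))
      }
      c0 <- corners(t_sec)
      cp <- corners(t_sec + h); cm <- corners(max(t_sec - h, 0))
      vel <- (cp - cm) / (t_sec + h - max(t_sec - h, 0))   # L per second
      sv <- c0[2, ] - c0[1, ]; cv <- c0[3, ] - c0[1, ]
      s_hat <- sv / sqrt(sum(sv^2)); c_hat <- cv / sqrt(sum(cv^2))
      n_hat <- c(s_hat[2] * c_hat[3] - s_hat[3] * c_hat[2],
                 s_hat[3] * c_hat[1] - s_hat[1] * c_hat[3],
                 s_hat[1] * c_hat[2] - s_hat[2] * c_hat[1])
      # angular velocity from the frame derivative: W = Rdot R^T
      svp <- cp[2, ] - cp[1, ]; svm <- cm[2, ] - cm[1, ]
      cvp <- cp[3, ] - cp[1, ]; cvm <- cm[3, ] - cm[1, ]
      dtc <- t_sec + h - max(t_sec - h, 0)
      ds_hat <- (svp / sqrt(sum(svp^2)) - svm / sqrt(sum(svm^2))) / dtc
      dc_hat <- (cvp / sqrt(sum(cvp^2)) - cvm / sqrt(sum(cvm^2))) / dtc
      np <- {
        sp <- svp / sqrt(sum(svp^2)); cpv <- cvp / sqrt(sum(cvp^2))
        c(sp[2] * cpv[3] - sp[3] * cpv[2], sp[3] * cpv[1] - sp[1] * cpv[3],
          sp[1] * cpv[2] - sp[2] * cpv[1])
      }
      nm <- {
        sm <- svm / sqrt(sum(svm^2)); cmv <- cvm / sqrt(sum(cvm^2))
        c(sm[2] * cmv[3] - sm[3] * cmv[2], sm[3] * cmv[1] - sm[1] * cmv[3],
          sm[1] * cmv[2] - sm[2] * cmv[1])
      }
      dn_hat <- (np - nm) / dtc
      Rm <- cbind(s_hat, c_hat, n_hat)
      Rd <- cbind(ds_hat, dc_hat, dn_hat)
      W_sec <- Rd %*% t(Rm)                       # rad/s, lab frame
      W_sec <- (W_sec - t(W_sec)) / 2             # enforce antisymmetry
      # convert: positions to cells, velocities to cells/step
      origin_cells <- (c0[1, ] - x0) / dx
      vfm_plate(origin_cells, s_hat, c_hat,
                span = g$span * res, chord = g$chord * res,
                v0 = vel[1, ] * dt_sec / dx,
                W = W_sec * dt_sec)
    })
    do.call(rbind, rows)
  }
}

#' Run the two-wing hovering simulation
#'
#' Sets up the nested grids, prescribes the three-angle flapping kinematics
#' for both wings, and advances the virtual-flux LBM solver for the
#' configured number of cycles, recording plate loads at every finest-tier
#' step.
#'
#' @param config a [flapwing_config()]; individual elements can be
#'   overridden with the remaining arguments.
#' @param phi_e0 elevation initial phase (deg).
#' @param figure_eight `FALSE` runs the planar motion (`theta_e = 0`).
#' @param reynolds target wing-tip Reynolds number.
#' @param cycles number of flapping cycles.
#' @param resolution finest-grid cells per chord.
#' @param domain domain side length in chords.
#' @param tiers number of grid tiers.
#' @param verbose print a per-cycle summary line?
#' @return object of class `flapping_run`: list with the per-step coefficient
#'   tibble (`$forces`), the step count per cycle, lattice references and the
#'   final simulation state.
#' @export
simulate_flapping <- function(config = flapwing_config(), phi_e0 = NULL,
                              figure_eight = TRUE, reynolds = NULL,
                              cycles = NULL, resolution = NULL, domain = NULL,
                              tiers = NULL, verbose = FALSE) {
  if (!is.null(resolution)) config$solver$resolution <- resolution
  if (!is.null(domain)) config$layout$domain <- domain
  if (!is.null(tiers)) config$layout$tiers <- tiers
  if (!is.null(cycles)) config$solver$cycles <- cycles
  if (!is.null(reynolds)) config$solver$reynolds <- reynolds
  re <- config$solver$reynolds
  if (is.null(re)) re <- physical_wing_from(config)$re
  kin <- config_kinematics(config, phi_e0, figure_eight)
  config$kin_run <- kin
  res <- config$solver$resolution
  U <- config$solver$u_lattice
  span_L <- config$wing$wing_length / config$wing$mean_chord
  sep <- config$wing$root_separation %||% 0
  lay <- build_layout(domain = config$layout$domain, resolution = res,
                      tiers = config$layout$tiers,
                      wing_reach = span_L + sep / 2 + 1,
                      z_reach = span_L * sin((config$kinematics$amp_elevation +
                        config$kinematics$phase_elevation) * pi / 180) + 1.2)
  nu1 <- U * res / re
  blocks <- layout_blocks(lay, nu1)
  spc <- steps_per_cycle(config)
  sim <- multiblock_sim(blocks, plates_fn = flapping_plates_fn(config,
                                                               blocks[[1]],
                                                               spc),
                        fixed_face = "y_hi", p_fixed = 1 / 3,
                        h1 = config$vfm$h1, h2 = config$vfm$h2,
                        record = TRUE)
  n_cyc <- config$solver$cycles
  for (cy in seq_len(n_cyc)) {
    advance_steps(sim, spc)
    if (verbose) {
      ff <- run_forces(sim, spc, U, area_cells = 2 * span_L * res^2)
      cm <- cycle_average(ff, cycle = cy)
      message(sprintf("cycle %d: CL=%.4f CT=%.4f CPWR=%.4f resid=%.2e",
                      cy, cm[["CL"]], cm[["CT"]], cm[["CPWR"]],
                      cm[["resid_mean"]]))
    }
  }
  forces <- run_forces(sim, spc, U, area_cells = 2 * span_L * res^2)
  structure(list(
    forces = forces, steps_per_cycle = spc, u_lattice = U,
    area_cells = 2 * span_L * res^2, reynolds = re, cycles = n_cyc,
    resolution = res, phi_e0 = kin$phase_elevation_initial,
    figure_eight = figure_eight, config = config, sim = sim
  ), class = "flapping_run")
}

# assemble the per-step coefficient tibble from the raw force records.
# Primary coefficients come from the momentum-exchange loads (the exact
# force the boundary reconstruction exerts); the traction integration
# provides the pressure/viscous split and an independent cross-check.
run_forces <- function(sim, spc, U, area_cells) {
  if (length(sim$force_rows) == 0) return(tibble::tibble())
  m <- do.call(rbind, sim$force_rows)
  np <- (ncol(m) - 1L) %/% 14L
  qd <- 0.5 * U^2 * area_cells
  qp <- 0.5 * U^3 * area_cells
  Fme <- array(0, c(nrow(m), 3)); Pme <- numeric(nrow(m))
  Fp <- array(0, c(nrow(m), 3)); Fv <- Fp
  rs <- numeric(nrow(m)); rx <- numeric(nrow(m))
  for (w in seq_len(np)) {
    o <- 1L + (w - 1L) * 14L
    Fme <- Fme + m[, o + 1:3, drop = FALSE]
    Pme <- Pme + m[, o + 4]
    Fp <- Fp + m[, o + 5:7, drop = FALSE]
    Fv <- Fv + m[, o + 8:10, drop = FALSE]
    rs <- rs + m[, o + 12] / np
    rx <- pmax(rx, m[, o + 13])
  }
  tibble::tibble(
    t = m[, 1] / spc,
    CL = Fme[, 3] / qd,
    CT = Fme[, 2] / qd,
    CPWR = -Pme / qp,
    CLp = Fp[, 3] / qd,
    CLtau = Fv[, 3] / qd,
    CL_traction = (Fp[, 3] + Fv[, 3]) / qd,
    resid_mean = rs,
    resid_max = rx
  )
}

#' @export
print.flapping_run <- function(x, ...) {
  cat(sprintf(
    "<flapping_run: Re=%.1f phi_e0=%g%s, %d cells/L, %d cycles, %d steps/cycle>\n",
    x$reynolds, x$phi_e0, if (x$figure_eight) "" else " (no figure-eight)",
    x$resolution, x$cycles, x$steps_per_cycle))
  if (nrow(x$forces)) {
    cm <- cycle_average(x$forces, cycle = x$cycles)
    cat(sprintf("  last-cycle means: CL=%.4f CT=%.4f CPWR=%.4f\n",
                cm[["CL"]], cm[["CT"]], cm[["CPWR"]]))
  }
  invisible(x)
}

physical_wing_from <- function(config) {
  w <- config$wing
  w$root_separation <- NULL
  do.call(physical_wing, w)
}

#' Oscillating rigid-plate validation case
#'
#' A rectangular plate (span 4 chords) heaving along x with displacement
#' `x(t) = L sin(2 pi f t)` and pitching about its mid-chord spanwise axis,
#' `theta(t) = pi/2 - (pi/4) sin(2 pi f t + pi/3)`, the classic hovering
#' benchmark.  The lift coefficient is normalized by the peak heave speed
#' `2 pi f L`.
#'
#' @param resolution cells per chord (= per stroke amplitude `L`).
#' @param cycles number of oscillation periods.
#' @param reynolds Reynolds number on chord and peak heave speed.
#' @param domain domain size in chords.
#' @param tiers grid tiers.
#' @param u_lattice peak heave speed in lattice units.
#' @param span plate span in chords.
#' @param heave_amp heave amplitude in chords.
#' @param pitch_amp pitch amplitude (rad).
#' @return `flapping_run`-like object with the `$forces` tibble (CL per
#'   step, lift along z).
#' @export
oscillating_plate_case <- function(resolution = 16, cycles = 2,
                                   reynolds = 100, domain = 16, tiers = 2,
                                   u_lattice = 0.04, span = 4,
                                   heave_amp = 1, pitch_amp = pi / 4) {
  lay <- build_layout(domain = domain, resolution = resolution, tiers = tiers,
                      wing_reach = heave_amp + span / 2 + 1, z_reach = 1.6)
  nu1 <- u_lattice * resolution / reynolds
  blocks <- layout_blocks(lay, nu1)
  # steps per cycle from the peak heave speed
  m <- 2L^(tiers - 1L)
  spc <- as.integer(m * round(2 * pi * max(heave_amp, 0.5) * resolution /
                                u_lattice / m))
  dx <- blocks[[1]]$dx_lab; x0 <- blocks[[1]]$x0
  plates_fn <- function(tf) {
    ph <- 2 * pi * tf / spc
    xo <- heave_amp * sin(ph)
    th <- pi / 2 - pitch_amp * sin(ph + pi / 3)
    dph <- 2 * pi / spc                       # per fine step
    dxo <- heave_amp * cos(ph) * dph
    dth <- -pitch_amp * cos(ph + pi / 3) * dph
    c_hat <- c(cos(th), 0, sin(th))
    s_hat <- c(0, 1, 0)
    centre <- c(xo, 0, 0)
    origin <- centre - (span / 2) * s_hat - 0.5 * c_hat
    W <- dth * matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3, byrow = TRUE)
    v0 <- c(dxo, 0, 0) * resolution +
      W %*% ((origin - centre) * resolution)
    vfm_plate((origin - x0) / dx, s_hat, c_hat,
              span = span * resolution, chord = 1 * resolution,
              v0 = as.numeric(v0), W = W)
  }
  sim <- multiblock_sim(blocks, plates_fn = plates_fn, fixed_face = "z_hi",
                        record = TRUE)
  advance_steps(sim, spc * cycles)
  forces <- run_forces(sim, spc, U = u_lattice,
                       area_cells = span * resolution^2)
  structure(list(forces = forces, steps_per_cycle = spc,
                 u_lattice = u_lattice, reynolds = reynolds,
                 area_cells = span * resolution^2, cycles = cycles,
                 resolution = resolution, phi_e0 = NA,
                 figure_eight = NA, sim = sim),
            class = "flapping_run")
}
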