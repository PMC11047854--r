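#' Write block fields as a legacy-VTK structured grid
#'
#' ASCII `STRUCTURED_POINTS` file with pressure as a scalar field and
#' velocity as a vector field, readable by ParaView/VisIt for isosurface
#' work (Q-criterion and helicity fields can be passed as extra scalars).
#'
#' @param b a [fluid_block()].
#' @param path output file.
#' @param extra named list of 3-D arrays (interior dimensions) written as
#'   additional scalar fields.
#' @export
write_vtk <- function(b, path, extra = list()) {
  update_macroscopics(b)
  p <- block_array(b, "p")
  ux <- block_array(b, "ux"); uy <- block_array(b, "uy")
  uz <- block_array(b, "uz")
  dn <- dim(p)
  g <- b$ghost
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "flapwing fields", "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dn[1], dn[2], dn[3]),
               sprintf("ORIGIN %g %g %g",
                       b$x0[1] + g * b$dx_lab, b$x0[2] + g * b$dx_lab,
                       b$x0[3] + g * b$dx_lab),
               sprintf("SPACING %g %g %g", b$dx_lab, b$dx_lab, b$dx_lab),
               sprintf("POINT_DATA %d", prod(dn)),
               "SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(p), digits = 9), con)
  writeLines("VECTORS velocity double", con)
  writeLines(paste(format(as.numeric(ux), digits = 9),
                   format(as.numeric(uy), digits = 9),
                   format(as.numeric(uz), digits = 9)), con)
  for (nm in names(extra)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(extra[[nm]]), digits = 9), con)
  }
  invisible(path)
}

#' Export a coefficient time series as CSV
#'
#' RFC-4180 CSV (comma separated, `.` decimal) of the per-step force
#' record.
#'
#' @param run a [simulate_flapping()] result.
#' @param path output file.
#' @export
export_forces_csv <- function(run, path) {
  utils::write.csv(run$forces, path, row.names = FALSE)
  invisible(path)
}

#' Checkpoint a multiblock state to disk
#'
#' Little-endian binary container (magic header, per-tier dimensions, then
#' the raw distribution planes) that restores bit-identically: continuing a
#' run from a checkpoint reproduces the uninterrupted run exactly on the
#' same platform.
#'
#' @param sim an [multiblock_sim()] state.
#' @param path checkpoint file.
#' @export
checkpoint_write <- function(sim, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("FLAPWCK1"), con)
  writeBin(as.integer(c(sim$K, sim$step_fine)), con, size = 4,
           endian = "little")
  for (b in sim$tiers) {
    writeBin(as.integer(c(b$nx, b$ny, b$nz, b$ghost)), con, size = 4,
             endian = "little")
    writeBin(c(b$tau, b$dx_lab, b$x0), con, size = 8, endian = "little")
    writeBin(b$f, con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Restore a multiblock state from a checkpoint
#'
#' @param sim an [multiblock_sim()] state with matching tier layout.
#' @param path checkpoint file written by [checkpoint_write()].
#' @export
checkpoint_read <- function(sim, path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (magic != "FLAPWCK1") stop("not a flapwing checkpoint: ", path)
  hd <- readBin(con, "integer", 2, size = 4, endian = "little")
  if (hd[1] != sim$K) stop("tier count mismatch")
  sim$step_fine <- hd[2]
  for (b in sim$tiers) {
    dims <- readBin(con, "integer", 4, size = 4, endian = "little")
    if (!all(dims[1:3] == c(b$nx, b$ny, b$nz)))
      stop("block dimensions do not match the checkpoint")
    readBin(con, "double", 5, size = 8, endian = "little")
    b$f <- readBin(con, "double", 27 * b$N, size = 8, endian = "little")
    b$f_alt <- b$f + 0
    update_macroscopics(b)
  }
  invisible(sim)
}
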