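#' Hounsfield-unit to relative stopping power calibration
#'
#' Piecewise-linear monotone calibration anchored at air
#' (HU -1000, RSP 0.001) and water (HU 0, RSP 1.0), rising through soft
#' tissue into bone. HU outside [-1000, 3000] are clamped with a warning.
#'
#' @format A two-column matrix (`hu`, `rsp`).
#' @export
rsp_calibration_table <- function() {
  cbind(hu  = c(-1000, -200, -50,    0,   50,  300,  800, 1200, 3000),
        rsp = c(0.001, 0.92, 0.98, 1.00, 1.03, 1.15, 1.46, 1.66, 2.40))
}

#' Convert an HU grid to relative stopping power
#'
#' @param hu_grid `voxel_grid` of Hounsfield units, or a plain numeric
#'   vector/array of HU values.
#' @param table calibration table as returned by
#'   [rsp_calibration_table()].
#' @return object of the same kind with relative stopping power values.
#' @export
hu_to_stopping_power <- function(hu_grid, table = rsp_calibration_table()) {
  hu <- if (inherits(hu_grid, "voxel_grid")) hu_grid$values else hu_grid
  rng <- range(table[, "hu"])
  if (any(hu < rng[1] | hu > rng[2])) {
    warning("HU outside [", rng[1], ", ", rng[2], "] clamped")
    hu <- pmin(pmax(hu, rng[1]), rng[2])
  }
  rsp <- stats::approx(table[, "hu"], table[, "rsp"], xout = as.numeric(hu),
                       rule = 2)$y
  if (inherits(hu_grid, "voxel_grid")) {
    out <- hu_grid
    out$values <- array(rsp, dim(hu_grid$values))
    out
  } else {
    if (is.array(hu_grid)) array(rsp, dim(hu_grid)) else rsp
  }
}
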