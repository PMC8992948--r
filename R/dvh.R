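#' Cumulative dose-volume histogram
#'
#' The curve value at a dose level is the fraction of the structure's
#' voxels receiving at least that dose, evaluated on a regular dose grid
#' of width `bin_width` from 0 to just past the maximum dose.
#'
#' @param dose a `dose_grid`/`voxel_grid`, or a plain numeric vector of
#'   voxel doses (Gy(RBE)).
#' @param mask logical array (same shape as `dose`) selecting the
#'   structure; omit when `dose` is already the structure's voxel doses.
#' @param bin_width dose bin width, Gy(RBE).
#' @param voxel_ml voxel volume in ml (taken from `dose` when it is a
#'   grid) used for the absolute structure volume.
#' @return object of class `dvh_curve` with `dose` (bin edges), `frac`
#'   (fraction >= dose) and `volume_ml`.
#' @export
compute_dvh <- function(dose, mask = NULL, bin_width = 0.05,
                        voxel_ml = NULL) {
  if (inherits(dose, "voxel_grid")) {
    if (is.null(voxel_ml)) voxel_ml <- voxel_volume(dose) / 1000
    d <- if (is.null(mask)) as.numeric(dose$values)
         else as.numeric(dose$values[mask])
  } else {
    d <- as.numeric(if (!is.null(mask)) dose[mask] else dose)
    if (is.null(voxel_ml)) voxel_ml <- NA_real_
  }
  if (length(d) == 0L) stop("empty structure mask")
  edges <- seq(0, max(d, 0) + bin_width, by = bin_width)
  # fraction of voxels with dose >= edge
  frac <- 1 - stats::ecdf(d)(edges - 1e-12)
  structure(list(dose = edges, frac = frac,
                 volume_ml = length(d) * voxel_ml, n_voxels = length(d),
                 bin_width = bin_width, dmax = max(d)), class = "dvh_curve")
}

#' Dose covering a given percent of the volume (Dq index)
#'
#' Linear interpolation of the cumulative DVH: the dose at which the
#' covered fraction crosses `volume_pct` / 100. `D99` is the minimum dose
#' to 99 % of the structure.
#'
#' @param dvh a `dvh_curve`.
#' @param volume_pct volume percentage in (0, 100].
#' @return dose in Gy(RBE).
#' @export
dvh_index_D <- function(dvh, volume_pct = 99) {
  stopifnot(volume_pct > 0, volume_pct <= 100)
  q <- volume_pct / 100
  f <- dvh$frac; d <- dvh$dose
  if (f[1] < q) return(0)
  i <- max(which(f >= q))
  if (i == length(f)) return(d[i])
  if (f[i] == f[i + 1]) return(d[i])
  d[i] + (d[i + 1] - d[i]) * (f[i] - q) / (f[i] - f[i + 1])
}

#' Volume receiving at least a threshold dose (Vx index)
#'
#' @param dvh a `dvh_curve`.
#' @param threshold dose threshold, Gy(RBE).
#' @param absolute return ml (uses the structure volume) instead of
#'   percent.
#' @return percent of the structure volume, or ml when `absolute`.
#' @export
dvh_index_V <- function(dvh, threshold, absolute = FALSE) {
  stopifnot(threshold >= 0)
  f <- stats::approx(dvh$dose, dvh$frac, xout = threshold, rule = 2)$y
  if (absolute) f * dvh$volume_ml else 100 * f
}

#' Maximum dose within the structure
#' @param dvh a `dvh_curve`.
#' @export
dvh_index_Dmax <- function(dvh) dvh$dmax

#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve> ", x$n_voxels, " voxels",
      if (!is.na(x$volume_ml)) paste0(" (", round(x$volume_ml, 1), " ml)"),
      ", D99 = ", round(dvh_index_D(x, 99), 2), " Gy(RBE)\n", sep = "")
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    graphics::plot(x$dose, 100 * x$frac, type = "l", col = col,
                   xlab = "Dose [Gy(RBE)]", ylab = "Volume [%]",
                   ylim = c(0, 100), ...)
  } else {
    graphics::lines(x$dose, 100 * x$frac, col = col, ...)
  }
  invisible(x)
}
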