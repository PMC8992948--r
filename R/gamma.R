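#' 3-D global gamma analysis
#'
#' For every reference voxel above the low-dose cutoff, the gamma index is
#' the minimum over nearby evaluated positions of
#' `sqrt((dr/dta)^2 + (dD / (dd% x Dmax_ref))^2)`; the voxel passes when
#' gamma <= 1. Dose difference is normalized globally to the reference
#' maximum. The evaluated distribution is probed on a sub-voxel search
#' lattice (pitch `dta_mm / 2`) out to `search_factor x dta_mm`, with
#' trilinear interpolation.
#'
#' @param reference,evaluated `dose_grid`s (the evaluated grid may have
#'   different geometry; it is interpolated).
#' @param dd_percent dose-difference criterion, percent of the reference
#'   maximum.
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param dose_cutoff_percent reference voxels below this percent of the
#'   reference maximum are excluded.
#' @param search_factor search radius in units of `dta_mm`.
#' @return list with `pass_rate` (percent), `gamma` (vector over analyzed
#'   voxels) and `n_analyzed`.
#' @export
gamma_analysis <- function(reference, evaluated, dd_percent = 1,
                           dta_mm = 1, dose_cutoff_percent = 10,
                           search_factor = 3) {
  dmax <- max(reference$values)
  if (dmax <= 0) stop("reference dose is empty")
  # require overlapping extents
  r_lo <- reference$origin; r_hi <- reference$origin +
    (reference$shape - 1) * reference$spacing
  e_lo <- evaluated$origin; e_hi <- evaluated$origin +
    (evaluated$shape - 1) * evaluated$spacing
  if (any(r_hi < e_lo) || any(e_hi < r_lo))
    stop("reference and evaluated grids do not overlap")
  keep <- reference$values >= dose_cutoff_percent / 100 * dmax
  if (!any(keep)) stop("no reference voxels above the dose cutoff")
  pts <- grid_coords(reference, keep)
  dref <- as.numeric(reference$values[keep])
  dd_abs <- dd_percent / 100 * dmax
  step <- dta_mm / 2
  r <- search_factor * dta_mm
  g1 <- seq(-r, r, by = step)
  offs <- as.matrix(expand.grid(x = g1, y = g1, z = g1))
  dist2 <- rowSums(offs^2)
  offs <- offs[dist2 <= r^2 + 1e-9, , drop = FALSE]
  dist2 <- dist2[dist2 <= r^2 + 1e-9]
  ord <- order(dist2)  # near offsets first lets most voxels settle early
  offs <- offs[ord, , drop = FALSE]; dist2 <- dist2[ord]
  g2 <- rep(Inf, length(dref))
  for (i in seq_len(nrow(offs))) {
    geo <- dist2[i] / dta_mm^2
    if (geo >= 1 && all(g2 <= geo)) next
    de <- interp_trilinear(evaluated,
                           sweep(pts, 2, offs[i, ], "+"), clamp = TRUE)
    g2 <- pmin(g2, geo + ((de - dref) / dd_abs)^2)
  }
  gam <- sqrt(g2)
  list(pass_rate = 100 * mean(gam <= 1), gamma = gam,
       n_analyzed = length(gam))
}
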