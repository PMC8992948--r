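#' Pencil-beam model for two opposed lateral fields
#'
#' Parallel (non-divergent) scanned proton beams entering along the
#' left-right axis. The depth dose is an analytic Bragg parameterization
#' (power-free plateau plus an asymmetric Gaussian peak); lateral spread
#' is a single Gaussian whose sigma grows linearly with water-equivalent
#' depth. Constants are package defaults chosen for qualitative realism,
#' not a fit to any machine.
#'
#' @param sigma0 spot lateral sigma at the surface (mm).
#' @param sigma_growth sigma growth per mm of water-equivalent depth.
#' @param spot_spacing lateral spot pitch in the beam's-eye view (mm).
#' @param layer_spacing energy-layer pitch in water range (mm).
#' @param lateral_margin,range_margin spot-placement margins around the
#'   target envelope (mm, mm water).
#' @param range_limits deliverable water range (mm).
#' @param peak_sigma_distal,peak_sigma_proximal Bragg peak widths (mm);
#'   the distal width sets the 80-20 falloff (about 1.13 sigma).
#' @param plateau_frac,plateau_rise entrance plateau height (fraction of
#'   peak amplitude) and its fractional rise towards the peak.
#' @param distal_cutoff depth beyond the nominal range at which the dose
#'   is exactly zero (mm).
#' @return object of class `beam_model`.
#' @export
beam_model <- function(sigma0 = 6, sigma_growth = 0.025,
                       spot_spacing = 1.5 * sigma0, layer_spacing = 10,
                       lateral_margin = 8, range_margin = 8,
                       range_limits = c(40, 330),
                       peak_sigma_distal = 3.55,
                       peak_sigma_proximal = 6.5,
                       plateau_frac = 0.25, plateau_rise = 0.6,
                       distal_cutoff = 8) {
  stopifnot(sigma0 > 0, diff(range_limits) > 0)
  structure(list(sigma0 = sigma0, sigma_growth = sigma_growth,
                 spot_spacing = spot_spacing,
                 layer_spacing = layer_spacing,
                 lateral_margin = lateral_margin,
                 range_margin = range_margin,
                 range_limits = range_limits,
                 peak_sigma_distal = peak_sigma_distal,
                 peak_sigma_proximal = peak_sigma_proximal,
                 plateau_frac = plateau_frac,
                 plateau_rise = plateau_rise,
                 distal_cutoff = distal_cutoff),
            class = "beam_model")
}

#' Analytic Bragg depth-dose per unit fluence
#'
#' Peak at water-equivalent depth equal to the nominal range; entrance to
#' peak ratio about `plateau_frac / (1 + plateau)`; exactly zero beyond
#' `range + distal_cutoff`.
#'
#' @param range_mm nominal range R80-like (mm water); scalar or vector.
#' @param wepl_mm water-equivalent depth (mm); scalar or vector
#'   (recycled against `range_mm`).
#' @param model a [beam_model()].
#' @return dose per unit fluence (arbitrary units).
#' @export
bragg_depth_dose <- function(range_mm, wepl_mm, model = beam_model()) {
  stopifnot(all(range_mm > 0))
  n <- max(length(range_mm), length(wepl_mm))
  R <- rep_len(range_mm, n); d <- rep_len(wepl_mm, n)
  u <- d - R
  sig <- ifelse(u >= 0, model$peak_sigma_distal, model$peak_sigma_proximal)
  peak <- exp(-u * u / (2 * sig * sig))
  # plateau hands off ~6 mm before the peak so the peak sets the maximum
  plateau <- model$plateau_frac * (1 + model$plateau_rise * pmin(d / R, 1)) /
    (1 + exp((d - R + 6) / 3))
  out <- peak + plateau
  out[d < 0 | u > model$distal_cutoff] <- 0
  out
}

#' Water-equivalent path length along a ray (exact voxel traversal)
#'
#' Siddon-style traversal: the ray is intersected with every voxel
#' boundary plane and the relative stopping power integrated segment by
#' segment. Material in front of the grid contributes nothing.
#'
#' @param rsp `voxel_grid` of relative stopping power.
#' @param entry_point ray origin (mm).
#' @param direction unit direction vector.
#' @param sample_points depths along the ray (mm from `entry_point`) at
#'   which the cumulative WEPL is returned.
#' @return numeric vector of WEPL values (mm water); empty if the ray
#'   misses the grid.
#' @export
trace_wepl <- function(rsp, entry_point, direction, sample_points) {
  direction <- direction / sqrt(sum(direction^2))
  lo <- rsp$origin - rsp$spacing / 2
  hi <- rsp$origin + (rsp$shape - 0.5) * rsp$spacing
  t0 <- -Inf; t1 <- Inf
  for (ax in 1:3) {
    if (abs(direction[ax]) < 1e-12) {
      if (entry_point[ax] < lo[ax] || entry_point[ax] > hi[ax])
        return(numeric(0))
    } else {
      ta <- (lo[ax] - entry_point[ax]) / direction[ax]
      tb <- (hi[ax] - entry_point[ax]) / direction[ax]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) return(numeric(0))
  t0 <- max(t0, 0)
  crossings <- c(t0, t1)
  for (ax in 1:3) {
    if (abs(direction[ax]) < 1e-12) next
    bounds <- lo[ax] + (0:rsp$shape[ax]) * rsp$spacing[ax]
    tc <- (bounds - entry_point[ax]) / direction[ax]
    crossings <- c(crossings, tc[tc > t0 & tc < t1])
  }
  tt <- sort(unique(crossings))
  mids <- (tt[-1] + tt[-length(tt)]) / 2
  seg <- diff(tt)
  pmid <- sweep(outer(mids, direction), 2, entry_point, "+")
  idx <- sweep(sweep(pmid, 2, rsp$origin, "-"), 2, rsp$spacing, "/")
  ijk <- pmin(pmax(round(idx) + 1, 1),
              matrix(rsp$shape, length(mids), 3, byrow = TRUE))
  vals <- rsp$values[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
  cum <- cumsum(vals * seg)
  stats::approx(x = c(t0, tt[-1]), y = c(0, cum), xout = sample_points,
                rule = 2, ties = "ordered")$y
}

# cumulative WEPL along +/- x for every voxel (voxel-centre convention:
# half the voxel's own water-equivalent thickness is included)
wepl_grids <- function(rsp) {
  dx <- rsp$spacing[1]
  sh <- rsp$shape
  m <- matrix(rsp$values, sh[1], sh[2] * sh[3])
  cs <- apply(m * dx, 2, cumsum)
  fwd <- cs - m * dx / 2                       # beam travelling +x
  tot <- matrix(cs[sh[1], ], sh[1], sh[2] * sh[3], byrow = TRUE)
  bwd <- tot - cs + m * dx / 2                 # beam travelling -x
  list(voxel_grid(array(fwd, sh), rsp$origin, rsp$spacing),
       voxel_grid(array(bwd, sh), rsp$origin, rsp$spacing))
}

# dose-calculation context reused across scenarios/spots for one anatomy
dose_context <- function(anatomy) {
  rsp <- hu_to_stopping_power(anatomy$grid)
  w <- wepl_grids(rsp)
  list(rsp = rsp, wepl = w, anatomy = anatomy)
}
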