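#' Robustness scenario
#'
#' One error condition for robust planning/evaluation: a rigid isocenter
#' shift (mm) and a multiplicative range (stopping-power) scale.
#'
#' @param shift_mm length-3 isocenter shift (mm).
#' @param range_scale unitless range scale: values above 1 make every
#'   spot penetrate deeper (the patient's stopping power was
#'   overestimated by that factor), below 1 shallower. `1.035`
#'   corresponds to the 3.5 % stopping-power-ratio uncertainty.
#' @export
scenario <- function(shift_mm = c(0, 0, 0), range_scale = 1) {
  structure(list(shift_mm = as.numeric(shift_mm),
                 range_scale = range_scale), class = "scenario")
}

is_nominal_scenario <- function(sc)
  all(sc$shift_mm == 0) && sc$range_scale == 1

#' Spot plan for two opposed lateral fields
#'
#' @param spots data frame with columns `field` (0 = from the patient's
#'   right, beam travelling +x; 1 = from the left, travelling -x), `y`,
#'   `z` (BEV lateral position, mm), `range` (nominal water range, mm)
#'   and `weight` (fluence units, >= 0).
#' @param beam a [beam_model()].
#' @param prescription_gy prescribed course dose, Gy(RBE).
#' @param n_fractions fraction count the prescription is delivered in.
#' @param rbe constant relative biological effectiveness factor.
#' @param meta optional convergence/audit metadata.
#' @export
spot_plan <- function(spots, beam, prescription_gy = 63, n_fractions = 21,
                      rbe = 1.1, meta = list()) {
  stopifnot(all(spots$weight >= 0),
            all(spots$field %in% c(0, 1)),
            all(spots$range >= beam$range_limits[1]),
            all(spots$range <= beam$range_limits[2]))
  structure(list(spots = spots, beam = beam,
                 prescription_gy = prescription_gy,
                 n_fractions = n_fractions, rbe = rbe, meta = meta),
            class = "impt_plan")
}

#' Place pencil-beam spots to cover the CTV
#'
#' For each lateral field a BEV lattice (pitch `spot_spacing`) is laid over
#' the CTV projection plus `lateral_margin`; energy layers are spaced
#' `layer_spacing` in water range over the CTV's water-equivalent depth
#' envelope plus `range_margin`, per lattice position restricted to the
#' depths the CTV actually occupies there.
#'
#' @param ctx dose context from `dose_context()` (internal) or an
#'   `anatomy_instance`.
#' @param beam a [beam_model()].
#' @return spot data frame (weights initialized to 1).
#' @export
place_spots <- function(ctx, beam = beam_model()) {
  if (inherits(ctx, "anatomy_instance")) ctx <- dose_context(ctx)
  anat <- ctx$anatomy
  stopifnot(!is.null(anat$structures), sum(anat$structures$ctv) > 0)
  pts <- grid_coords(anat$grid, anat$structures$ctv)
  lat <- beam$lateral_margin
  ys <- lattice_1d(range(pts[, 2]), beam$spot_spacing, lat)
  zs <- lattice_1d(range(pts[, 3]), beam$spot_spacing, lat)
  out <- list()
  for (field in 0:1) {
    W <- interp_trilinear(ctx$wepl[[field + 1]], pts, clamp = TRUE)
    for (y in ys) for (z in zs) {
      near <- abs(pts[, 2] - y) <= beam$spot_spacing / 2 + lat &
              abs(pts[, 3] - z) <= beam$spot_spacing / 2 + lat
      if (!any(near)) next
      wr <- range(W[near])
      layers <- lattice_1d(wr, beam$layer_spacing, beam$range_margin)
      layers <- pmin(pmax(layers, beam$range_limits[1]),
                     beam$range_limits[2])
      out[[length(out) + 1L]] <- data.frame(
        field = field, y = y, z = z, range = unique(layers), weight = 1)
    }
  }
  do.call(rbind, out)
}

lattice_1d <- function(rng, pitch, margin) {
  lo <- rng[1] - margin; hi <- rng[2] + margin
  n <- max(1L, ceiling((hi - lo) / pitch))
  mid <- (lo + hi) / 2
  mid + (seq_len(n + 1L) - 1 - n / 2) * pitch
}

#' Per-spot dose influence at arbitrary points
#'
#' Returns the `n_points x n_spots` matrix of RBE-weighted dose per unit
#' spot weight under a scenario: the isocenter shift displaces the
#' patient rigidly relative to the beams, the range scale multiplies the
#' water-equivalent depth.
#'
#' @param ctx dose context (or `anatomy_instance`).
#' @param spots spot data frame (see [spot_plan()]).
#' @param points n x 3 world coordinates (mm).
#' @param sc a [scenario()].
#' @param rbe RBE factor applied once.
#' @return dense influence matrix (Gy(RBE) per unit weight).
#' @export
dose_influence <- function(ctx, spots, points, sc = scenario(),
                           rbe = 1.1) {
  if (inherits(ctx, "anatomy_instance")) ctx <- dose_context(ctx)
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  beam <- ctx$beam %||% beam_model()
  np <- nrow(points); ns <- nrow(spots)
  p2 <- sweep(points, 2, sc$shift_mm, "+")
  out <- matrix(0, np, ns)
  for (field in 0:1) {
    idx <- which(spots$field == field)
    if (length(idx) == 0L) next
    W <- interp_trilinear(ctx$wepl[[field + 1]], p2, clamp = TRUE) /
      sc$range_scale
    sig <- beam$sigma0 + beam$sigma_growth * W
    # depth dose: vectorized over the (point, spot) outer structure
    B <- bragg_depth_dose(rep(spots$range[idx], each = np),
                          rep(W, times = length(idx)), beam)
    dy <- rep(p2[, 2], times = length(idx)) -
      rep(spots$y[idx], each = np)
    dz <- rep(p2[, 3], times = length(idx)) -
      rep(spots$z[idx], each = np)
    s2 <- rep(sig * sig, times = length(idx))
    lat <- exp(-(dy * dy + dz * dz) / (2 * s2)) / (2 * pi * s2)
    out[, idx] <- B * lat
  }
  out * rbe
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute the dose of a plan on an anatomy
#'
#' @param plan an `impt_plan`.
#' @param anatomy an `anatomy_instance` (or a prebuilt dose context).
#' @param sc a [scenario()]; nominal by default.
#' @param eval_grid `voxel_grid` defining where dose is evaluated; by
#'   default a 2 mm isotropic grid is laid over the anatomy's structure
#'   bounding box. Alternatively `points` gives explicit coordinates.
#' @param points optional n x 3 matrix; if given, a numeric vector of
#'   dose values at these points is returned instead of a grid.
#' @param spot_chunk spots are processed in chunks of this size to bound
#'   memory.
#' @return a `dose_grid` (a `voxel_grid` carrying Gy(RBE) values plus
#'   metadata), or a numeric vector if `points` was supplied.
#' @export
compute_dose <- function(plan, anatomy, sc = scenario(),
                         eval_grid = NULL, points = NULL,
                         spot_chunk = 96L) {
  ctx <- if (inherits(anatomy, "anatomy_instance")) dose_context(anatomy)
         else anatomy
  ctx$beam <- plan$beam
  ret_grid <- is.null(points)
  if (ret_grid) {
    if (is.null(eval_grid))
      eval_grid <- default_eval_grid(ctx$anatomy)
    points <- grid_coords(eval_grid)
  }
  dose <- numeric(nrow(points))
  spots <- plan$spots
  if (nrow(spots) > 0) {
    for (chunk in split(seq_len(nrow(spots)),
                        ceiling(seq_len(nrow(spots)) / spot_chunk))) {
      infl <- dose_influence(ctx, spots[chunk, , drop = FALSE], points,
                             sc, rbe = plan$rbe)
      dose <- dose + as.numeric(infl %*% spots$weight[chunk])
    }
  }
  if (!ret_grid) return(dose)
  eval_grid$values <- array(dose, eval_grid$shape)
  as_dose_grid(eval_grid, fractions = plan$n_fractions, rbe = plan$rbe)
}

as_dose_grid <- function(grid, fractions = 1, rbe = 1.1) {
  grid$fractions_represented <- fractions
  grid$rbe <- rbe
  class(grid) <- c("dose_grid", "voxel_grid")
  grid
}

# 2 mm isotropic evaluation grid over the structure bounding box
default_eval_grid <- function(anatomy, spacing = 2, margin = 10) {
  s <- anatomy$structures
  any_struct <- s$prostate | s$sv | s$rectum | s$bladder
  pts <- grid_coords(anatomy$grid, any_struct)
  grid_from_box(apply(pts, 2, min) - margin,
                apply(pts, 2, max) + margin, spacing)
}

#' Serialize a spot plan to JSON (and back)
#'
#' @param plan an `impt_plan`.
#' @param path file path.
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(
    list(prescription_gy = plan$prescription_gy,
         n_fractions = plan$n_fractions, rbe = plan$rbe,
         beam = unclass(plan$beam), spots = plan$spots,
         meta = plan$meta),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beam <- do.call(beam_model, x$beam[setdiff(names(x$beam), NULL)])
  spot_plan(as.data.frame(x$spots), beam, x$prescription_gy,
            x$n_fractions, x$rbe, as.list(x$meta))
}
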