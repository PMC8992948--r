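#' Patient configuration for the pelvic reference phantom
#'
#' Defines the analytic organ geometry (prostate, paired seminal-vesicle
#' lobes, rectal tube, bladder, pelvic bone shell, body contour), the
#' tissue-class HU values and the voxel grid. With `seed` given, organ
#' sizes and positions are jittered within anatomically plausible bounds so
#' a cohort of synthetic patients is heterogeneous; `seed = NULL` returns
#' the nominal geometry.
#'
#' @param seed optional integer; per-patient geometry jitter.
#' @param spacing voxel pitch in mm (recycled to length 3). The CT-like
#'   profile of the source protocol is `c(1.07, 1.07, 2)`; the default 3 mm
#'   keeps single-phantom work interactive.
#' @return A list of class `patient_config`.
#' @export
patient_config <- function(seed = NULL, spacing = c(3, 3, 3)) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  j <- function(lo, hi) lo  # overwritten below when seeded
  if (!is.null(seed)) {
    rng <- local_rng(as.integer(seed))
    on.exit(rng$restore(), add = TRUE)
    j <- function(lo, hi) stats::runif(1, lo, hi)
  } else {
    j <- function(lo, hi) (lo + hi) / 2
  }
  pr_semi <- c(22, 20, 20) * j(0.90, 1.10)
  sv_semi <- c(9, 7, 16) * j(0.88, 1.12)
  sv_y <- 14 + j(-3, 3); sv_z <- 20 + j(-3, 3)
  re_y <- 36 + j(-1.5, 1.5); re_r <- 15 * j(0.95, 1.08)
  bl_ctr <- c(0, -40 + j(-4, 4), 45 + j(-4, 4))
  bl_semi <- c(42, 34, 34) * j(0.88, 1.12)
  shapes <- list(
    prostate = shape_ellipsoid(c(0, 0, 0), pr_semi),
    sv_left  = shape_ellipsoid(c(13, sv_y, sv_z), sv_semi,
                               anchor = c(13, sv_y, sv_z - sv_semi[3])),
    sv_right = shape_ellipsoid(c(-13, sv_y, sv_z), sv_semi,
                               anchor = c(-13, sv_y, sv_z - sv_semi[3])),
    # posterior wall rests on the sacrum: distension is anterior
    rectum   = shape_tube(c(0, re_y), re_r, c(-65, 55),
                          anchor_xy = c(0, re_y + re_r)),
    bladder  = shape_ellipsoid(bl_ctr, bl_semi,
                               # anchored near the bladder neck: filling
                               # expands the dome anteriorly/superiorly
                               anchor = bl_ctr + c(0, 0.8 * bl_semi[2],
                                                   -0.9 * bl_semi[3])),
    bone     = shape_pelvic_bone(outer = c(120, 88), inner = c(96, 68),
                                 zlim = c(-25.3, 59.8), sector_deg = 48,
                                 sacrum = list(center = c(0, 73.2, 24.9),
                                               semi = c(23.9, 11.4, 29.7))),
    body     = shape_elliptic_cylinder(c(155, 105), c(-69.7, 81.6))
  )
  hu <- c(body = 30, prostate = 45, sv = 40, rectum = 25, bladder = 15,
          bone = 700, air = -1000)
  grid_lo <- c(-162, -110, -72)
  grid_hi <- c(162, 110, 84)
  structure(list(shapes = shapes, hu = hu, spacing = spacing,
                 grid_lo = grid_lo, grid_hi = grid_hi,
                 isocenter = c(0, 0, 0), seed = seed),
            class = "patient_config")
}

#' Water-box validation phantom
#'
#' A homogeneous water body (HU 0) with a rectangular CTV at the
#' isocenter and vestigial distant OAR surrogates, used for dose-engine
#' and optimizer validation.
#'
#' @param ctv_half CTV half-widths (mm).
#' @param spacing voxel pitch (mm).
#' @return a `patient_config`.
#' @export
water_box_config <- function(ctv_half = c(25, 25, 25),
                             spacing = c(4, 4, 4)) {
  cfg <- patient_config(spacing = spacing)
  cfg$shapes$prostate <- shape_box(c(0, 0, 0), ctv_half)
  # SV lobes buried in the CTV box: clipped empty, CTV = box exactly
  cfg$shapes$sv_left <- shape_ellipsoid(c(5, 0, 0), c(2, 2, 2))
  cfg$shapes$sv_right <- shape_ellipsoid(c(-5, 0, 0), c(2, 2, 2))
  cfg$shapes$rectum <- shape_tube(c(0, 90), 6, c(-40, 40))
  cfg$shapes$bladder <- shape_ellipsoid(c(0, -90, 40), c(8, 8, 8))
  cfg$shapes$bone$sector_deg <- 0
  cfg$shapes$bone$sacrum <- list(center = c(0, 0, 0), semi = c(0, 0, 0))
  cfg$hu[] <- c(body = 0, prostate = 0, sv = 0, rectum = 0, bladder = 0,
                bone = 0, air = -1000)
  cfg
}

# RNG sandbox: seed locally, restore global state on exit
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
}

organ_names <- c("prostate", "sv", "rectum", "bladder")

# shapes belonging to a (statistical) organ
organ_shape_keys <- function(organ) {
  if (organ == "sv") c("sv_left", "sv_right") else organ
}

#' Build the planning reference phantom
#'
#' Voxelizes the analytic geometry of a [patient_config()] into an
#' `anatomy_instance`: an HU grid plus boolean structure masks for
#' prostate, SV, rectum, bladder, bone and body, with
#' `CTV = prostate` \eqn{\cup} `SV`. Structures are clipped against each
#' other with priority prostate > SV > rectum > bladder so the label masks
#' are pairwise disjoint.
#'
#' @param config a [patient_config()].
#' @return an object of class `anatomy_instance`.
#' @export
build_reference_phantom <- function(config = patient_config()) {
  check_phantom_geometry(config)
  anat <- new_anatomy(config,
                      states = stats::setNames(
                        replicate(4, identity_state(), simplify = FALSE),
                        organ_names),
                      setup = rigid_transform(isocenter = config$isocenter),
                      variation = NULL, is_reference = TRUE)
  anat$structures <- voxelize_structures(anat)
  anat$grid <- anatomy_hu_grid(anat)
  anat
}

new_anatomy <- function(config, states, setup, variation, is_reference) {
  grid <- grid_from_box(config$grid_lo, config$grid_hi, config$spacing)
  structure(list(config = config, grid = grid, states = states,
                 setup = setup, variation = variation,
                 is_reference = is_reference, structures = NULL),
            class = "anatomy_instance")
}

# reject configurations whose raw organ shapes overlap beyond tolerance
check_phantom_geometry <- function(config, tol = 0.15) {
  keys <- c("prostate", "sv_left", "sv_right", "rectum", "bladder")
  # compare on a coarse probe lattice per pair
  for (i in seq_along(keys)) for (jj in seq_along(keys)) {
    if (jj <= i) next
    a <- config$shapes[[keys[i]]]; b <- config$shapes[[keys[jj]]]
    if (grepl("^sv", keys[i]) && grepl("^sv", keys[jj])) next
    bb <- shape_bbox(a, margin = 0)
    g <- grid_from_box(bb$lo, bb$hi, pmax((bb$hi - bb$lo) / 24, 1))
    pts <- grid_coords(g)
    ina <- shape_inside(a, pts)
    if (!any(ina)) next
    frac <- mean(shape_inside(b, pts[ina, , drop = FALSE]))
    if (frac > tol)
      stop("geometry error: requested organs '", keys[i], "' and '",
           keys[jj], "' overlap by ", round(100 * frac, 1), "%")
  }
  invisible(TRUE)
}

# is each daily-frame point inside the (state-deformed, set-up-shifted)
# organ shape?
organ_inside_daily <- function(anatomy, key, pts) {
  shape <- anatomy$config$shapes[[key]]
  organ <- if (grepl("^sv", key)) "sv" else key
  state <- anatomy$states[[organ]]
  p <- apply_rigid(invert_rigid(anatomy$setup), pts)
  if (!is.null(state)) p <- shape_unscale_points(shape, state, p)
  shape_inside(shape, p)
}

voxelize_structures <- function(anatomy, grid = anatomy$grid) {
  pts <- grid_coords(grid)
  sh <- grid$shape
  as_arr <- function(v) array(v, sh)
  body <- organ_inside_daily(anatomy, "body", pts)
  bone <- organ_inside_daily(anatomy, "bone", pts) & body
  prostate <- organ_inside_daily(anatomy, "prostate", pts) & body & !bone
  sv <- (organ_inside_daily(anatomy, "sv_left", pts) |
         organ_inside_daily(anatomy, "sv_right", pts)) &
        body & !bone & !prostate
  rectum <- organ_inside_daily(anatomy, "rectum", pts) &
            body & !bone & !prostate & !sv
  bladder <- organ_inside_daily(anatomy, "bladder", pts) &
             body & !bone & !prostate & !sv & !rectum
  list(prostate = as_arr(prostate), sv = as_arr(sv),
       rectum = as_arr(rectum), bladder = as_arr(bladder),
       bone = as_arr(bone), body = as_arr(body),
       ctv = as_arr(prostate | sv))
}

anatomy_hu_grid <- function(anatomy) {
  s <- anatomy$structures
  hu <- anatomy$config$hu
  vals <- array(hu[["air"]], anatomy$grid$shape)
  vals[s$body] <- hu[["body"]]
  vals[s$bladder] <- hu[["bladder"]]
  vals[s$rectum] <- hu[["rectum"]]
  vals[s$sv] <- hu[["sv"]]
  vals[s$prostate] <- hu[["prostate"]]
  vals[s$bone] <- hu[["bone"]]
  voxel_grid(vals, anatomy$grid$origin, anatomy$grid$spacing)
}

#' Organ volumes of an anatomy instance
#'
#' `method = "analytic"` evaluates the closed-form volume of each
#' parametric organ shape under its daily state (exact; rigid set-up
#' motion is volume-preserving). `method = "voxel"` voxelizes each organ
#' shape alone (no label-map clipping) inside its bounding box, voxel
#' centres deciding membership — the estimate available when only masks
#' exist.
#'
#' @param anatomy an `anatomy_instance`.
#' @param method `"analytic"` or `"voxel"`.
#' @param spacing voxel pitch for `method = "voxel"` (defaults to the
#'   anatomy grid spacing).
#' @return named numeric vector of volumes in ml.
#' @export
organ_volumes <- function(anatomy, method = c("analytic", "voxel"),
                          spacing = NULL) {
  method <- match.arg(method)
  if (is.null(spacing)) spacing <- anatomy$grid$spacing
  out <- numeric(0)
  for (organ in organ_names) {
    vol <- 0
    for (key in organ_shape_keys(organ)) {
      shape <- anatomy$config$shapes[[key]]
      state <- anatomy$states[[organ]]
      if (method == "analytic") {
        vol <- vol + shape_volume(shape) * state$vol_scale
      } else {
        bb <- shape_bbox(shape, state, anatomy$setup, margin = 4)
        g <- grid_from_box(bb$lo, bb$hi, spacing)
        inside <- organ_inside_daily(anatomy, key, grid_coords(g))
        vol <- vol + sum(inside) * voxel_volume(g)
      }
    }
    out[organ] <- vol / 1000
  }
  out
}

#' @export
print.anatomy_instance <- function(x, ...) {
  cat("<anatomy_instance> ", if (x$is_reference) "planning reference"
      else "daily instance", "\n", sep = "")
  cat("  grid ", paste(x$grid$shape, collapse = " x "), " voxels @ ",
      paste(signif(x$grid$spacing, 3), collapse = "x"), " mm\n", sep = "")
  if (!is.null(x$structures)) {
    vv <- voxel_volume(x$grid) / 1000
    for (s in c("prostate", "sv", "rectum", "bladder")) {
      cat(sprintf("  %-8s %7.1f ml\n", s, sum(x$structures[[s]]) * vv))
    }
  }
  if (!is.null(x$variation)) {
    cat("  volume change (%):",
        paste(sprintf("%s %+.1f", names(x$variation$percent),
                      x$variation$percent), collapse = ", "), "\n")
  }
  invisible(x)
}
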