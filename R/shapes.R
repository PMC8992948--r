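# Analytic organ shapes. Every organ is a parametric region in the planning
# frame; a daily instance carries a per-organ state (volume scale about an
# anatomical anchor, plus a translation) and a whole-patient rigid set-up
# transform. Masks are voxelized by mapping voxel centres back through the
# set-up transform and the organ's affine.

shape_ellipsoid <- function(center, semi, anchor = center) {
  list(type = "ellipsoid", center = as.numeric(center),
       semi = as.numeric(semi), anchor = as.numeric(anchor))
}

shape_box <- function(center, half, anchor = center) {
  list(type = "box", center = as.numeric(center),
       half = as.numeric(half), anchor = as.numeric(anchor))
}

shape_tube <- function(center_xy, radius, zlim, taper = 12,
                       anchor_xy = center_xy) {
  list(type = "tube", center_xy = as.numeric(center_xy), radius = radius,
       zlim = as.numeric(zlim), taper = taper,
       anchor_xy = as.numeric(anchor_xy))
}

shape_elliptic_cylinder <- function(semi_xy, zlim) {
  list(type = "elliptic_cylinder", semi_xy = as.numeric(semi_xy),
       zlim = as.numeric(zlim))
}

# iliac shell with angle-modulated (curved) crest profiles plus an
# ellipsoidal sacrum; curved surfaces let rigid registration resolve
# sub-voxel rotations that flat faces would quantize away
shape_pelvic_bone <- function(outer, inner, zlim, sector_deg, sacrum,
                              crest_amp = c(9, 7)) {
  list(type = "pelvic_bone", outer = as.numeric(outer),
       inner = as.numeric(inner), zlim = as.numeric(zlim),
       sector_deg = sector_deg, sacrum = sacrum,
       crest_amp = as.numeric(crest_amp))
}

identity_state <- function() list(vol_scale = 1, shift = c(0, 0, 0))

# linear scale factor realizing a volume scale for a given shape type
shape_linear_scale <- function(shape, vol_scale) {
  if (shape$type == "tube") sqrt(vol_scale) else vol_scale^(1 / 3)
}

# map daily-frame points back to the undeformed shape frame
shape_unscale_points <- function(shape, state, pts) {
  if (state$vol_scale == 1 && all(state$shift == 0)) return(pts)
  if (shape$type %in% c("ellipsoid", "box")) {
    lin <- state$vol_scale^(1 / 3)
    p <- shape$anchor
    sweep(sweep(pts, 2, state$shift + p, "-") / lin, 2, p, "+")
  } else if (shape$type == "tube") {
    st <- sqrt(state$vol_scale)
    a <- shape$anchor_xy
    out <- sweep(pts, 2, state$shift, "-")
    out[, 1] <- a[1] + (out[, 1] - a[1]) / st
    out[, 2] <- a[2] + (out[, 2] - a[2]) / st
    out
  } else {
    pts  # rigid-only shapes (bone, body) take no state
  }
}

# forward affine of a shape's state (planning frame -> daily local frame)
shape_affine_points <- function(shape, state, pts) {
  if (shape$type %in% c("ellipsoid", "box")) {
    lin <- state$vol_scale^(1 / 3)
    p <- shape$anchor
    sweep(sweep(pts, 2, p, "-") * lin, 2, p + state$shift, "+")
  } else if (shape$type == "tube") {
    st <- sqrt(state$vol_scale)
    a <- shape$anchor_xy
    out <- pts
    out[, 1] <- a[1] + (out[, 1] - a[1]) * st
    out[, 2] <- a[2] + (out[, 2] - a[2]) * st
    sweep(out, 2, state$shift, "+")
  } else pts
}

shape_inside <- function(shape, pts) {
  switch(shape$type,
    ellipsoid = {
      d <- sweep(pts, 2, shape$center, "-")
      (d[, 1] / shape$semi[1])^2 + (d[, 2] / shape$semi[2])^2 +
        (d[, 3] / shape$semi[3])^2 <= 1
    },
    box = {
      d <- abs(sweep(pts, 2, shape$center, "-"))
      d[, 1] <= shape$half[1] & d[, 2] <= shape$half[2] &
        d[, 3] <= shape$half[3]
    },
    tube = {
      dx <- pts[, 1] - shape$center_xy[1]
      dy <- pts[, 2] - shape$center_xy[2]
      dx * dx + dy * dy <= shape$radius^2 &
        pts[, 3] >= shape$zlim[1] & pts[, 3] <= shape$zlim[2]
    },
    elliptic_cylinder = {
      (pts[, 1] / shape$semi_xy[1])^2 + (pts[, 2] / shape$semi_xy[2])^2 <= 1 &
        pts[, 3] >= shape$zlim[1] & pts[, 3] <= shape$zlim[2]
    },
    pelvic_bone = {
      r_out <- (pts[, 1] / shape$outer[1])^2 + (pts[, 2] / shape$outer[2])^2
      r_in <- (pts[, 1] / shape$inner[1])^2 + (pts[, 2] / shape$inner[2])^2
      th <- atan2(pts[, 2], pts[, 1])
      lat <- pmin(abs(th), pi - abs(th)) < shape$sector_deg * pi / 180
      ztop <- shape$zlim[2] - shape$crest_amp[1] * (1 + cos(2 * th)) / 2
      zbot <- shape$zlim[1] + shape$crest_amp[2] * (1 - cos(2 * th)) / 2
      ring <- r_out <= 1 & r_in >= 1 & lat &
        pts[, 3] >= zbot & pts[, 3] <= ztop
      s <- shape$sacrum
      sac <- if (any(s$semi <= 0)) rep(FALSE, nrow(pts)) else {
        d <- sweep(pts, 2, s$center, "-")
        (d[, 1] / s$semi[1])^2 + (d[, 2] / s$semi[2])^2 +
          (d[, 3] / s$semi[3])^2 <= 1
      }
      ring | sac
    },
    stop("unknown shape type: ", shape$type))
}

# dimensionless shape coordinate rho (<= 1 inside), used for the smooth
# compactly-supported displacement carrying surrounding soft tissue
shape_rho <- function(shape, pts) {
  switch(shape$type,
    ellipsoid = {
      d <- sweep(pts, 2, shape$center, "-")
      sqrt((d[, 1] / shape$semi[1])^2 + (d[, 2] / shape$semi[2])^2 +
             (d[, 3] / shape$semi[3])^2)
    },
    box = {
      d <- abs(sweep(pts, 2, shape$center, "-"))
      pmax(d[, 1] / shape$half[1], d[, 2] / shape$half[2],
           d[, 3] / shape$half[3])
    },
    tube = {
      dx <- pts[, 1] - shape$center_xy[1]
      dy <- pts[, 2] - shape$center_xy[2]
      sqrt(dx * dx + dy * dy) / shape$radius
    },
    stop("shape_rho undefined for type ", shape$type))
}

# support weight: 1 inside, smoothstep to 0 at rho = rho_support
shape_support_weight <- function(shape, pts, rho_support = 1.6) {
  rho <- shape_rho(shape, pts)
  w <- numeric(length(rho))
  w[rho <= 1] <- 1
  mid <- rho > 1 & rho < rho_support
  t <- (rho_support - rho[mid]) / (rho_support - 1)
  w[mid] <- t * t * (3 - 2 * t)
  if (shape$type == "tube") {
    # taper the displacement near the open tube ends
    z <- pts[, 3]
    g <- rep(1, length(z))
    lo <- shape$zlim[1] + shape$taper; hi <- shape$zlim[2] - shape$taper
    below <- z < lo; above <- z > hi
    tb <- pmax(0, pmin(1, (z[below] - (shape$zlim[1] - shape$taper)) /
                         (2 * shape$taper)))
    ta <- pmax(0, pmin(1, ((shape$zlim[2] + shape$taper) - z[above]) /
                         (2 * shape$taper)))
    g[below] <- tb * tb * (3 - 2 * tb)
    g[above] <- ta * ta * (3 - 2 * ta)
    w <- w * g
  }
  w
}

# analytic volume (mm^3) of the undeformed shape
shape_volume <- function(shape) {
  switch(shape$type,
    ellipsoid = 4 / 3 * pi * prod(shape$semi),
    box = 8 * prod(shape$half),
    tube = pi * shape$radius^2 * diff(shape$zlim),
    stop("analytic volume undefined for type ", shape$type))
}

# conservative world-frame bounding box of a shape under state + set-up
shape_bbox <- function(shape, state = identity_state(),
                       setup = rigid_transform(), margin = 8) {
  lin <- shape_linear_scale(shape, state$vol_scale)
  box <- switch(shape$type,
    ellipsoid = {
      p <- shape$anchor
      ctr <- p + lin * (shape$center - p) + state$shift
      list(lo = ctr - lin * shape$semi, hi = ctr + lin * shape$semi)
    },
    box = {
      p <- shape$anchor
      ctr <- p + lin * (shape$center - p) + state$shift
      list(lo = ctr - lin * shape$half, hi = ctr + lin * shape$half)
    },
    tube = {
      c2 <- shape$anchor_xy + lin * (shape$center_xy - shape$anchor_xy) +
        state$shift[1:2]
      list(lo = c(c2 - lin * shape$radius, shape$zlim[1] + state$shift[3]),
           hi = c(c2 + lin * shape$radius, shape$zlim[2] + state$shift[3]))
    },
    stop("bbox undefined for type ", shape$type))
  corners <- as.matrix(expand.grid(c(box$lo[1], box$hi[1]),
                                   c(box$lo[2], box$hi[2]),
                                   c(box$lo[3], box$hi[3])))
  tc <- apply_rigid(setup, corners)
  list(lo = apply(tc, 2, min) - margin, hi = apply(tc, 2, max) + margin)
}
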