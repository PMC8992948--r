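# Daily-to-planning alignment (bone rigid matching, prostate-centre
# registration) and deformable dose accumulation onto the planning grid.

#' Recover the rigid set-up error by bone matching
#'
#' Six-axis rigid registration of the daily bone mask to the planning
#' bone mask: closed-form initialization from mask centroids and
#' principal axes (the bone moves rigidly, so its first and second
#' moments determine the transform), optionally refined by maximizing
#' soft mask overlap over the six parameters. Returns the correcting
#' transform, i.e. the one that maps the daily anatomy back onto the
#' reference; for a synthetically applied set-up error it recovers its
#' inverse.
#'
#' @param daily,reference `anatomy_instance`s with non-empty bone masks.
#' @param refine Nelder-Mead refinement iterations on the smoothed-mask
#'   mismatch (0 keeps the closed-form moment estimate, which is what the
#'   trial pipeline uses since the subsequent prostate-centre registration
#'   absorbs residual translation).
#' @return a `rigid_transform` about the planning isocenter.
#' @export
rigid_align_bone <- function(daily, reference, refine = 200L) {
  bd <- daily$structures$bone; br <- reference$structures$bone
  if (is.null(bd) || !any(bd)) stop("daily bone mask is empty")
  if (is.null(br) || !any(br)) stop("reference bone mask is empty")
  iso <- reference$config$isocenter
  pd <- grid_coords(daily$grid, bd)
  pr <- grid_coords(reference$grid, br)
  cd <- colMeans(pd); cr <- colMeans(pr)
  Sd <- stats::cov(pd); Sr <- stats::cov(pr)
  ed <- eigen(Sd, symmetric = TRUE); er <- eigen(Sr, symmetric = TRUE)
  Vd <- ed$vectors; Vr <- er$vectors
  # fix eigenvector signs so the daily axes match the reference axes
  for (i in 1:3) if (sum(Vd[, i] * Vr[, i]) < 0) Vd[, i] <- -Vd[, i]
  R <- Vd %*% t(Vr)
  if (det(R) < 0) { Vd[, 3] <- -Vd[, 3]; R <- Vd %*% t(Vr) }
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3]); rz <- atan2(R[2, 1], R[1, 1])
  t_s <- cd - as.numeric(R %*% (cr - iso)) - iso
  setup_est <- rigid_transform(c(rx, ry, rz) * 180 / pi, t_s, iso)
  if (refine > 0) {
    # smoothed-indicator matching: both masks approximate the same
    # blurred bone indicator, so the mismatch has a smooth sub-voxel
    # minimum at the true transform
    soft_d <- daily$grid
    soft_d$values <- box_blur3(array(as.numeric(bd), daily$grid$shape))
    soft_r <- reference$grid
    soft_r$values <- box_blur3(array(as.numeric(br),
                                     reference$grid$shape))
    band <- which(soft_r$values > 0.05 & soft_r$values < 0.95)
    if (length(band) > 6000)
      band <- band[seq(1, length(band), length.out = 6000)]
    pts <- grid_coords(reference$grid)[band, , drop = FALSE]
    target <- as.numeric(soft_r$values)[band]
    score <- function(par) {
      tr <- rigid_transform(par[1:3], par[4:6], iso)
      mean((interp_trilinear(soft_d, apply_rigid(tr, pts),
                             clamp = TRUE) - target)^2)
    }
    par <- c(setup_est$rotation_deg, setup_est$translation_mm)
    best <- score(par)
    for (round in 1:3) {  # restarted simplex: recovers from collapse
      fit <- stats::optim(par, score, method = "Nelder-Mead",
                          control = list(maxit = refine,
                                         reltol = 1e-12))
      if (fit$value <= best) { par <- fit$par; best <- fit$value }
    }
    setup_est <- rigid_transform(par[1:3], par[4:6], iso)
  }
  invert_rigid(setup_est)
}

# separable 3-D box blur (two passes, radius one voxel)
box_blur3 <- function(a, passes = 2) {
  blur_dim1 <- function(m) {
    n <- dim(m)[1]
    if (n < 3) return(m)
    out <- m
    out[2:(n - 1), , ] <- (m[1:(n - 2), , ] + m[2:(n - 1), , ] +
                             m[3:n, , ]) / 3
    out[1, , ] <- (m[1, , ] + m[2, , ]) / 2
    out[n, , ] <- (m[n - 1, , ] + m[n, , ]) / 2
    out
  }
  for (p in seq_len(passes)) {
    a <- blur_dim1(a)
    a <- aperm(blur_dim1(aperm(a, c(2, 1, 3))), c(2, 1, 3))
    a <- aperm(blur_dim1(aperm(a, c(3, 2, 1))), c(3, 2, 1))
  }
  a
}

#' Register the daily prostate centre to the planning isocenter
#'
#' After the bone correction `after`, the translation that brings the
#' daily prostate centroid (mean of its mask voxel centres) onto the
#' planning isocenter. The isocenter sits at the planning prostate's
#' geometric centre, which is measured from the reference mask with the
#' same centroid estimator so that identical anatomies map to a zero
#' translation exactly.
#'
#' @param daily,reference `anatomy_instance`s.
#' @param after a `rigid_transform` already applied to the daily anatomy
#'   (identity by default).
#' @return length-3 translation (mm).
#' @export
align_prostate_center <- function(daily, reference,
                                  after = rigid_transform()) {
  m <- daily$structures$prostate
  if (is.null(m) || !any(m)) stop("daily prostate mask is empty")
  mr <- reference$structures$prostate
  if (is.null(mr) || !any(mr)) stop("reference prostate mask is empty")
  ctr <- colMeans(apply_rigid(after, grid_coords(daily$grid, m)))
  colMeans(grid_coords(reference$grid, mr)) - ctr
}

#' Apply a rigid transform to an anatomy instance
#'
#' Composes the transform into the instance's rigid set-up component and
#' re-voxelizes masks and HU exactly from the analytic geometry (no
#' interpolation).
#'
#' @param anatomy an `anatomy_instance`.
#' @param transform a `rigid_transform` about the same isocenter.
#' @param voxelize rebuild masks/HU immediately.
#' @export
transform_anatomy <- function(anatomy, transform, voxelize = TRUE) {
  out <- anatomy
  tr <- transform
  tr$isocenter <- anatomy$setup$isocenter
  out$setup <- compose_rigid(tr, anatomy$setup)
  out$is_reference <- out$is_reference && is_identity_rigid(transform)
  if (voxelize) {
    out$structures <- voxelize_structures(out)
    out$grid <- anatomy_hu_grid(out)
  } else {
    out$structures <- NULL
  }
  out
}

#' Map a fraction dose onto the planning grid through the known
#' deformation
#'
#' Pull-back with trilinear interpolation: the dose at planning voxel `x`
#' is the fraction dose at the daily position `phi(x)` given by the
#' generator's ground-truth deformation of `daily`. Voxels whose mapped
#' position falls outside the fraction-dose grid receive 0 and are
#' counted in `attr(, "n_outside")`.
#'
#' @param fraction_dose `dose_grid` computed on the daily anatomy.
#' @param daily the daily `anatomy_instance` carrying its deformation
#'   (after any alignment applied to it).
#' @param ref_grid `voxel_grid` defining the planning-grid geometry of
#'   the output.
#' @return `dose_grid` on `ref_grid`'s geometry.
#' @export
map_dose_to_reference <- function(fraction_dose, daily, ref_grid) {
  if (is.null(daily$states)) stop("daily instance carries no deformation")
  pts <- grid_coords(ref_grid)
  mapped <- deform_forward(daily, pts)
  vals <- interp_trilinear(fraction_dose, mapped, clamp = FALSE,
                           outside = NA_real_)
  n_outside <- sum(is.na(vals))
  vals[is.na(vals)] <- 0
  out <- ref_grid
  out$values <- array(vals, ref_grid$shape)
  out <- as_dose_grid(out, fractions = fraction_dose$fractions_represented
                      %||% 1, rbe = fraction_dose$rbe %||% 1.1)
  attr(out, "n_outside") <- n_outside
  out
}

#' Sum mapped fraction doses into the accumulated course dose
#'
#' @param mapped_doses list of co-registered `dose_grid`s on the planning
#'   grid, one per fraction (the full course: 21 by default).
#' @param expected_n required fraction count.
#' @param provenance optional list recorded in the result.
#' @return object of class `accumulated_dose` (also a `dose_grid`).
#' @export
accumulate_dose <- function(mapped_doses, expected_n = 21,
                            provenance = NULL) {
  if (length(mapped_doses) != expected_n)
    stop("expected ", expected_n, " mapped fraction doses, got ",
         length(mapped_doses))
  g0 <- mapped_doses[[1]]
  for (g in mapped_doses[-1]) {
    if (!isTRUE(all.equal(g$origin, g0$origin)) ||
        !identical(g$shape, g0$shape) ||
        !isTRUE(all.equal(g$spacing, g0$spacing)))
      stop("mapped fraction doses are not co-registered")
  }
  total <- Reduce(`+`, lapply(mapped_doses, function(g) g$values))
  out <- g0
  out$values <- total
  out <- as_dose_grid(out, fractions = expected_n, rbe = g0$rbe %||% 1.1)
  out$provenance <- provenance
  class(out) <- c("accumulated_dose", class(out))
  out
}

#' Scale a single-fraction dose to the full course
#'
#' Worst-case fractional evaluation: one fraction times the fraction
#' count. Refuses doses that already represent more than one fraction.
#'
#' @param fraction_dose a `dose_grid` with `fractions_represented == 1`.
#' @param n_fractions course fraction count.
#' @export
scale_fraction_dose <- function(fraction_dose, n_fractions = 21) {
  fr <- fraction_dose$fractions_represented %||% 1
  if (fr != 1)
    stop("dose already represents ", fr, " fractions; refusing to rescale")
  out <- fraction_dose
  out$values <- out$values * n_fractions
  out$fractions_represented <- n_fractions
  out
}

# course dose -> single-fraction dose
fraction_dose_from_course <- function(course_dose, n_fractions) {
  out <- course_dose
  out$values <- out$values / n_fractions
  out$fractions_represented <- 1
  out
}
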