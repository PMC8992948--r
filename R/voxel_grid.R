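#' Voxel grid container
#'
#' A `voxel_grid` holds a scalar field (HU, relative stopping power, dose or
#' labels) on a regular axis-aligned grid in world millimetre coordinates
#' (LPS: +x left, +y posterior, +z superior). `origin` is the world position
#' of the centre of the first voxel; `spacing` the voxel pitch per axis.
#'
#' @param values numeric or logical 3-D array, dimensions `(nx, ny, nz)`.
#' @param origin numeric length-3, mm (centre of voxel `[1,1,1]`).
#' @param spacing numeric length-3, mm, strictly positive.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, origin, spacing) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("origin and spacing must have length 3")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  structure(list(values = values, origin = origin, spacing = spacing,
                 shape = dim(values)), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  origin (", paste(signif(x$origin, 5), collapse = ", "),
      ") mm; value range [", signif(min(x$values), 5), ", ",
      signif(max(x$values), 5), "]\n", sep = "")
  invisible(x)
}

#' Voxel-centre world coordinates along one axis
#' @param grid a `voxel_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of centre coordinates (mm).
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' All voxel-centre coordinates of a grid (or of a mask subset)
#'
#' @param grid a `voxel_grid`.
#' @param mask optional logical array of the grid's shape; if given, only
#'   coordinates of `TRUE` voxels are returned.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
grid_coords <- function(grid, mask = NULL) {
  sh <- grid$shape
  if (is.null(mask)) {
    idx <- arrayInd(seq_len(prod(sh)), sh)
  } else {
    idx <- which(mask)
    if (length(idx) == 0L) return(matrix(numeric(0), 0, 3))
    idx <- arrayInd(idx, sh)
  }
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Empty grid with the same geometry as another
#' @param grid template `voxel_grid`.
#' @param fill fill value.
#' @export
grid_like <- function(grid, fill = 0) {
  voxel_grid(array(fill, grid$shape), grid$origin, grid$spacing)
}

#' Build a grid covering a world-coordinate box
#'
#' @param lower,upper numeric length-3 box corners (mm).
#' @param spacing voxel pitch (mm), recycled to length 3.
#' @export
grid_from_box <- function(lower, upper, spacing) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  n <- pmax(1L, as.integer(ceiling((upper - lower) / spacing)) + 1L)
  voxel_grid(array(0, n), lower, spacing)
}

voxel_volume <- function(grid) prod(grid$spacing)

#' Trilinear interpolation of a grid at arbitrary points
#'
#' Points outside the grid are clamped to the boundary (`clamp = TRUE`)
#' or given `outside` (default 0).
#'
#' @param grid a `voxel_grid` (numeric values).
#' @param points n x 3 matrix of world coordinates (mm).
#' @param clamp clamp out-of-grid points to the border instead of `outside`.
#' @param outside value assigned to out-of-grid points when `clamp = FALSE`.
#' @return numeric vector of interpolated values.
#' @export
interp_trilinear <- function(grid, points, clamp = FALSE, outside = 0) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  sh <- grid$shape
  # continuous 1-based voxel index of each point
  u <- sweep(sweep(points, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
  inside <- u[, 1] >= 1 & u[, 1] <= sh[1] &
            u[, 2] >= 1 & u[, 2] <= sh[2] &
            u[, 3] >= 1 & u[, 3] <= sh[3]
  uc <- pmin(pmax(u[, 1], 1), sh[1])
  vc <- pmin(pmax(u[, 2], 1), sh[2])
  wc <- pmin(pmax(u[, 3], 1), sh[3])
  i0 <- pmin(floor(uc), sh[1] - 1); i0[sh[1] == 1] <- 1
  j0 <- pmin(floor(vc), sh[2] - 1); j0[sh[2] == 1] <- 1
  k0 <- pmin(floor(wc), sh[3] - 1); k0[sh[3] == 1] <- 1
  fx <- uc - i0; fy <- vc - j0; fz <- wc - k0
  i1 <- pmin(i0 + 1, sh[1]); j1 <- pmin(j0 + 1, sh[2]); k1 <- pmin(k0 + 1, sh[3])
  v <- as.numeric(grid$values)
  at <- function(i, j, k) v[i + (j - 1) * sh[1] + (k - 1) * sh[1] * sh[2]]
  out <- at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
         at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
         at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
         at(i1, j1, k0) * fx       * fy       * (1 - fz) +
         at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
         at(i1, j0, k1) * fx       * (1 - fy) * fz +
         at(i0, j1, k1) * (1 - fx) * fy       * fz +
         at(i1, j1, k1) * fx       * fy       * fz
  if (!clamp) out[!inside] <- outside
  out
}
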