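#' Six-degree-of-freedom rigid transform
#'
#' Rotation (degrees, applied as Rz Ry Rx about the isocenter) followed by
#' translation: `T(x) = R (x - iso) + iso + t`. The planning isocenter is
#' the world origin unless stated otherwise.
#'
#' @param rotation_deg length-3 rotation angles about x, y, z (degrees).
#' @param translation_mm length-3 translation (mm).
#' @param isocenter centre of rotation (mm), default the origin.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            isocenter = c(0, 0, 0)) {
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm),
                 isocenter = as.numeric(isocenter)),
            class = "rigid_transform")
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix (mm).
#' @export
apply_rigid <- function(transform, points) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  R <- rotation_matrix(transform$rotation_deg)
  ctr <- sweep(points, 2, transform$isocenter, "-")
  sweep(ctr %*% t(R), 2,
        transform$isocenter + transform$translation_mm, "+")
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  R <- rotation_matrix(transform$rotation_deg)
  # inverse map: x = R^T (y - iso - t) + iso; express in same parameterization
  a <- transform$rotation_deg * pi / 180
  # extract angles of R^T = (Rz Ry Rx)^T; solve generally from the matrix
  Rt <- t(R)
  ry <- asin(-Rt[3, 1])
  rx <- atan2(Rt[3, 2], Rt[3, 3])
  rz <- atan2(Rt[2, 1], Rt[1, 1])
  inv_t <- -Rt %*% transform$translation_mm
  rigid_transform(c(rx, ry, rz) * 180 / pi, as.numeric(inv_t),
                  transform$isocenter)
}

#' Compose two rigid transforms (`first` applied first)
#' @param second,first `rigid_transform`s about the same isocenter.
#' @export
compose_rigid <- function(second, first) {
  stopifnot(max(abs(second$isocenter - first$isocenter)) < 1e-9)
  R2 <- rotation_matrix(second$rotation_deg)
  R1 <- rotation_matrix(first$rotation_deg)
  R <- R2 %*% R1
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  t_new <- as.numeric(R2 %*% first$translation_mm) + second$translation_mm
  rigid_transform(c(rx, ry, rz) * 180 / pi, t_new, first$isocenter)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rot (deg):",
      paste(signif(x$rotation_deg, 4), collapse = ", "),
      "; trans (mm):",
      paste(signif(x$translation_mm, 4), collapse = ", "), "\n")
  invisible(x)
}

is_identity_rigid <- function(transform, tol = 1e-9) {
  max(abs(transform$rotation_deg)) < tol &&
    max(abs(transform$translation_mm)) < tol
}

#' Serialize / restore a rigid transform as JSON
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @export
write_rigid_json <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rigid_json
#' @export
read_rigid_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation_deg, x$translation_mm, x$isocenter)
}
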