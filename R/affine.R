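#' 12-parameter affine spatial transform
#'
#' World-to-world mapping parameterised as translation (mm), rotation
#' (radians, applied about x, then y, then z), anisotropic scale and
#' shear, composed as `world' = T . Rz Ry Rx . Shear . Scale . world`.
#' An optional rotation `center` (world mm) conjugates the linear part so
#' rotations/scales pivot about it instead of the world origin.
#'
#' @param translation_mm numeric length 3.
#' @param rotation_rad numeric length 3.
#' @param scale numeric length 3, strictly positive.
#' @param shear numeric length 3 (xy, xz, yz upper-triangular terms).
#' @param center numeric length 3, world mm; pivot of the linear part.
#' @return An object of class `affine_transform`.
#' @examples
#' affine_matrix(affine_identity())  # 4x4 identity
#' @export
affine_transform <- function(translation_mm = c(0, 0, 0),
                             rotation_rad = c(0, 0, 0),
                             scale = c(1, 1, 1),
                             shear = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  stopifnot(length(translation_mm) == 3, length(rotation_rad) == 3,
            length(scale) == 3, length(shear) == 3, length(center) == 3)
  if (any(scale <= 0)) stop("scale components must be positive", call. = FALSE)
  structure(list(translation_mm = as.numeric(translation_mm),
                 rotation_rad = as.numeric(rotation_rad),
                 scale = as.numeric(scale),
                 shear = as.numeric(shear),
                 center = as.numeric(center)),
            class = "affine_transform")
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform()

rotation_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' 4x4 matrix form of an affine transform
#'
#' @param transform an [affine_transform].
#' @return 4x4 numeric matrix (the authoritative form).
#' @export
affine_matrix <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  Sh <- rbind(c(1, transform$shear[1], transform$shear[2]),
              c(0, 1, transform$shear[3]),
              c(0, 0, 1))
  M <- rotation_matrix(transform$rotation_rad) %*% Sh %*% diag(transform$scale)
  cen <- transform$center
  t_eff <- transform$translation_mm + cen - M %*% cen
  out <- diag(4)
  out[1:3, 1:3] <- M
  out[1:3, 4] <- t_eff
  out
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  cat("  translation (mm):", signif(x$translation_mm, 4), "\n")
  cat("  rotation (deg):  ", signif(x$rotation_rad * 180 / pi, 4), "\n")
  cat("  scale:           ", signif(x$scale, 4), "\n")
  cat("  shear:           ", signif(x$shear, 4), "\n")
  invisible(x)
}

#' Invert an affine transform (matrix form)
#'
#' @param transform an [affine_transform] or 4x4 matrix.
#' @return 4x4 matrix of the inverse map.
#' @export
affine_invert <- function(transform) {
  M <- if (inherits(transform, "affine_transform")) affine_matrix(transform)
       else as.matrix(transform)
  solve(M)
}

#' Serialize / restore a transform as JSON
#'
#' Both the 12 named parameters and the 4x4 matrix are stored; on reading,
#' the matrix is authoritative.
#'
#' @param transform an [affine_transform].
#' @param path JSON file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a list with `matrix` (4x4) and `parameters`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "affine_transform"))
  obj <- list(parameters = list(translation_mm = transform$translation_mm,
                                rotation_rad = transform$rotation_rad,
                                scale = transform$scale,
                                shear = transform$shear,
                                center = transform$center),
              matrix = affine_matrix(transform))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(matrix = matrix(as.numeric(obj$matrix), 4, 4),
       parameters = obj$parameters)
}
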