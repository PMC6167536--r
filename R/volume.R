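#' 3D brain volume with a voxel-to-world affine
#'
#' The universal image currency of the package: a 3D scalar grid together
#' with a 4x4 affine mapping 0-based voxel indices to world coordinates in
#' millimetres (RAS+: +x towards subject right, +y anterior, +z superior).
#' Background voxels are exactly 0 by convention; all other values must be
#' finite.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix mapping 0-based voxel index
#'   `(i, j, k, 1)` to world mm. Must be invertible.
#' @return An object of class `pet_volume` with elements `data`, `affine`
#'   and `voxel_size_mm` (the Euclidean norms of the three spatial columns).
#' @examples
#' v <- pet_volume(array(0, dim = c(8, 8, 8)), diag(c(3, 3, 3, 1)))
#' voxel_size(v)
#' @export
pet_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) {
    data <- array(data, dim = dim(data)[1:3])
  }
  if (length(dim(data)) != 3L) {
    stop("volume data must be a 3D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1", call. = FALSE)
  affine <- unclass(as.matrix(affine))
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4", call. = FALSE)
  d <- det(affine)
  if (!is.finite(d) || abs(d) < 1e-12) stop("affine is singular", call. = FALSE)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, affine = affine, voxel_size_mm = vs),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  fg <- x$data != 0
  cat("  foreground: ", sum(fg), " voxels, range [",
      if (any(fg)) signif(min(x$data[fg]), 4) else NA, ", ",
      if (any(fg)) signif(max(x$data[fg]), 4) else NA, "]\n", sep = "")
  invisible(x)
}

#' @rdname pet_volume
#' @param x a `pet_volume`.
#' @export
voxel_size <- function(x) x$voxel_size_mm

#' World coordinates of all voxel centres
#'
#' @param vol a `pet_volume`.
#' @param mask optional logical array on the same grid; only those voxels.
#' @return n x 3 matrix of world mm coordinates.
#' @keywords internal
voxel_world_coords <- function(vol, mask = NULL) {
  d <- dim(vol$data)
  if (is.null(mask)) {
    idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1,
                                 j = seq_len(d[2]) - 1,
                                 k = seq_len(d[3]) - 1))
  } else {
    idx <- which(mask, arr.ind = TRUE) - 1
  }
  w <- cbind(idx, 1) %*% t(vol$affine)
  w[, 1:3, drop = FALSE]
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [pet_volume]. Integer-typed
#' files are promoted to double; 4D files with a single timepoint are
#' squeezed to 3D.
#'
#' @param path path to an existing NIfTI-1 file.
#' @return A [pet_volume].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[4] != 1L) {
      stop("4D NIfTI with ", d[4], " timepoints; only single-timepoint ",
           "volumes are supported", call. = FALSE)
    }
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), dim = d)
  } else {
    stop("expected a 3D (or degenerate 4D) NIfTI, got ", length(d),
         " dimensions", call. = FALSE)
  }
  aff <- structure(RNifti::xform(img), code = NULL, imagedim = NULL)
  pet_volume(img2, matrix(as.numeric(aff), 4, 4))
}

#' Write a volume as NIfTI-1
#'
#' The affine is stored as the sform (code 2; the quaternion qform cannot
#' represent shear); data are written as float64 so read/write
#' round-trips are bit-identical.
#'
#' @param volume a [pet_volume] with all-finite data.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  if (any(!is.finite(volume$data))) {
    stop("volume contains non-finite values; refusing to write", call. = FALSE)
  }
  # sform only: the quaternion qform cannot represent shear
  img <- RNifti::asNifti(array(volume$data, dim = dim(volume$data)))
  RNifti::pixdim(img) <- volume$voxel_size_mm
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a target grid under an affine transform
#'
#' Output voxel values are pulled from the source at the world coordinates
#' obtained by mapping each target voxel centre through the inverse of
#' `transform` (a world-to-world map taking source anatomy onto the
#' target). Out-of-field voxels are set to 0. Use `nearest` for label
#' volumes.
#'
#' @param source a [pet_volume].
#' @param transform an [affine_transform] or a plain 4x4 world-to-world
#'   matrix; the identity by default.
#' @param target_grid a [pet_volume] (only its grid is used) or a list
#'   with elements `dim` and `affine`.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return A [pet_volume] on the target grid.
#' @export
resample <- function(source, transform = affine_identity(), target_grid,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  Tm <- if (inherits(transform, "affine_transform")) {
    affine_matrix(transform)
  } else {
    as.matrix(transform)
  }
  d <- det(Tm)
  if (!is.finite(d) || abs(d) < 1e-12) stop("singular transform", call. = FALSE)
  if (inherits(target_grid, "pet_volume")) {
    odim <- dim(target_grid$data)
    oaff <- target_grid$affine
  } else {
    odim <- as.integer(target_grid$dim)
    oaff <- as.matrix(target_grid$affine)
  }
  # combined map: output voxel index -> source voxel index
  M <- solve(source$affine) %*% solve(Tm) %*% oaff
  out <- cpp_affine_resample(as.numeric(source$data), dim(source$data), M,
                             as.integer(odim),
                             if (interpolation == "nearest") 1L else 0L)
  pet_volume(array(out, dim = odim), oaff)
}

#' Gaussian smoothing by FWHM in millimetres
#'
#' Separable Gaussian filter with per-axis
#' `sigma_voxels = fwhm_mm / (voxel_size * sqrt(8 log 2))`. The kernel is
#' normalised to unit sum, so total intensity is conserved away from the
#' (zero-padded) boundary.
#'
#' @param volume a [pet_volume].
#' @param fwhm_mm positive kernel full width at half maximum, mm.
#' @return A smoothed [pet_volume] on the same grid.
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "pet_volume"), fwhm_mm > 0)
  if (fwhm_mm < min(volume$voxel_size_mm) / 2) {
    warning("fwhm_mm = ", fwhm_mm, " mm is smaller than half a voxel; ",
            "applying anyway", call. = FALSE)
  }
  x <- as.numeric(volume$data)
  d <- dim(volume$data)
  for (axis in 0:2) {
    sigma <- fwhm_mm / (volume$voxel_size_mm[axis + 1] * sqrt(8 * log(2)))
    r <- max(1L, as.integer(ceiling(4 * sigma)))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k <- k / sum(k)
    x <- cpp_convolve_axis(x, d, k, axis)
  }
  pet_volume(array(x, dim = d), volume$affine)
}

#' Downsample a volume by an integer factor (for registration pyramids)
#'
#' Smooths with a factor-matched Gaussian (anti-aliasing) and decimates by
#' strided sampling; the affine is updated so world coordinates are
#' preserved.
#'
#' @param volume a [pet_volume].
#' @param factor integer >= 1.
#' @return A [pet_volume].
#' @keywords internal
downsample_volume <- function(volume, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(volume)
  sm <- gaussian_smooth(volume, fwhm_mm = 2.3548 * 0.5 * factor *
                          mean(volume$voxel_size_mm))
  d <- dim(sm$data)
  ii <- seq(1L, d[1], by = factor)
  jj <- seq(1L, d[2], by = factor)
  kk <- seq(1L, d[3], by = factor)
  aff <- sm$affine
  aff[, 1:3] <- aff[, 1:3] * factor
  pet_volume(sm$data[ii, jj, kk, drop = FALSE], aff)
}

#' Named standard-space grid presets
#'
#' Grid geometries of the common normalization targets: the pediatric
#' 1-mm standard space (197 x 233 x 189), the adult 2-mm standard space
#' (91 x 109 x 91), and the 3-mm phantom grid used by the synthetic
#' cohort. Origins are placed so the grid centre is world (0, 0, 0),
#' RAS+.
#'
#' @param name one of `"pediatric_1mm"`, `"adult_2mm"`, `"phantom_3mm"`.
#' @return A list with `dim` (integer length 3) and `affine` (4x4),
#'   usable as the `target_grid` of [resample()].
#' @export
grid_preset <- function(name = c("pediatric_1mm", "adult_2mm",
                                 "phantom_3mm")) {
  name <- match.arg(name)
  geom <- switch(name,
                 pediatric_1mm = list(dim = c(197L, 233L, 189L), vox = 1),
                 adult_2mm = list(dim = c(91L, 109L, 91L), vox = 2),
                 phantom_3mm = list(dim = c(64L, 76L, 64L), vox = 3))
  org <- -geom$vox * (geom$dim - 1) / 2
  aff <- diag(c(geom$vox, geom$vox, geom$vox, 1))
  aff[1:3, 4] <- org
  list(dim = geom$dim, affine = aff)
}
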