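#' Atlas label volume with a region legend
#'
#' An integer label grid aligned to a volume grid, plus a legend mapping
#' each label to a region name, lobe and hemisphere. Label 0 is
#' background. Any conforming parcellation is accepted; the phantom
#' module generates one with six cortical lobe regions and two cerebellar
#' hemispheres.
#'
#' @param labels 3D integer array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param legend data frame with columns `label`, `region_name`, `lobe`
#'   (one of frontal, temporal, parietal_occipital, cerebellum, other)
#'   and `hemisphere` (left, right, midline).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, affine, legend) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  req <- c("label", "region_name", "lobe", "hemisphere")
  if (!all(req %in% names(legend))) {
    stop("legend must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  lobes <- c("frontal", "temporal", "parietal_occipital", "cerebellum", "other")
  hemis <- c("left", "right", "midline")
  if (!all(legend$lobe %in% lobes)) stop("invalid lobe in legend", call. = FALSE)
  if (!all(legend$hemisphere %in% hemis)) {
    stop("invalid hemisphere in legend", call. = FALSE)
  }
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, legend$label)
  if (length(missing) > 0) {
    stop("labels present in grid but absent from legend: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, affine = as.matrix(affine),
                 legend = as.data.frame(legend)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", nrow(x$legend), " regions\n", sep = "")
  print(x$legend)
  invisible(x)
}

#' Read / write an atlas label volume (NIfTI + legend TSV)
#'
#' @param nifti_path label image path.
#' @param legend_path TSV with columns label, region_name, lobe, hemisphere.
#' @return A [label_volume].
#' @export
read_label_volume <- function(nifti_path, legend_path) {
  vol <- read_nifti(nifti_path)
  legend <- utils::read.table(legend_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  label_volume(array(as.integer(round(vol$data)), dim = dim(vol$data)),
               vol$affine, legend)
}

#' @rdname read_label_volume
#' @param atlas a [label_volume].
#' @export
write_label_volume <- function(atlas, nifti_path, legend_path) {
  stopifnot(inherits(atlas, "label_volume"))
  write_nifti(pet_volume(array(as.numeric(atlas$labels),
                               dim = dim(atlas$labels)), atlas$affine),
              nifti_path)
  utils::write.table(atlas$legend, legend_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(nifti_path)
}

#' Binary mask of the atlas regions in a given lobe
#'
#' @param atlas a [label_volume].
#' @param lobe lobe name, e.g. `"cerebellum"`.
#' @param hemisphere optional hemisphere restriction.
#' @return Logical array on the atlas grid.
#' @export
lobe_mask <- function(atlas, lobe, hemisphere = NULL) {
  sel <- atlas$legend$lobe == lobe
  if (!is.null(hemisphere)) sel <- sel & atlas$legend$hemisphere == hemisphere
  array(atlas$labels %in% atlas$legend$label[sel], dim = dim(atlas$labels))
}
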