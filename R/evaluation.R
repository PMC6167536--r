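#' Cohen's kappa for paired categorical calls
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between
#' two raters (e.g. an automated pipeline and the multidisciplinary-team
#' diagnosis) on one axis (lateralization or localization). When expected
#' agreement is 1 (both raters constant on the same category), kappa is
#' defined as 1 if observed agreement is also 1 and is an error otherwise.
#'
#' @param call_a,call_b character vectors of equal length, or `call_a`
#'   may be a 2-way contingency `table`/matrix (categories in rows for
#'   rater a, columns for rater b) with `call_b` missing.
#' @param categories optional fixed category alphabet.
#' @return Scalar kappa in [-1, 1].
#' @export
cohen_kappa <- function(call_a, call_b = NULL, categories = NULL) {
  if (is.null(call_b)) {
    tab <- as.matrix(call_a)
    if (nrow(tab) != ncol(tab)) stop("table must be square", call. = FALSE)
  } else {
    if (length(call_a) != length(call_b) || length(call_a) == 0) {
      stop("call_a and call_b must be nonempty and of equal length",
           call. = FALSE)
    }
    if (is.null(categories)) categories <- sort(unique(c(call_a, call_b)))
    fa <- factor(call_a, levels = categories)
    fb <- factor(call_b, levels = categories)
    if (any(is.na(fa)) || any(is.na(fb))) {
      stop("calls outside the declared category alphabet", call. = FALSE)
    }
    tab <- table(fa, fb)
  }
  n <- sum(tab)
  if (n == 0) stop("empty call set", call. = FALSE)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    if (po == 1) return(1)
    stop("expected agreement is 1 but observed is not; kappa undefined",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Landis-Koch agreement band for a kappa value
#'
#' Bands: 0.01-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-0.99 almost perfect; kappa <= 0 is
#' poor/none and kappa ~ 1 is almost perfect. Values falling between the
#' printed band edges are assigned by rounding to two decimals first.
#'
#' @param kappa scalar in [-1, 1].
#' @return Band label string.
#' @examples
#' kappa_category(0.489)  # "moderate"
#' kappa_category(0.826)  # "almost perfect"
#' @export
kappa_category <- function(kappa) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  # half-up rounding to 2 decimals (round() would take 0.205 down: its
  # binary representation is just below the midpoint)
  k <- sign(kappa) * floor(abs(kappa) * 100 + 0.5) / 100
  if (k <= 0) "poor/none"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Validation record for one resected patient
#'
#' @param patient_id string.
#' @param cluster_table a [threshold_statmap()] result.
#' @param resection_mask binary [pet_volume] in patient-anatomy space.
#' @param map_to_anatomy [affine_transform] (or 4x4 matrix) taking
#'   template-space world coordinates to anatomy-space world coordinates;
#'   identity when the map already lives in anatomy space.
#' @param engel_class post-surgical outcome class `"I"`..`"IV"`;
#'   only class I (seizure-free) patients enter sensitivity.
#' @return An object of class `validation_record`.
#' @export
validation_record <- function(patient_id, cluster_table, resection_mask,
                              map_to_anatomy = affine_identity(),
                              engel_class = "I") {
  engel_class <- match.arg(engel_class, c("I", "II", "III", "IV"))
  stopifnot(inherits(cluster_table, "cluster_table"),
            inherits(resection_mask, "pet_volume"))
  if (!any(resection_mask$data != 0)) {
    stop("resection mask is empty", call. = FALSE)
  }
  structure(list(patient_id = patient_id, cluster_table = cluster_table,
                 resection_mask = resection_mask,
                 map_to_anatomy = map_to_anatomy,
                 engel_class = engel_class),
            class = "validation_record")
}

peak_cluster_in_anatomy <- function(record) {
  ct <- record$cluster_table
  hypo <- ct$clusters[ct$clusters$direction == "hypo", , drop = FALSE]
  if (nrow(hypo) == 0) return(NULL)
  top <- hypo[1, ]
  cl_mask <- pet_volume(array(as.numeric(ct$label_map == top$cluster_id),
                              dim = dim(ct$label_map)), ct$affine)
  moved <- resample(cl_mask, record$map_to_anatomy, record$resection_mask,
                    interpolation = "nearest")
  Tm <- if (inherits(record$map_to_anatomy, "affine_transform")) {
    affine_matrix(record$map_to_anatomy)
  } else as.matrix(record$map_to_anatomy)
  peak_anat <- (Tm %*% c(top$peak_x_mm, top$peak_y_mm, top$peak_z_mm, 1))[1:3]
  list(mask = moved$data != 0, peak_world = peak_anat, peak_t = top$peak_t)
}

#' Is the peak cluster in the hemisphere of the resection?
#'
#' True when the peak voxel of the most significant hypometabolic
#' cluster, mapped to anatomy space, lies on the same side of the
#' mid-sagittal plane (world x = `midline_x`) as the centroid of the
#' resection mask. An empty cluster table yields `FALSE` with reason
#' attribute `"no significant cluster"`.
#'
#' @param record a [validation_record()].
#' @param midline_x world-x of the mid-sagittal plane, mm.
#' @return Logical scalar.
#' @export
lateralization_correct <- function(record, midline_x = 0) {
  pk <- peak_cluster_in_anatomy(record)
  if (is.null(pk)) {
    return(structure(FALSE, reason = "no significant cluster"))
  }
  sel <- record$resection_mask$data != 0
  w <- voxel_world_coords(record$resection_mask, sel)
  centroid_x <- mean(w[, 1])
  sign(pk$peak_world[1] - midline_x) == sign(centroid_x - midline_x)
}

#' Does the peak cluster colocalize with the resection?
#'
#' True when at least one voxel of the most significant hypometabolic
#' cluster, mapped to anatomy space by nearest-neighbour resampling,
#' falls inside the resection mask (any-overlap rule, the binary
#' counterpart of [resection_overlap_percent()]).
#'
#' @param record a [validation_record()].
#' @return Logical scalar.
#' @export
localization_correct <- function(record) {
  pk <- peak_cluster_in_anatomy(record)
  if (is.null(pk)) {
    return(structure(FALSE, reason = "no significant cluster"))
  }
  any(pk$mask & record$resection_mask$data != 0)
}

#' Sensitivity over a set of validation outcomes
#'
#' The proportion of patients in whom the statistical-map maximum
#' correctly lateralized (or colocalized with) the resected area.
#'
#' @param outcomes nonempty logical vector.
#' @return Fraction in [0, 1].
#' @export
sensitivity <- function(outcomes) {
  if (length(outcomes) == 0) stop("empty outcome list", call. = FALSE)
  mean(as.logical(outcomes))
}

#' Percentage of peak-cluster voxels inside the resection cavity
#'
#' `100 * |cluster intersect mask| / |cluster|` with the most significant
#' hypometabolic cluster mapped to anatomy space by nearest-neighbour
#' resampling of its binary mask. Undefined (NA, with a reason) when no
#' cluster survives thresholding or the mapped cluster is empty.
#'
#' @param record a [validation_record()].
#' @return Scalar percent, or `NA` with a `reason` attribute.
#' @export
resection_overlap_percent <- function(record) {
  pk <- peak_cluster_in_anatomy(record)
  if (is.null(pk)) {
    return(structure(NA_real_, reason = "no significant cluster"))
  }
  ncl <- sum(pk$mask)
  if (ncl == 0) {
    return(structure(NA_real_, reason = "cluster maps outside anatomy grid"))
  }
  100 * sum(pk$mask & record$resection_mask$data != 0) / ncl
}
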