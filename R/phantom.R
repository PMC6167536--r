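#' Specification of the synthetic brain phantom
#'
#' Defines the canonical grid, tissue uptake means, the point-spread
#' blur, voxel noise, per-subject affine variability and the global
#' uptake scale range used when simulating control cohorts and patients.
#' Defaults emulate reconstructed pediatric FDG-PET at desk scale: a 3-mm
#' isotropic grid, cortical/cerebellar grey matter uptake 1.0 with white
#' matter at 0.35 and CSF near zero, a 6-mm reconstruction point spread,
#' 5% voxel noise, moderate inter-subject head pose/size variability, and
#' a wide global uptake scale spread standing in for the dose-per-weight
#' range seen clinically.
#'
#' @param grid_shape integer length 3.
#' @param voxel_size_mm scalar, isotropic voxel size.
#' @param uptake named list of tissue uptake means.
#' @param noise_sd voxelwise Gaussian noise SD (relative to cortex 1.0),
#'   applied after global scaling (scaled by the subject's global factor).
#' @param max_translation_mm,max_rotation_deg,scale_range,max_shear
#'   per-subject affine variability.
#' @param global_scale_range range of the random global uptake factor.
#' @param psf_fwhm_mm reconstruction point-spread FWHM.
#' @param age_range controls' ages are drawn uniformly from this range.
#' @param seed master seed; combined with per-subject seeds.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 76L, 64L),
                         voxel_size_mm = 3.0,
                         uptake = list(cortex_gm = 1.0, wm = 0.35,
                                       cerebellum_gm = 1.0,
                                       ventricles = 0.05, background = 0),
                         noise_sd = 0.05,
                         max_translation_mm = 5,
                         max_rotation_deg = 5,
                         scale_range = c(0.95, 1.05),
                         max_shear = 0.03,
                         global_scale_range = c(0.5, 2.0),
                         psf_fwhm_mm = 6,
                         age_range = c(6, 20),
                         seed = 1L) {
  stopifnot(all(grid_shape >= 1), voxel_size_mm > 0,
            all(unlist(uptake) >= 0), noise_sd >= 0,
            scale_range[1] <= scale_range[2],
            global_scale_range[1] <= global_scale_range[2])
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, uptake = uptake,
                 noise_sd = noise_sd,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 scale_range = scale_range, max_shear = max_shear,
                 global_scale_range = global_scale_range,
                 psf_fwhm_mm = psf_fwhm_mm, age_range = age_range,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Lesion specification for simulated patients
#'
#' @param lobe one of `"frontal"`, `"temporal"`, `"parietal_occipital"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param radius_mm lesion radius.
#' @param reduction_fraction fractional uptake reduction in (0, 1).
#' @param center_jitter_mm uniform jitter applied to the lesion centre.
#' @param shape `"sphere"` (ellipsoid reserved for future use).
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(lobe = "temporal", hemisphere = "right",
                        radius_mm = 12, reduction_fraction = 0.3,
                        center_jitter_mm = 0, shape = "sphere") {
  lobe <- match.arg(lobe, c("frontal", "temporal", "parietal_occipital"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  if (reduction_fraction <= 0 || reduction_fraction >= 1) {
    stop("reduction_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(lobe = lobe, hemisphere = hemisphere, radius_mm = radius_mm,
                 reduction_fraction = reduction_fraction,
                 center_jitter_mm = center_jitter_mm, shape = shape),
            class = "lesion_spec")
}

phantom_affine <- function(spec) {
  v <- spec$voxel_size_mm
  org <- -v * (spec$grid_shape - 1) / 2
  rbind(c(v, 0, 0, org[1]),
        c(0, v, 0, org[2]),
        c(0, 0, v, org[3]),
        c(0, 0, 0, 1))
}

# world coordinate arrays for the canonical grid
phantom_coords <- function(spec) {
  aff <- phantom_affine(spec)
  d <- spec$grid_shape
  list(x = aff[1, 1] * (seq_len(d[1]) - 1) + aff[1, 4],
       y = aff[2, 2] * (seq_len(d[2]) - 1) + aff[2, 4],
       z = aff[3, 3] * (seq_len(d[3]) - 1) + aff[3, 4])
}

in_ellipsoid <- function(cx, cy, cz, center, radii) {
  outer(outer((cx - center[1])^2 / radii[1]^2,
              (cy - center[2])^2 / radii[2]^2, "+"),
        (cz - center[3])^2 / radii[3]^2, "+") <= 1
}

#' Canonical phantom anatomy: structural, PET reference and atlas
#'
#' Builds a deterministic nested-ellipsoid brain: left/right frontal,
#' temporal and parietal/occipital cortical shells around a white-matter
#' core with ventricles, plus an inferior-posterior cerebellum. The
#' structural volume has MRI-like contrast (bright white matter), the PET
#' reference has FDG-like contrast (bright grey matter), so cross-modal
#' registration is genuinely exercised. The atlas labels the six cortical
#' lobe regions and the two cerebellar hemispheres.
#'
#' @param spec a [phantom_spec].
#' @return A list with `structural`, `pet_reference` ([pet_volume]s),
#'   `atlas` (a [label_volume]) and `tissue` (integer array of tissue
#'   classes, for internal use).
#' @export
make_anatomy <- function(spec = phantom_spec()) {
  if (any(spec$grid_shape < 32L)) {
    stop("grid too small to fit brain compartments (need >= 32 voxels per axis)",
         call. = FALSE)
  }
  co <- phantom_coords(spec)
  d <- spec$grid_shape

  cerebrum <- in_ellipsoid(co$x, co$y, co$z, c(0, 12, 12), c(63, 78, 60))
  wm <- in_ellipsoid(co$x, co$y, co$z, c(0, 12, 12), 0.62 * c(63, 78, 60))
  vent <- in_ellipsoid(co$x, co$y, co$z, c(10, 2, 8), c(7, 22, 11)) |
    in_ellipsoid(co$x, co$y, co$z, c(-10, 2, 8), c(7, 22, 11))
  cereb <- in_ellipsoid(co$x, co$y, co$z, c(0, -58, -48), c(40, 28, 24))

  # tissue classes: 0 bg, 1 cortex, 2 wm, 3 ventricles, 4 cerebellum
  tissue <- array(0L, dim = d)
  tissue[cerebrum] <- 1L
  tissue[cerebrum & wm] <- 2L
  tissue[cerebrum & vent] <- 3L
  tissue[cereb] <- 4L

  X <- array(rep(co$x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(co$y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(co$z, each = d[1] * d[2]), dim = d)

  cortex <- tissue == 1L
  labels <- array(0L, dim = d)
  frontal <- cortex & Y > 40
  temporal <- cortex & Y <= 40 & Y > -35 & Z < 0
  par_occ <- cortex & !frontal & !temporal
  right <- X > 0
  labels[frontal & !right] <- 1L
  labels[frontal & right] <- 2L
  labels[temporal & !right] <- 3L
  labels[temporal & right] <- 4L
  labels[par_occ & !right] <- 5L
  labels[par_occ & right] <- 6L
  labels[tissue == 4L & !right] <- 7L
  labels[tissue == 4L & right] <- 8L

  legend <- data.frame(
    label = 1:8,
    region_name = c("frontal_left", "frontal_right", "temporal_left",
                    "temporal_right", "parietal_occipital_left",
                    "parietal_occipital_right", "cerebellum_left",
                    "cerebellum_right"),
    lobe = c("frontal", "frontal", "temporal", "temporal",
             "parietal_occipital", "parietal_occipital",
             "cerebellum", "cerebellum"),
    hemisphere = rep(c("left", "right"), 4),
    stringsAsFactors = FALSE)

  aff <- phantom_affine(spec)
  up <- spec$uptake
  pet <- array(0, dim = d)
  pet[tissue == 1L] <- up$cortex_gm
  pet[tissue == 2L] <- up$wm
  pet[tissue == 3L] <- up$ventricles
  pet[tissue == 4L] <- up$cerebellum_gm
  struct_vals <- c(0, 0.6, 1.0, 0.15, 0.6)
  struct <- array(struct_vals[tissue + 1L], dim = d)
  structural <- gaussian_smooth(pet_volume(struct, aff), fwhm_mm = 4)

  list(structural = structural,
       pet_reference = pet_volume(pet, aff),
       atlas = label_volume(labels, aff, legend),
       tissue = tissue)
}

# deterministic combination of the master and per-subject seed
combine_seeds <- function(master, subject) {
  as.integer((as.numeric(master) * 1009 + as.numeric(subject) * 7919) %%
               2147483647)
}

random_subject_transform <- function(spec) {
  affine_transform(
    translation_mm = runif(3, -spec$max_translation_mm, spec$max_translation_mm),
    rotation_rad = runif(3, -spec$max_rotation_deg, spec$max_rotation_deg) *
      pi / 180,
    scale = runif(3, spec$scale_range[1], spec$scale_range[2]),
    shear = runif(3, -spec$max_shear, spec$max_shear))
}

simulate_scan <- function(spec, subject_seed, reference, anatomy) {
  set.seed(combine_seeds(spec$seed, subject_seed))
  tr <- random_subject_transform(spec)
  gscale <- runif(1, spec$global_scale_range[1], spec$global_scale_range[2])
  age <- runif(1, spec$age_range[1], spec$age_range[2])
  warped <- resample(reference, tr, reference)
  blurred <- if (spec$psf_fwhm_mm > 0) {
    gaussian_smooth(warped, spec$psf_fwhm_mm)
  } else {
    warped
  }
  img <- blurred$data * gscale
  if (spec$noise_sd > 0) {
    support <- blurred$data > 0.02
    noise <- array(0, dim = dim(img))
    noise[support] <- rnorm(sum(support), 0, spec$noise_sd * gscale)
    img <- img + noise
    img[img < 0] <- 0
  }
  list(volume = pet_volume(img, reference$affine), transform = tr,
       global_scale = gscale, age = age)
}

#' Simulate one control scan
#'
#' Warps the canonical PET reference by a random per-subject 12-dof
#' transform, applies a random global uptake factor, the reconstruction
#' point spread, and voxelwise Gaussian noise on the head support. Fully
#' reproducible from `(spec$seed, subject_seed)`.
#'
#' @param spec a [phantom_spec].
#' @param subject_seed integer distinguishing subjects.
#' @param anatomy optional precomputed [make_anatomy()] output (avoids
#'   rebuilding it per subject).
#' @return A list of class `control_scan` with `volume`, `subject_id`,
#'   `age_years`, plus ground truth (`true_transform`, `global_scale`).
#' @export
simulate_control <- function(spec = phantom_spec(), subject_seed = 1L,
                             anatomy = NULL) {
  if (is.null(anatomy)) anatomy <- make_anatomy(spec)
  res <- simulate_scan(spec, subject_seed, anatomy$pet_reference, anatomy)
  structure(list(volume = res$volume,
                 subject_id = sprintf("C%03d", subject_seed),
                 age_years = res$age,
                 true_transform = res$transform,
                 global_scale = res$global_scale),
            class = "control_scan")
}

#' Simulate one lesioned patient
#'
#' As [simulate_control()], but uptake inside a focal lesion is multiplied
#' by `1 - reduction_fraction` before warping. The lesion centre is the
#' centroid of the target atlas region (plus optional jitter), so the
#' ground-truth focus call is the lesion's hemisphere and lobe.
#'
#' @param spec a [phantom_spec].
#' @param lesion a [lesion_spec].
#' @param subject_seed integer.
#' @param anatomy optional precomputed [make_anatomy()] output.
#' @param cortical_reduction fraction in [0, 1): additional diffuse
#'   uptake reduction over the cerebrum (cortex, white matter,
#'   ventricles) with the cerebellum preserved — emulates a globally low
#'   baseline cortical metabolism, the situation in which global-mean
#'   intensity normalization biases hypometabolism detection.
#' @return A list of class `patient_scan`: `volume`, `subject_id`,
#'   `age_years`, `truth_mask` (binary [pet_volume], canonical space),
#'   `truth_call` (a [focus_call]), plus ground truth fields.
#' @export
simulate_patient <- function(spec = phantom_spec(), lesion = lesion_spec(),
                             subject_seed = 1L, anatomy = NULL,
                             cortical_reduction = 0) {
  if (is.null(anatomy)) anatomy <- make_anatomy(spec)
  atlas <- anatomy$atlas
  row <- atlas$legend[atlas$legend$lobe == lesion$lobe &
                        atlas$legend$hemisphere == lesion$hemisphere, ]
  if (nrow(row) != 1) stop("lesion target not found in atlas legend", call. = FALSE)
  sel <- atlas$labels == row$label
  if (!any(sel)) stop("lesion target region is empty", call. = FALSE)
  ref <- anatomy$pet_reference
  w <- voxel_world_coords(ref, sel)
  center <- colMeans(w)
  set.seed(combine_seeds(spec$seed, subject_seed) %% 2147483000 + 577L)
  if (lesion$center_jitter_mm > 0) {
    center <- center + runif(3, -lesion$center_jitter_mm, lesion$center_jitter_mm)
  }
  co <- phantom_coords(spec)
  sphere <- in_ellipsoid(co$x, co$y, co$z, center, rep(lesion$radius_mm, 3))
  region_extent <- max(sqrt(rowSums(sweep(w, 2, colMeans(w))^2)))
  if (lesion$radius_mm > region_extent) {
    stop("lesion radius exceeds the extent of the target lobe", call. = FALSE)
  }
  lesioned <- ref
  if (cortical_reduction > 0) {
    cereb <- anatomy$tissue %in% c(1L, 2L, 3L)
    lesioned$data[cereb] <- lesioned$data[cereb] * (1 - cortical_reduction)
  }
  lesioned$data[sphere] <- lesioned$data[sphere] * (1 - lesion$reduction_fraction)
  res <- simulate_scan(spec, subject_seed, lesioned, anatomy)
  truth_mask <- pet_volume(array(as.numeric(sphere), dim = spec$grid_shape),
                           ref$affine)
  structure(list(volume = res$volume,
                 subject_id = sprintf("P%03d", subject_seed),
                 age_years = res$age,
                 truth_mask = truth_mask,
                 truth_call = focus_call(lesion$hemisphere, lesion$lobe),
                 lesion = lesion,
                 true_transform = res$transform,
                 global_scale = res$global_scale),
            class = "patient_scan")
}

#' Simulate and write a full phantom cohort to disk
#'
#' Writes the structural template, atlas (+ legend TSV), control scans
#' with ages, lesioned patients with canonical-space truth masks, and a
#' manifest TSV recording roles, ages, seeds and lesion parameters.
#' Deterministic given `(spec, seed)`.
#'
#' @param spec a [phantom_spec].
#' @param n_controls number of control scans.
#' @param patients list of [lesion_spec]s (one patient each); may be empty.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return Invisibly, the manifest data frame.
#' @export
simulate_cohort <- function(spec = phantom_spec(), n_controls = 19,
                            patients = list(), out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  anatomy <- make_anatomy(spec)
  write_nifti(anatomy$structural, file.path(out_dir, "structural.nii.gz"))
  write_label_volume(anatomy$atlas, file.path(out_dir, "atlas.nii.gz"),
                     file.path(out_dir, "atlas_legend.tsv"))
  rows <- list()
  for (s in seq_len(n_controls)) {
    ctl <- simulate_control(spec, subject_seed = s, anatomy = anatomy)
    fn <- sprintf("control_%s.nii.gz", ctl$subject_id)
    write_nifti(ctl$volume, file.path(out_dir, fn))
    rows[[length(rows) + 1]] <- data.frame(
      file = fn, role = "control", subject_id = ctl$subject_id,
      age_years = ctl$age_years, seed = s, lobe = NA, hemisphere = NA,
      radius_mm = NA, reduction_fraction = NA, stringsAsFactors = FALSE)
  }
  for (p in seq_along(patients)) {
    pat <- simulate_patient(spec, patients[[p]], subject_seed = 10000L + p,
                            anatomy = anatomy)
    fn <- sprintf("patient_%s.nii.gz", pat$subject_id)
    write_nifti(pat$volume, file.path(out_dir, fn))
    write_nifti(pat$truth_mask,
                file.path(out_dir, sprintf("truth_%s.nii.gz", pat$subject_id)))
    rows[[length(rows) + 1]] <- data.frame(
      file = fn, role = "patient", subject_id = pat$subject_id,
      age_years = pat$age_years, seed = 10000L + p,
      lobe = patients[[p]]$lobe, hemisphere = patients[[p]]$hemisphere,
      radius_mm = patients[[p]]$radius_mm,
      reduction_fraction = patients[[p]]$reduction_fraction,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
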