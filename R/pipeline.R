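#' Analysis pipeline configuration
#'
#' Two presets mirror the two analysis arms: `spm_style` (6-mm smoothing,
#' cerebellar grey-matter intensity normalization, age-specific pediatric
#' template space) and `scenium_style` (12-mm fixed smoothing, global-mean
#' intensity normalization). Any explicit argument overrides its preset
#' default.
#'
#' @param mode `"spm_style"` or `"scenium_style"`.
#' @param fwhm_mm smoothing kernel FWHM (6 for spm_style, 12 for
#'   scenium_style unless overridden).
#' @param normalization_mode intensity normalization reference
#'   (`"cerebellum_gm"` for spm_style, `"global_mean"` for scenium_style).
#' @param p_threshold uncorrected voxel p threshold.
#' @param extent minimum cluster size, voxels.
#' @param connectivity 6, 18 or 26.
#' @param qc_threshold registration QC threshold.
#' @param smooth_after_normalize smooth after (instead of before) spatial
#'   normalization; the default follows the stated processing order
#'   (smoothing, then spatial normalization, then intensity
#'   normalization).
#' @param registration settings from [registration_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("spm_style", "scenium_style"),
                       fwhm_mm = NULL, normalization_mode = NULL,
                       p_threshold = 0.001, extent = 100L,
                       connectivity = 18L, qc_threshold = 0.90,
                       smooth_after_normalize = FALSE,
                       registration = registration_config()) {
  mode <- match.arg(mode)
  if (is.null(fwhm_mm)) fwhm_mm <- if (mode == "spm_style") 6 else 12
  if (is.null(normalization_mode)) {
    normalization_mode <- if (mode == "spm_style") "cerebellum_gm"
                          else "global_mean"
  }
  registration$qc_threshold <- qc_threshold
  structure(list(mode = mode, fwhm_mm = fwhm_mm,
                 normalization_mode = normalization_mode,
                 p_threshold = p_threshold, extent = as.integer(extent),
                 connectivity = as.integer(connectivity),
                 qc_threshold = qc_threshold,
                 smooth_after_normalize = smooth_after_normalize,
                 registration = registration),
            class = "run_config")
}

# smoothing + spatial normalization (+ optional intensity normalization)
process_scan <- function(scan, template, config, reference_mask = NULL,
                         normalize = TRUE) {
  stopifnot(inherits(scan, "pet_volume"))
  if (!config$smooth_after_normalize) {
    scan <- gaussian_smooth(scan, config$fwhm_mm)
  }
  norm <- normalize_to_template(scan, template,
                                config = config$registration)
  vol <- norm$volume
  if (config$smooth_after_normalize) {
    vol <- gaussian_smooth(vol, config$fwhm_mm)
  }
  if (normalize) {
    vol <- intensity_normalize(vol, mode = config$normalization_mode,
                               reference_mask = reference_mask)
  }
  list(volume = vol, registration = norm$registration)
}

#' Build the control statistics database for a pipeline configuration
#'
#' Processes every control scan exactly as patients are processed
#' (smoothing, spatial normalization to the template, intensity
#' normalization) and accumulates per-voxel control statistics.
#'
#' @param controls list of `control_scan` objects (or [pet_volume]s).
#' @param template template-space [pet_volume] (a bundle's `average2`).
#' @param config a [run_config()].
#' @param atlas [label_volume] on the template grid; required for
#'   cerebellar normalization (supplies the reference mask) and region
#'   tables.
#' @return A `control_stats` object (see [build_control_stats()]).
#' @export
build_control_database <- function(controls, template, config = run_config(),
                                   atlas = NULL) {
  ref_mask <- pipeline_reference_mask(config, atlas)
  processed <- lapply(controls, function(ctl) {
    vol <- if (inherits(ctl, "pet_volume")) ctl else ctl$volume
    process_scan(vol, template, config, normalize = FALSE)$volume
  })
  build_control_stats(processed, normalization_mode = config$normalization_mode,
                      reference_mask = ref_mask)
}

pipeline_reference_mask <- function(config, atlas) {
  if (config$normalization_mode != "cerebellum_gm") return(NULL)
  if (is.null(atlas)) {
    stop("cerebellum_gm normalization requires an atlas for the reference mask",
         call. = FALSE)
  }
  lobe_mask(atlas, "cerebellum")
}

#' Run the single-patient analysis pipeline
#'
#' Smoothing, spatial normalization to the template, intensity
#' normalization, single-subject t-test against the control database,
#' cluster-extent thresholding, atlas-region SD table, and the focus
#' call.
#'
#' @param patient a [pet_volume] (native space).
#' @param template template-space [pet_volume].
#' @param control_stats a `control_stats` database built with
#'   [build_control_database()] under the same `config`.
#' @param atlas [label_volume] on the template grid.
#' @param config a [run_config()].
#' @return A list of class `analysis_result`: `stat_map`, `clusters`,
#'   `regions`, `focus`, `registration`, `normalized` and `config`.
#' @export
run_analysis <- function(patient, template, control_stats, atlas,
                         config = run_config()) {
  stopifnot(inherits(control_stats, "control_stats"),
            inherits(atlas, "label_volume"))
  ref_mask <- pipeline_reference_mask(config, atlas)
  proc <- process_scan(patient, template, config, reference_mask = ref_mask)
  smap <- single_subject_ttest(proc$volume, control_stats)
  clusters <- threshold_statmap(smap, p = config$p_threshold,
                                extent = config$extent,
                                connectivity = config$connectivity)
  regions <- region_sd_scores(proc$volume, control_stats, atlas)
  focus <- if (config$mode == "scenium_style") {
    classify_focus(regions = regions, atlas = atlas, mode = "scenium_style")
  } else {
    classify_focus(clusters = clusters, atlas = atlas, mode = "spm_style")
  }
  structure(list(stat_map = smap, clusters = clusters, regions = regions,
                 focus = focus, registration = proc$registration,
                 normalized = proc$volume, config = config),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("<analysis_result> mode =", x$config$mode, "\n")
  print(x$clusters)
  cat("focus call:", format(x$focus), "\n")
  invisible(x)
}

#' Agreement and validation metrics for a set of patients
#'
#' Computes Cohen's kappa with its Landis-Koch band per axis
#' (lateralization, localization) between pipeline calls and reference
#' calls, and, when validation records are supplied, lateralization /
#' localization sensitivity over seizure-free (Engel class I) patients
#' and per-patient resection overlap percentages.
#'
#' @param calls named list (by patient id) of [focus_call]s from the
#'   pipeline.
#' @param truth named list (by patient id) of reference [focus_call]s.
#' @param records optional list of [validation_record()]s.
#' @return A list of class `evaluation_metrics`.
#' @export
run_evaluation <- function(calls, truth, records = NULL) {
  ids <- intersect(names(calls), names(truth))
  if (length(ids) == 0) stop("no common patient ids between calls and truth",
                             call. = FALSE)
  extra <- c(setdiff(names(calls), names(truth)),
             setdiff(names(truth), names(calls)))
  if (length(extra) > 0) {
    warning("ids present on one side only: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  lat_a <- vapply(calls[ids], function(x) x$lateralization, "")
  lat_b <- vapply(truth[ids], function(x) x$lateralization, "")
  loc_a <- vapply(calls[ids], function(x) x$localization, "")
  loc_b <- vapply(truth[ids], function(x) x$localization, "")
  k_lat <- cohen_kappa(lat_a, lat_b,
                       categories = c("right", "left", "normal", "multifocal"))
  k_loc <- cohen_kappa(loc_a, loc_b,
                       categories = c("frontal", "temporal",
                                      "parietal_occipital", "normal",
                                      "multifocal"))
  out <- list(n = length(ids),
              kappa = list(
                lateralization = list(kappa = k_lat,
                                      band = kappa_category(k_lat)),
                localization = list(kappa = k_loc,
                                    band = kappa_category(k_loc))),
              accuracy = list(lateralization = mean(lat_a == lat_b),
                              localization = mean(loc_a == loc_b)))
  if (!is.null(records)) {
    szfree <- Filter(function(r) r$engel_class == "I", records)
    if (length(szfree) > 0) {
      lat_ok <- vapply(szfree, function(r) isTRUE(lateralization_correct(r)), TRUE)
      loc_ok <- vapply(szfree, function(r) isTRUE(localization_correct(r)), TRUE)
      out$sensitivity <- list(lateralization = sensitivity(lat_ok),
                              localization = sensitivity(loc_ok),
                              n = length(szfree))
      out$overlap_percent <- vapply(szfree, function(r) {
        as.numeric(resection_overlap_percent(r))
      }, 0)
      names(out$overlap_percent) <-
        vapply(szfree, function(r) r$patient_id, "")
    }
    out$n_not_seizure_free <- length(records) - length(szfree)
  }
  class(out) <- "evaluation_metrics"
  out
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat("<evaluation_metrics> n =", x$n, "\n")
  cat(sprintf("  kappa lateralization: %.3f (%s)\n",
              x$kappa$lateralization$kappa, x$kappa$lateralization$band))
  cat(sprintf("  kappa localization:   %.3f (%s)\n",
              x$kappa$localization$kappa, x$kappa$localization$band))
  if (!is.null(x$sensitivity)) {
    cat(sprintf("  sensitivity (n=%d): lat %.2f, loc %.2f\n",
                x$sensitivity$n, x$sensitivity$lateralization,
                x$sensitivity$localization))
  }
  invisible(x)
}
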