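#' Categorical focus call
#'
#' Lateralization (right / left / normal / multifocal) and localization
#' (frontal / temporal / parietal_occipital / normal / multifocal) of the
#' presumed epileptogenic focus, with the supporting evidence (the peak
#' cluster or driving atlas region).
#'
#' @param lateralization,localization category strings.
#' @param evidence optional list describing the peak cluster / region.
#' @return An object of class `focus_call`.
#' @export
focus_call <- function(lateralization, localization, evidence = NULL) {
  lat_alpha <- c("right", "left", "normal", "multifocal")
  loc_alpha <- c("frontal", "temporal", "parietal_occipital", "normal",
                 "multifocal")
  lateralization <- match.arg(lateralization, lat_alpha)
  localization <- match.arg(localization, loc_alpha)
  if ((lateralization == "normal") != (localization == "normal")) {
    stop("'normal' must apply to both axes or neither", call. = FALSE)
  }
  if ((lateralization == "multifocal") != (localization == "multifocal")) {
    stop("'multifocal' must apply to both axes or neither", call. = FALSE)
  }
  structure(list(lateralization = lateralization,
                 localization = localization, evidence = evidence),
            class = "focus_call")
}

#' @export
print.focus_call <- function(x, ...) {
  cat("<focus_call>", x$lateralization, "/", x$localization, "\n")
  invisible(x)
}

#' @export
format.focus_call <- function(x, ...) {
  paste0(x$lateralization, "/", x$localization)
}

#' Spatially normalize a scan to a template
#'
#' Affine registration ([register_affine()]) followed by resampling onto
#' the template grid. The default correlation-ratio cost matches the
#' within-modality case (patient PET to PET template).
#'
#' @param scan a [pet_volume].
#' @param template target [pet_volume] (typically a template bundle's
#'   second-pass average).
#' @param cost similarity passed to [register_affine()].
#' @param config registration settings.
#' @return List with `volume` (scan on the template grid) and
#'   `registration` (the [register_affine()] result).
#' @export
normalize_to_template <- function(scan, template, cost = "correlation_ratio",
                                  config = registration_config()) {
  reg <- register_affine(scan, template, cost = cost, config = config)
  list(volume = resample(scan, reg$transform, template),
       registration = reg)
}

#' Intensity normalization by a reference uptake
#'
#' Divides a volume by the mean uptake over a reference region: either
#' cerebellar grey matter (minimally affected in epilepsy, so preserving
#' sensitivity to global hypometabolism) or the global brain mean (which
#' can bias hypometabolism detection when baseline metabolism is globally
#' low). The reference-region mean of the output is exactly 1.
#'
#' @param volume a [pet_volume].
#' @param mode `"cerebellum_gm"` or `"global_mean"`.
#' @param reference_mask logical array on the volume grid; required for
#'   `cerebellum_gm`. For `global_mean` the default reference is all
#'   voxels above 10% of the volume maximum.
#' @return A normalized [pet_volume].
#' @export
intensity_normalize <- function(volume, mode = c("cerebellum_gm", "global_mean"),
                                reference_mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "pet_volume"))
  if (mode == "cerebellum_gm") {
    if (is.null(reference_mask)) {
      stop("cerebellum_gm mode requires a reference_mask", call. = FALSE)
    }
  } else if (is.null(reference_mask)) {
    reference_mask <- volume$data > 0.1 * max(volume$data)
  }
  nref <- sum(reference_mask)
  if (nref < 100) {
    stop("reference region has ", nref, " voxels (< 100)", call. = FALSE)
  }
  m <- mean(volume$data[reference_mask])
  if (!is.finite(m) || m <= 0) {
    stop("reference region mean is not positive", call. = FALSE)
  }
  pet_volume(volume$data / m, volume$affine)
}

#' Per-voxel control statistics on the template grid
#'
#' Sample mean and SD (n - 1 denominator) of intensity-normalized control
#' scans, with a brain mask where the mean exceeds a fraction of its own
#' maximum. The individual normalized scans are retained by default so
#' region-level SD scores (which need per-control region means) can be
#' computed later.
#'
#' @param controls list of [pet_volume]s on one grid, already spatially
#'   normalized.
#' @param normalization_mode `"cerebellum_gm"` or `"global_mean"`;
#'   applied to every control.
#' @param reference_mask passed to [intensity_normalize()].
#' @param mask_fraction brain mask cut: mean > `mask_fraction * max(mean)`.
#' @param keep_scans retain the normalized controls (needed by
#'   [region_sd_scores()]).
#' @return An object of class `control_stats`: `mean`, `sd`
#'   ([pet_volume]s), `n`, `brain_mask` (logical array),
#'   `normalization_mode`, and optionally `scans`.
#' @export
build_control_stats <- function(controls,
                                normalization_mode = c("cerebellum_gm",
                                                       "global_mean"),
                                reference_mask = NULL, mask_fraction = 0.1,
                                keep_scans = TRUE) {
  normalization_mode <- match.arg(normalization_mode)
  n <- length(controls)
  if (n < 2) stop("need at least 2 control scans", call. = FALSE)
  for (i in seq_len(n)[-1]) {
    if (!same_grid(controls[[1]], controls[[i]])) {
      stop("all controls must share one grid", call. = FALSE)
    }
  }
  normed <- lapply(controls, intensity_normalize, mode = normalization_mode,
                   reference_mask = reference_mask)
  d <- dim(normed[[1]]$data)
  s1 <- array(0, dim = d); s2 <- array(0, dim = d)
  for (v in normed) {
    s1 <- s1 + v$data
    s2 <- s2 + v$data^2
  }
  mu <- s1 / n
  ss <- pmax(s2 - n * mu^2, 0)
  sdv <- sqrt(ss / (n - 1))
  mask <- mu > mask_fraction * max(mu)
  structure(list(mean = pet_volume(mu, normed[[1]]$affine),
                 sd = pet_volume(sdv, normed[[1]]$affine),
                 n = n, brain_mask = mask,
                 normalization_mode = normalization_mode,
                 reference_mask = reference_mask,
                 scans = if (keep_scans) normed else NULL),
            class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat("<control_stats> n =", x$n, "|", sum(x$brain_mask),
      "voxels in brain mask | normalization:", x$normalization_mode, "\n")
  invisible(x)
}

#' Single-subject vs control-group t-map
#'
#' The two-sample t test with group sizes 1 and n reduces to
#' `t = (x - mean) / (sd * sqrt(1 + 1/n))` with `df = n - 1`, since the
#' pooled variance collapses to the control variance. Voxels where the
#' control SD is zero get t = 0 when the patient matches the mean and are
#' otherwise clamped to +/- 1e6 and flagged (flagged voxels are excluded
#' from cluster peaks downstream).
#'
#' @param patient a [pet_volume] in template space, intensity-normalized
#'   with the same mode as `stats`.
#' @param stats a [build_control_stats()] result.
#' @return An object of class `stat_map`: `t` ([pet_volume]), `df`,
#'   `mask`, `flagged` (logical arrays).
#' @export
single_subject_ttest <- function(patient, stats) {
  stopifnot(inherits(patient, "pet_volume"), inherits(stats, "control_stats"))
  if (!same_grid(patient, stats$mean)) {
    stop("patient and control stats are on different grids", call. = FALSE)
  }
  se <- stats$sd$data * sqrt(1 + 1 / stats$n)
  delta <- patient$data - stats$mean$data
  tmap <- array(0, dim = dim(delta))
  ok <- se > 0
  tmap[ok] <- delta[ok] / se[ok]
  flagged <- !ok & delta != 0
  tmap[flagged & delta > 0] <- 1e6
  tmap[flagged & delta < 0] <- -1e6
  tmap[!stats$brain_mask] <- 0
  structure(list(t = pet_volume(tmap, patient$affine), df = stats$n - 1,
                 mask = stats$brain_mask,
                 flagged = flagged & stats$brain_mask),
            class = "stat_map")
}

#' One-sided t threshold for a given p value
#'
#' Returns `t*` with `P(T_df > t*) = p`.
#'
#' @param p tail probability in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return Positive scalar for `p < 0.5`.
#' @export
p_to_t_threshold <- function(p, df) {
  stopifnot(p > 0, p < 1, df >= 1)
  stats::qt(1 - p, df = df)
}

#' Threshold a t-map into a cluster table
#'
#' Suprathreshold voxels (t <= -t* for hypometabolism, t >= +t* for
#' hypermetabolism, one-sided per direction) are connected-component
#' labelled, components smaller than `extent` voxels are discarded, and
#' the survivors are tabulated sorted by |peak t| descending (ties broken
#' by the smaller linear peak voxel index). SD-clamped voxels are never
#' cluster peaks.
#'
#' @param map a [single_subject_ttest()] result.
#' @param p uncorrected voxel-level p threshold.
#' @param extent minimum cluster size in voxels of the working grid.
#' @param connectivity 6, 18 or 26.
#' @param directions subset of `c("hypo", "hyper")`.
#' @return An object of class `cluster_table`: a data frame `clusters`
#'   with columns cluster_id, direction, size_voxels, peak_t,
#'   peak_i/j/k (1-based), peak_x/y/z_mm; `label_map` (integer array,
#'   cluster id per voxel); and threshold metadata.
#' @export
threshold_statmap <- function(map, p = 0.001, extent = 100L,
                              connectivity = 18L,
                              directions = c("hypo", "hyper")) {
  stopifnot(inherits(map, "stat_map"), connectivity %in% c(6L, 18L, 26L))
  tstar <- p_to_t_threshold(p, map$df)
  tdata <- map$t$data
  d <- dim(tdata)
  rows <- list()
  label_map <- array(0L, dim = d)
  next_id <- 0L
  for (dir in directions) {
    supra <- if (dir == "hypo") tdata <= -tstar & map$mask
             else tdata >= tstar & map$mask
    if (!any(supra)) next
    labs <- array(cpp_label_components(as.logical(supra), d,
                                       as.integer(connectivity)), dim = d)
    sizes <- tabulate(labs[labs > 0])
    for (comp in which(sizes >= extent)) {
      sel <- labs == comp
      cand <- sel & !map$flagged
      if (!any(cand)) next
      vals <- tdata[cand]
      lin <- which(cand)
      peak_lin <- if (dir == "hypo") lin[which.min(vals)] else lin[which.max(vals)]
      pk <- arrayInd(peak_lin, d)
      wk <- (c(pk - 1, 1) %*% t(map$t$affine))[1:3]
      next_id <- next_id + 1L
      label_map[sel] <- next_id
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = next_id, direction = dir,
        size_voxels = sizes[comp], peak_t = tdata[peak_lin],
        peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
        peak_x_mm = wk[1], peak_y_mm = wk[2], peak_z_mm = wk[3],
        peak_lin = peak_lin, stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), direction = character(),
               size_voxels = integer(), peak_t = numeric(),
               peak_i = integer(), peak_j = integer(), peak_k = integer(),
               peak_x_mm = numeric(), peak_y_mm = numeric(),
               peak_z_mm = numeric(), peak_lin = integer(),
               stringsAsFactors = FALSE)
  if (nrow(clusters) > 0) {
    ord <- order(-abs(clusters$peak_t), clusters$peak_lin)
    clusters <- clusters[ord, , drop = FALSE]
    remap <- integer(max(clusters$cluster_id))
    remap[clusters$cluster_id] <- seq_len(nrow(clusters))
    label_map[label_map > 0] <- remap[label_map[label_map > 0]]
    clusters$cluster_id <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  }
  structure(list(clusters = clusters, label_map = label_map,
                 affine = map$t$affine,
                 p_threshold = p, t_threshold = tstar, extent = extent,
                 connectivity = connectivity, df = map$df),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("<cluster_table> p <", x$p_threshold, "(|t| >",
      sprintf("%.3f", x$t_threshold), "), extent", x$extent,
      ",", x$connectivity, "-connectivity:", nrow(x$clusters), "clusters\n")
  if (nrow(x$clusters)) {
    print(x$clusters[, c("cluster_id", "direction", "size_voxels", "peak_t",
                         "peak_x_mm", "peak_y_mm", "peak_z_mm")])
  }
  invisible(x)
}

#' Atlas-region SD scores for one patient
#'
#' Emulates region-of-interest statistics tables: for each atlas region,
#' the patient's mean regional uptake is expressed in SDs of the control
#' distribution of regional means,
#' `sd_score = (patient_region_mean - control_region_mean) / SD_controls(region mean)`.
#' A region is significantly hypometabolic when its score is strictly
#' below -2 (95% confidence bound).
#'
#' @param patient normalized [pet_volume] in template space.
#' @param stats a [build_control_stats()] result with retained scans.
#' @param atlas a [label_volume] on the template grid.
#' @return Data frame with region_name, hemisphere, lobe, n_voxels,
#'   sd_score, significant_hypo.
#' @export
region_sd_scores <- function(patient, stats, atlas) {
  stopifnot(inherits(patient, "pet_volume"), inherits(stats, "control_stats"),
            inherits(atlas, "label_volume"))
  if (is.null(stats$scans)) {
    stop("control_stats was built with keep_scans = FALSE; per-control ",
         "region means are unavailable", call. = FALSE)
  }
  if (!all(dim(atlas$labels) == dim(patient$data))) {
    stop("atlas and patient are on different grids", call. = FALSE)
  }
  legend <- atlas$legend
  out <- lapply(seq_len(nrow(legend)), function(r) {
    lab <- legend$label[r]
    sel <- atlas$labels == lab & stats$brain_mask
    row <- data.frame(region_name = legend$region_name[r],
                      hemisphere = legend$hemisphere[r],
                      lobe = legend$lobe[r],
                      n_voxels = sum(sel), sd_score = NA_real_,
                      significant_hypo = FALSE, stringsAsFactors = FALSE)
    if (row$n_voxels == 0) return(row)
    ctrl_means <- vapply(stats$scans, function(v) mean(v$data[sel]), 0)
    s <- stats::sd(ctrl_means)
    if (s > 0) {
      row$sd_score <- (mean(patient$data[sel]) - mean(ctrl_means)) / s
      row$significant_hypo <- row$sd_score < -2
    }
    row
  })
  do.call(rbind, out)
}

nearest_label <- function(atlas, world_mm, max_dist_mm = 10) {
  idx0 <- (solve(atlas$affine) %*% c(world_mm, 1))[1:3]
  idx <- round(idx0) + 1
  d <- dim(atlas$labels)
  if (all(idx >= 1) && all(idx <= d)) {
    lab <- atlas$labels[idx[1], idx[2], idx[3]]
    if (lab != 0) return(lab)
  }
  sel <- atlas$labels != 0
  w <- cbind(which(sel, arr.ind = TRUE) - 1, 1) %*% t(atlas$affine)
  dist <- sqrt(rowSums(sweep(w[, 1:3, drop = FALSE], 2, world_mm)^2))
  if (min(dist) > max_dist_mm) return(NA_integer_)
  atlas$labels[sel][which.min(dist)]
}

#' Classify the epileptogenic focus
#'
#' SPM-style: the atlas region under the peak of the most significant
#' hypometabolic cluster gives the hemisphere (lateralization) and lobe
#' (localization); no cluster means a normal call. Scenium-style: the
#' region with the most negative SD score below -2 drives the call.
#' Either way, a generalized pattern - more than three significant
#' regions spanning at least two distinct lobes - overrides the call to
#' multifocal. A peak falling outside the atlas is snapped to the nearest
#' labelled voxel within 10 mm, else the call is normal with a warning.
#'
#' @param clusters a [threshold_statmap()] result (spm_style).
#' @param regions a [region_sd_scores()] data frame (scenium_style).
#' @param atlas a [label_volume].
#' @param mode `"spm_style"` or `"scenium_style"`.
#' @param multifocal_min_regions significant-region count that must be
#'   exceeded for a multifocal call.
#' @param multifocal_min_lobes minimum distinct lobes among them.
#' @return A [focus_call].
#' @export
classify_focus <- function(clusters = NULL, regions = NULL, atlas,
                           mode = c("spm_style", "scenium_style"),
                           multifocal_min_regions = 3L,
                           multifocal_min_lobes = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(atlas, "label_volume"))
  legend <- atlas$legend

  if (mode == "spm_style") {
    stopifnot(inherits(clusters, "cluster_table"))
    hypo <- clusters$clusters[clusters$clusters$direction == "hypo", ,
                              drop = FALSE]
    if (nrow(hypo) == 0) return(focus_call("normal", "normal"))
    labs <- vapply(seq_len(nrow(hypo)), function(i) {
      lab <- nearest_label(atlas, c(hypo$peak_x_mm[i], hypo$peak_y_mm[i],
                                    hypo$peak_z_mm[i]))
      if (is.na(lab)) 0L else as.integer(lab)
    }, 0L)
    known <- labs != 0
    sig_lobes <- legend$lobe[match(labs[known], legend$label)]
    if (nrow(hypo) > multifocal_min_regions &&
        length(unique(sig_lobes)) >= multifocal_min_lobes) {
      return(focus_call("multifocal", "multifocal",
                        evidence = list(n_clusters = nrow(hypo),
                                        lobes = unique(sig_lobes))))
    }
    if (!known[1]) {
      warning("peak cluster lies > 10 mm outside the atlas; calling normal",
              call. = FALSE)
      return(focus_call("normal", "normal"))
    }
    r <- match(labs[1], legend$label)
    return(focus_call(legend$hemisphere[r], legend$lobe[r],
                      evidence = list(cluster = hypo[1, ],
                                      region = legend$region_name[r])))
  }

  # scenium_style
  stopifnot(is.data.frame(regions))
  sig <- regions[!is.na(regions$sd_score) & regions$significant_hypo, ,
                 drop = FALSE]
  if (nrow(sig) == 0) return(focus_call("normal", "normal"))
  if (nrow(sig) > multifocal_min_regions &&
      length(unique(sig$lobe)) >= multifocal_min_lobes) {
    return(focus_call("multifocal", "multifocal",
                      evidence = list(n_regions = nrow(sig),
                                      lobes = unique(sig$lobe))))
  }
  top <- sig[which.min(sig$sd_score), ]
  focus_call(top$hemisphere, top$lobe, evidence = list(region = top))
}
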