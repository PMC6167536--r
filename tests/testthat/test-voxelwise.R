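test_that("intensity normalization: arithmetic, scale invariance, errors", {
  d <- c(10, 10, 10)
  x <- array(10, dim = d)
  mask <- array(FALSE, dim = d)
  mask[1:5, , ] <- TRUE           # 500-voxel reference region
  x[mask] <- 5
  v <- pet_volume(x, diag(4))
  out <- intensity_normalize(v, "cerebellum_gm", reference_mask = mask)
  expect_equal(mean(out$data[mask]), 1, tolerance = 1e-12)
  expect_equal(unique(as.numeric(out$data[!mask])), 2)

  # scale invariance
  v2 <- pet_volume(3.7 * x, diag(4))
  out2 <- intensity_normalize(v2, "cerebellum_gm", reference_mask = mask)
  expect_equal(out2$data, out$data, tolerance = 1e-12)

  # reference must be big and positive
  small <- array(FALSE, dim = d); small[1:3, 1, 1] <- TRUE
  expect_error(intensity_normalize(v, "cerebellum_gm", reference_mask = small),
               "< 100")
  zero <- pet_volume(array(0, dim = d), diag(4))
  expect_error(intensity_normalize(zero, "cerebellum_gm", reference_mask = mask),
               "not positive")
})

test_that("control statistics match a brute-force loop and the noise level", {
  set.seed(41)
  d <- c(12, 12, 12)
  sigma <- 0.05
  base <- array(1, dim = d)
  vols <- lapply(1:30, function(i) {
    pet_volume(base + array(rnorm(prod(d), 0, sigma), dim = d), diag(4))
  })
  cs <- build_control_stats(vols, normalization_mode = "global_mean",
                            reference_mask = array(TRUE, dim = d))
  # brute-force voxelwise mean and sd over the normalized scans
  normed <- lapply(vols, function(v) v$data / mean(v$data))
  stack <- simplify2array(normed)
  expect_equal(cs$mean$data, apply(stack, 1:3, mean), tolerance = 1e-12)
  expect_equal(cs$sd$data, apply(stack, 1:3, sd), tolerance = 1e-12)
  expect_equal(cs$n, 30)
  # median within-mask sd close to the injected noise
  expect_lt(abs(median(cs$sd$data[cs$brain_mask]) - sigma) / sigma, 0.15)

  # two identical controls: sd identically 0
  cs2 <- build_control_stats(vols[c(1, 1)], "global_mean",
                             reference_mask = array(TRUE, dim = d))
  expect_true(all(cs2$sd$data == 0))
  expect_error(build_control_stats(vols[1], "global_mean"), "at least 2")
})

test_that("single-subject t equals the closed form and flags sd = 0", {
  d <- c(8, 8, 8)
  mu <- pet_volume(array(1, dim = d), diag(4))
  sdv <- pet_volume(array(0.1, dim = d), diag(4))
  cs <- structure(list(mean = mu, sd = sdv, n = 25,
                       brain_mask = array(TRUE, dim = d),
                       normalization_mode = "global_mean", scans = NULL),
                  class = "control_stats")
  pat <- pet_volume(array(0.7, dim = d), diag(4))
  sm <- single_subject_ttest(pat, cs)
  expect_equal(sm$df, 24)
  expect_equal(unique(as.numeric(sm$t$data)), -0.3 / (0.1 * sqrt(1 + 1 / 25)),
               tolerance = 1e-12)
  expect_equal(round(unique(as.numeric(sm$t$data)), 4), -2.9417)

  # x equal to the mean: t = 0
  sm0 <- single_subject_ttest(mu, cs)
  expect_true(all(sm0$t$data == 0))

  # sd = 0 voxels are clamped and flagged
  sdz <- pet_volume(array(0, dim = d), diag(4))
  csz <- structure(list(mean = mu, sd = sdz, n = 25,
                        brain_mask = array(TRUE, dim = d),
                        normalization_mode = "global_mean", scans = NULL),
                   class = "control_stats")
  smz <- single_subject_ttest(pat, csz)
  expect_true(all(smz$t$data == -1e6))
  expect_true(all(smz$flagged))
  smz0 <- single_subject_ttest(mu, csz)
  expect_true(all(smz0$t$data == 0))
  expect_false(any(smz0$flagged))
})

test_that("p-to-t thresholds match Student quantiles", {
  expect_equal(p_to_t_threshold(0.5, 10), 0, tolerance = 1e-12)
  # df -> infinity limit approaches the normal quantile 3.0902
  expect_equal(p_to_t_threshold(0.001, 1e6), 3.0902, tolerance = 1e-3)
  # heavier tails at finite df
  expect_gt(p_to_t_threshold(0.001, 30), 3.0902)
  expect_gt(p_to_t_threshold(0.001, 10), p_to_t_threshold(0.001, 30))
})

test_that("cluster extent boundary: 99 voxels rejected, 100 retained", {
  sm <- fx_flat_statmap(dim = c(20, 20, 20), df = 29)
  # a compact blob of exactly 99 voxels at t = -10
  blob <- which(array(TRUE, dim = c(5, 5, 4)))  # 100 linear slots
  coords <- as.matrix(expand.grid(i = 3:7, j = 3:7, k = 3:6))
  stopifnot(nrow(coords) == 100)
  for (r in 1:99) sm$t$data[coords[r, 1], coords[r, 2], coords[r, 3]] <- -10
  ct99 <- threshold_statmap(sm, p = 0.001, extent = 100)
  expect_equal(nrow(ct99$clusters), 0)

  sm$t$data[coords[100, 1], coords[100, 2], coords[100, 3]] <- -10
  ct100 <- threshold_statmap(sm, p = 0.001, extent = 100)
  expect_equal(nrow(ct100$clusters), 1)
  expect_equal(ct100$clusters$size_voxels, 100)
  expect_equal(ct100$clusters$direction, "hypo")
})

test_that("clusters are sorted by |peak t| and split by direction", {
  sm <- fx_flat_statmap(dim = c(30, 20, 20), df = 29)
  sm$t$data[2:6, 2:6, 2:6] <- -5      # 125 voxels, peak -5
  sm$t$data[4, 4, 4] <- -5.5
  sm$t$data[20:24, 2:6, 2:6] <- -8    # disjoint, peak -8
  sm$t$data[20:24, 12:16, 12:16] <- 7 # hypermetabolic
  ct <- threshold_statmap(sm, p = 0.001, extent = 100)
  expect_equal(nrow(ct$clusters), 3)
  expect_equal(ct$clusters$peak_t, c(-8, 7, -5.5))
  expect_equal(ct$clusters$direction, c("hypo", "hyper", "hypo"))
  expect_equal(ct$clusters$cluster_id, 1:3)
  # label map consistent with the table
  expect_equal(sum(ct$label_map == 1), 125)
  expect_equal(ct$t_threshold, p_to_t_threshold(0.001, 29))
})

test_that("connected-component labelling equals the flood-fill oracle", {
  set.seed(99)
  for (trial in 1:50) {
    d <- c(9, 9, 9)
    mask <- array(runif(prod(d)) < 0.35, dim = d)
    conn <- sample(c(6L, 18L, 26L), 1)
    fast <- array(pedpet:::cpp_label_components(as.logical(mask), d, conn),
                  dim = d)
    slow <- flood_fill_oracle(mask, conn)
    # same partition: component memberships agree up to label names
    expect_equal(fast > 0, mask)
    key <- paste(fast[mask], slow[mask])
    expect_equal(length(unique(key)), length(unique(fast[mask])))
    expect_equal(length(unique(key)), length(unique(slow[mask])))
  }
})

test_that("region SD scores score the patient against per-control spread", {
  an <- fx_anatomy()
  set.seed(13)
  d <- dim(an$atlas$labels)
  vols <- lapply(1:20, function(i) {
    pet_volume((an$pet_reference$data + array(rnorm(prod(d), 0, 0.05), dim = d)) *
                 (an$pet_reference$data > 0), an$pet_reference$affine)
  })
  cs <- build_control_stats(vols, "global_mean")
  # a patient equal to the control mean scores ~0 everywhere
  pat <- cs$mean
  rows <- region_sd_scores(pat, cs, an$atlas)
  expect_equal(nrow(rows), 8)
  expect_true(all(abs(rows$sd_score) < 1e-8))
  expect_false(any(rows$significant_hypo))

  # hand-computed score for one region
  lab <- an$atlas$legend$label[an$atlas$legend$region_name == "temporal_right"]
  sel <- an$atlas$labels == lab & cs$brain_mask
  ctrl_means <- vapply(cs$scans, function(v) mean(v$data[sel]), 0)
  pat2 <- pet_volume(cs$mean$data * ifelse(array(sel, dim = d), 0.8, 1),
                     cs$mean$affine)
  rows2 <- region_sd_scores(pat2, cs, an$atlas)
  got <- rows2$sd_score[rows2$region_name == "temporal_right"]
  want <- (mean(pat2$data[sel]) - mean(ctrl_means)) / sd(ctrl_means)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(rows2$significant_hypo[rows2$region_name == "temporal_right"])

  # strict -2 rule: exactly -2 is NOT significant
  expect_false(-2 < -2)
  r <- rows
  r$sd_score[1] <- -2
  r$significant_hypo[1] <- r$sd_score[1] < -2
  expect_false(r$significant_hypo[1])
})

test_that("focus classification: normal, peak-region, multifocal, scenium", {
  an <- fx_anatomy()
  d <- dim(an$atlas$labels)
  sm <- structure(list(t = pet_volume(array(0, dim = d), an$atlas$affine),
                       df = 29L, mask = array(TRUE, dim = d),
                       flagged = array(FALSE, dim = d)),
                  class = "stat_map")

  # empty table -> normal
  ct_empty <- threshold_statmap(sm, extent = 100)
  expect_equal(format(classify_focus(clusters = ct_empty, atlas = an$atlas,
                                     mode = "spm_style")), "normal/normal")

  # one blob inside the right frontal region -> (right, frontal)
  lab <- an$atlas$legend$label[an$atlas$legend$region_name == "frontal_right"]
  idx <- which(an$atlas$labels == lab, arr.ind = TRUE)
  cen <- idx[which.min(rowSums(sweep(idx, 2, colMeans(idx))^2)), ]
  sm$t$data[cen[1] + (-3:3), cen[2] + (-3:3), cen[3] + (-2:2)] <- -9
  ct <- threshold_statmap(sm, extent = 100)
  fc <- classify_focus(clusters = ct, atlas = an$atlas, mode = "spm_style")
  expect_equal(fc$lateralization, "right")
  expect_equal(fc$localization, "frontal")

  # scenium-style on a region table
  regions <- data.frame(
    region_name = c("temporal_left", "frontal_right"),
    hemisphere = c("left", "right"),
    lobe = c("temporal", "frontal"),
    n_voxels = c(100, 100),
    sd_score = c(-3, -0.3),
    significant_hypo = c(TRUE, FALSE), stringsAsFactors = FALSE)
  fc2 <- classify_focus(regions = regions, atlas = an$atlas,
                        mode = "scenium_style")
  expect_equal(format(fc2), "left/temporal")

  # generalized rule: 4 significant regions over >= 2 lobes -> multifocal
  regions4 <- data.frame(
    region_name = c("frontal_left", "temporal_right",
                    "parietal_occipital_left", "frontal_right"),
    hemisphere = c("left", "right", "left", "right"),
    lobe = c("frontal", "temporal", "parietal_occipital", "frontal"),
    n_voxels = 100, sd_score = c(-2.5, -2.6, -2.2, -2.1),
    significant_hypo = TRUE, stringsAsFactors = FALSE)
  fc3 <- classify_focus(regions = regions4, atlas = an$atlas,
                        mode = "scenium_style")
  expect_equal(format(fc3), "multifocal/multifocal")

  # 3 significant regions is not multifocal (rule needs more than three)
  fc4 <- classify_focus(regions = regions4[1:3, ], atlas = an$atlas,
                        mode = "scenium_style")
  expect_equal(fc4$lateralization, "right")  # most negative: temporal_right
  expect_equal(fc4$localization, "temporal")
})

test_that("focus_call enforces the normal/multifocal pairing", {
  expect_error(focus_call("normal", "temporal"), "normal")
  expect_error(focus_call("multifocal", "frontal"), "multifocal")
  expect_silent(focus_call("left", "temporal"))
})
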