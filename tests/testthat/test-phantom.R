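test_that("canonical anatomy has the expected compartments and symmetry", {
  an <- fx_anatomy()
  labs <- sort(setdiff(unique(as.integer(an$atlas$labels)), 0L))
  expect_gte(length(labs), 7)
  expect_true(all(c("cerebellum") %in%
                    an$atlas$legend$lobe[an$atlas$legend$label %in% labs]))

  # mirror symmetry about the mid-sagittal plane: left/right label volumes
  legend <- an$atlas$legend
  for (lb in unique(legend$lobe)) {
    nl <- sum(an$atlas$labels %in%
                legend$label[legend$lobe == lb & legend$hemisphere == "left"])
    nr <- sum(an$atlas$labels %in%
                legend$label[legend$lobe == lb & legend$hemisphere == "right"])
    expect_equal(nl, nr)
  }

  # PET reference: cerebellum and cortex share unit uptake
  cereb <- lobe_mask(an$atlas, "cerebellum")
  cortex <- lobe_mask(an$atlas, "frontal") | lobe_mask(an$atlas, "temporal")
  expect_equal(mean(an$pet_reference$data[cereb]), 1)
  expect_equal(mean(an$pet_reference$data[cortex]), 1)

  # distinct contrasts: related but far from a perfect functional line
  expect_gt(mutual_information(an$structural, an$pet_reference), 0)
  fg <- an$structural$data > 0 & an$pet_reference$data > 0
  expect_lt(abs(cor(an$structural$data[fg], an$pet_reference$data[fg])), 0.95)

  expect_error(make_anatomy(phantom_spec(grid_shape = c(16, 16, 16))),
               "too small")
})

test_that("control simulation is deterministic and spans the scale range", {
  spec <- fx_spec()
  an <- fx_anatomy()
  c1 <- simulate_control(spec, 7, anatomy = an)
  c2 <- simulate_control(spec, 7, anatomy = an)
  expect_identical(c1$volume$data, c2$volume$data)
  expect_identical(c1$age_years, c2$age_years)
  c3 <- simulate_control(spec, 8, anatomy = an)
  expect_false(identical(c1$volume$data, c3$volume$data))

  # no variability, no noise, unit scale: output is the blurred reference
  quiet <- phantom_spec(noise_sd = 0, max_translation_mm = 0,
                        max_rotation_deg = 0, scale_range = c(1, 1),
                        max_shear = 0, global_scale_range = c(1, 1),
                        seed = spec$seed)
  cq <- simulate_control(quiet, 1, anatomy = an)
  ref <- gaussian_smooth(an$pet_reference, quiet$psf_fwhm_mm)
  expect_equal(cq$volume$data, ref$data, tolerance = 1e-12)

  # global means of a cohort spread over the configured range
  gs <- vapply(1:30, function(s) simulate_control(spec, s, anatomy = an)$global_scale, 0)
  expect_gt(max(gs), 1.5)
  expect_lt(min(gs), 0.8)
  ages <- vapply(1:30, function(s) simulate_control(spec, s, anatomy = an)$age_years, 0)
  expect_true(all(ages >= 6 & ages <= 20))
})

test_that("patients carry a truth mask and call matching the lesion", {
  spec <- fx_spec()
  an <- fx_anatomy()
  les <- lesion_spec("temporal", "right", radius_mm = 12,
                     reduction_fraction = 0.3)
  pat <- simulate_patient(spec, les, subject_seed = 301, anatomy = an)
  expect_equal(format(pat$truth_call), "right/temporal")
  expect_gt(sum(pat$truth_mask$data), 0)
  # truth mask sits in the right hemisphere (world x > 0)
  w <- pedpet:::voxel_world_coords(pat$truth_mask, pat$truth_mask$data != 0)
  expect_true(all(w[, 1] > 0))

  # mean uptake in the mask is reduced by the specified fraction
  # (canonical space, before warping/noise)
  quiet <- phantom_spec(noise_sd = 0, max_translation_mm = 0,
                        max_rotation_deg = 0, scale_range = c(1, 1),
                        max_shear = 0, global_scale_range = c(1, 1),
                        psf_fwhm_mm = 0, seed = spec$seed)
  pq <- simulate_patient(quiet, les, subject_seed = 301, anatomy = an)
  sel <- pq$truth_mask$data != 0 & an$pet_reference$data > 0
  ratio <- mean(pq$volume$data[sel]) / mean(an$pet_reference$data[sel])
  expect_equal(ratio, 0.7, tolerance = 1e-10)

  expect_error(simulate_patient(spec, lesion_spec("temporal", "right",
                                                  radius_mm = 200),
                                anatomy = an),
               "radius exceeds")
  expect_error(lesion_spec(reduction_fraction = 1.2), "reduction_fraction")
})

test_that("lesion contrast grows with the reduction fraction", {
  spec <- fx_spec()
  an <- fx_anatomy()
  cs <- fx_control_stats("cerebellum_gm")
  cfg <- fx_config()
  tpl <- fx_template()
  peaks <- vapply(c(0.1, 0.3), function(rf) {
    pat <- simulate_patient(spec, lesion_spec("temporal", "right", 12, rf),
                            subject_seed = 777, anatomy = an)
    res <- run_analysis(pat$volume, tpl, cs, an$atlas, cfg)
    min(res$stat_map$t$data[res$stat_map$mask & !res$stat_map$flagged])
  }, 0)
  expect_lt(peaks[2], peaks[1])
})

test_that("simulate_cohort writes a complete, reproducible directory", {
  spec <- phantom_spec(grid_shape = c(40L, 48L, 40L), voxel_size_mm = 4,
                       seed = 5L)
  # compartments need a grid covering the head; 40x48x40 at 4 mm does
  dir1 <- file.path(tempdir(), "cohort1")
  man1 <- simulate_cohort(spec, n_controls = 3,
                          patients = list(lesion_spec("frontal", "left")),
                          out_dir = dir1, force = TRUE)
  expect_true(file.exists(file.path(dir1, "structural.nii.gz")))
  expect_true(file.exists(file.path(dir1, "atlas.nii.gz")))
  expect_true(file.exists(file.path(dir1, "atlas_legend.tsv")))
  expect_true(file.exists(file.path(dir1, "manifest.tsv")))
  expect_equal(sum(man1$role == "control"), 3)
  expect_equal(sum(man1$role == "patient"), 1)

  atlas <- read_label_volume(file.path(dir1, "atlas.nii.gz"),
                             file.path(dir1, "atlas_legend.tsv"))
  expect_s3_class(atlas, "label_volume")
  expect_equal(nrow(atlas$legend), 8)

  # reruns with the same seed are bit-identical
  dir2 <- file.path(tempdir(), "cohort2")
  simulate_cohort(spec, n_controls = 3,
                  patients = list(lesion_spec("frontal", "left")),
                  out_dir = dir2, force = TRUE)
  f <- "control_C001.nii.gz"
  expect_identical(read_nifti(file.path(dir1, f))$data,
                   read_nifti(file.path(dir2, f))$data)

  # refuses to clobber without force
  expect_error(simulate_cohort(spec, n_controls = 1, out_dir = dir1),
               "force")
})
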