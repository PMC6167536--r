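test_that("NIfTI write/read round-trips data and affine, gz or not", {
  tr <- affine_transform(translation_mm = c(4, -3, 2),
                         rotation_rad = c(0.1, -0.05, 0.2),
                         scale = c(1.1, 0.9, 1.05),
                         shear = c(0.05, -0.02, 0.03))
  affines <- list(diag(4),
                  diag(c(2, 2, 3.27, 1)),           # anisotropic patient grid
                  affine_matrix(tr) %*% diag(c(2, 2, 3.27, 1)))
  for (A in affines) {
    set.seed(7)
    v <- pet_volume(array(runif(8 * 7 * 6), dim = c(8, 7, 6)), A)
    fgz <- tempfile(fileext = ".nii.gz")
    fnii <- tempfile(fileext = ".nii")
    write_nifti(v, fgz)
    write_nifti(v, fnii)
    rgz <- read_nifti(fgz)
    rnii <- read_nifti(fnii)
    expect_identical(rgz$data, v$data)
    expect_lt(max(abs(rgz$affine - v$affine)), 1e-6)
    expect_identical(rgz$data, rnii$data)
    expect_equal(rgz$affine, rnii$affine)
    expect_equal(rgz$voxel_size_mm, v$voxel_size_mm, tolerance = 1e-6)
  }
})

test_that("degenerate 4D volumes are squeezed; >1 timepoint is refused", {
  img4 <- RNifti::asNifti(array(as.numeric(1:24), dim = c(2, 3, 4, 1)))
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img4, f)
  v <- read_nifti(f)
  expect_length(dim(v$data), 3L)
  expect_equal(dim(v$data), c(2L, 3L, 4L))

  img4b <- RNifti::asNifti(array(0, dim = c(2, 3, 4, 2)))
  f2 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img4b, f2)
  expect_error(read_nifti(f2), "timepoints")
  expect_error(read_nifti(tempfile(fileext = ".nii")), "does not exist")
})

test_that("write_nifti refuses non-finite data", {
  x <- array(0, dim = c(4, 4, 4))
  x[2, 2, 2] <- NaN
  v <- pet_volume(x, diag(4))
  expect_error(write_nifti(v, tempfile(fileext = ".nii")), "non-finite")
})

test_that("volume constructor validates grid and affine", {
  expect_error(pet_volume(matrix(0, 2, 2)), "3D")
  expect_error(pet_volume(array(0, dim = c(2, 2, 2)), matrix(0, 4, 4)),
               "singular")
})

test_that("resampling: identity, pure translation, constant invariance", {
  set.seed(1)
  A <- diag(c(1, 1, 1, 1))
  v <- pet_volume(array(runif(20^3), dim = c(20, 20, 20)), A)
  out <- resample(v, affine_identity(), v)
  expect_equal(out$data, v$data, tolerance = 1e-12)

  # +10 mm x-translation moves a bright voxel 10 voxels in x on a 1 mm grid
  x <- array(0, dim = c(30, 20, 20))
  x[10, 10, 10] <- 1
  vb <- pet_volume(x, A)
  shifted <- resample(vb, affine_transform(translation_mm = c(10, 0, 0)), vb)
  pk <- arrayInd(which.max(shifted$data), dim(shifted$data))
  expect_equal(as.integer(pk), c(20L, 10L, 10L))
  expect_equal(max(shifted$data), 1, tolerance = 1e-12)

  # constant volume stays constant inside the field of view
  vc <- pet_volume(array(5, dim = c(16, 16, 16)), A)
  tr <- affine_transform(translation_mm = c(0.3, -0.2, 0.1),
                         rotation_rad = c(0.02, 0.01, -0.03))
  rc <- resample(vc, tr, vc)
  interior <- rc$data[4:13, 4:13, 4:13]
  expect_true(all(abs(interior - 5) < 1e-9))

  expect_error(resample(v, matrix(0, 4, 4), v), "singular")
})

test_that("resampling under T then T^-1 reproduces a smooth phantom", {
  an <- fx_anatomy()
  base <- fx_template()
  tr <- affine_transform(translation_mm = c(4, -6, 3),
                         rotation_rad = c(0.05, -0.03, 0.08),
                         scale = c(1.04, 0.97, 1.02), shear = c(0.01, 0, -0.02))
  fwd <- resample(base, tr, base)
  back <- resample(fwd, affine_invert(tr), base)
  sel <- base$data > 0.1 & back$data > 0
  expect_gt(cor(base$data[sel], back$data[sel]), 0.99)
})

test_that("nearest-neighbour resampling preserves label values", {
  an <- fx_anatomy()
  lab <- pet_volume(array(as.numeric(an$atlas$labels),
                          dim = dim(an$atlas$labels)), an$atlas$affine)
  tr <- affine_transform(translation_mm = c(3, 0, 0))  # exactly one voxel
  moved <- resample(lab, tr, lab, interpolation = "nearest")
  expect_true(all(moved$data %in% c(0:8)))
  expect_equal(moved$data[2:64, , ], lab$data[1:63, , ])
})

test_that("gaussian smoothing: measured FWHM, mass conservation, linearity", {
  d <- c(33, 33, 33)
  x <- array(0, dim = d)
  x[17, 17, 17] <- 1
  v <- pet_volume(x, diag(c(3, 3, 3, 1)))
  sm <- gaussian_smooth(v, 6)

  # kernel mass is conserved for an interior delta
  expect_equal(sum(sm$data), 1, tolerance = 1e-3)

  # measured FWHM along each axis is 6 mm within one voxel
  for (axis in 1:3) {
    prof <- switch(axis, sm$data[, 17, 17], sm$data[17, , 17], sm$data[17, 17, ])
    half <- max(prof) / 2
    above <- range(which(prof >= half))
    # linear interpolation of the half-max crossings
    lo <- above[1] - (prof[above[1]] - half) /
      (prof[above[1]] - prof[above[1] - 1])
    hi <- above[2] + (prof[above[2]] - half) /
      (prof[above[2]] - prof[above[2] + 1])
    fwhm_mm <- (hi - lo) * 3
    expect_lt(abs(fwhm_mm - 6), 3)
  }

  # constant image unchanged in the interior
  vc <- pet_volume(array(2, dim = d), diag(c(3, 3, 3, 1)))
  smc <- gaussian_smooth(vc, 6)
  expect_equal(smc$data[10:24, 10:24, 10:24],
               array(2, dim = c(15, 15, 15)), tolerance = 1e-9)

  # linearity: smooth(a + b) == smooth(a) + smooth(b)
  set.seed(2)
  a <- pet_volume(array(runif(prod(d)), dim = d), diag(c(3, 3, 3, 1)))
  b <- pet_volume(array(runif(prod(d)), dim = d), diag(c(3, 3, 3, 1)))
  ab <- pet_volume(a$data + b$data, diag(c(3, 3, 3, 1)))
  lhs <- gaussian_smooth(ab, 6)$data
  rhs <- gaussian_smooth(a, 6)$data + gaussian_smooth(b, 6)$data
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-10)

  expect_warning(gaussian_smooth(v, 1), "half a voxel")
})

test_that("affine transform parameterization: identity, inverse, JSON", {
  expect_equal(affine_matrix(affine_identity()), diag(4))
  tr <- affine_transform(translation_mm = c(1, 2, 3),
                         rotation_rad = c(0.1, 0.2, 0.3),
                         scale = c(1.1, 0.9, 1), shear = c(0.02, 0, -0.01),
                         center = c(5, -5, 10))
  M <- affine_matrix(tr)
  expect_equal(M %*% affine_invert(tr), diag(4), tolerance = 1e-12)
  expect_error(affine_transform(scale = c(0, 1, 1)), "positive")

  f <- tempfile(fileext = ".json")
  write_transform(tr, f)
  back <- read_transform(f)
  expect_equal(back$matrix, M, tolerance = 1e-12)
  expect_equal(unlist(back$parameters$translation_mm), c(1, 2, 3),
               ignore_attr = TRUE)
})

test_that("grid presets define centred standard-space geometries", {
  for (nm in c("pediatric_1mm", "adult_2mm", "phantom_3mm")) {
    g <- grid_preset(nm)
    expect_length(g$dim, 3)
    # grid centre maps to the world origin
    centre <- (g$dim - 1) / 2
    expect_equal(as.numeric((g$affine %*% c(centre, 1))[1:3]), c(0, 0, 0))
  }
  expect_equal(grid_preset("pediatric_1mm")$dim, c(197L, 233L, 189L))
  expect_equal(grid_preset("adult_2mm")$dim, c(91L, 109L, 91L))
  # usable as a resampling target
  v <- pet_volume(array(1, dim = c(10, 10, 10)), diag(c(20, 20, 20, 1)))
  out <- resample(v, affine_identity(), grid_preset("adult_2mm"))
  expect_equal(dim(out$data), c(91L, 109L, 91L))
  expect_equal(out$voxel_size_mm, c(2, 2, 2))
})
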