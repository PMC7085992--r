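test_that("NIfTI write/read round-trips data and geometry exactly", {
  arr <- array(rnorm(6 * 5 * 4), c(4, 5, 6))
  vg <- VolumeGrid(arr, spacing = c(3, 1, 1), origin = c(10, -5, 2.5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(vg, f)
  vg2 <- readVolume(f, "CT_HU")
  expect_identical(voxelData(vg2), voxelData(vg))
  expect_equal(spacing(vg2), c(3, 1, 1))
  expect_equal(origin(vg2), c(10, -5, 2.5))
})

test_that("label masks survive the NIfTI round trip", {
  lab <- array(sample(0:2, 60, replace = TRUE), c(3, 4, 5))
  mk <- BinaryMask3D(lab, spacing = c(3, 1, 1), origin = c(0, 1, 2),
                     gridId = "ct")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeMask(mk, f)
  mk2 <- readMask(f, "ct")
  expect_identical(maskLabels(mk2), maskLabels(mk))
  expect_equal(spacing(mk2), spacing(mk))
})

test_that("DICOM-style rescale maps stored values to HU", {
  expect_equal(applyRescale(1064, slope = 1, intercept = -1024), 40)
  expect_equal(applyRescale(c(0, 2048), 0.5, -1000), c(-1000, 24))
})

test_that("SUV conversion follows concentration * weight / dose", {
  mk <- function(v) VolumeGrid(array(v, c(2, 3, 3)),
                               modality = "PET_KBQ_ML")
  expect_equal(unique(as.vector(voxelData(
    computeSUV(mk(5), ScanMeta(70, 350))))), 1)
  expect_equal(unique(as.vector(voxelData(
    computeSUV(mk(0), ScanMeta(70, 350))))), 0)
  expect_equal(unique(as.vector(voxelData(
    computeSUV(mk(2.5), ScanMeta(60, 250))))), 0.6)
})

test_that("SUV conversion is linear and invertible", {
  arr <- array(runif(36, 0, 10), c(2, 3, 6))
  pet <- VolumeGrid(arr, modality = "PET_KBQ_ML")
  meta <- ScanMeta(82.5, 312)
  suv <- computeSUV(pet, meta)
  pet3 <- VolumeGrid(3 * arr, modality = "PET_KBQ_ML")
  expect_equal(voxelData(computeSUV(pet3, meta)), 3 * voxelData(suv))
  back <- voxelData(suv) / (82.5 / 312)
  expect_equal(back, arr, tolerance = 1e-14)
})

test_that("SUV conversion validates modality and metadata", {
  ct <- VolumeGrid(array(0, c(2, 2, 2)), modality = "CT_HU")
  expect_error(computeSUV(ct, ScanMeta(70, 350)), "PET_KBQ_ML")
  expect_error(ScanMeta(-1, 350), "bodyWeightKg")
  expect_error(ScanMeta(70, 0), "injectedDoseMBq")
  expect_error(ScanMeta(70, 350, sex = "x"), "sex")
})

test_that("negative PET voxels are clamped with a message", {
  arr <- array(1, c(2, 2, 2)); arr[1, 1, 1] <- -0.5
  expect_message(vg <- VolumeGrid(arr, modality = "PET_KBQ_ML"),
                 "clamped 1")
  expect_equal(min(voxelData(vg)), 0)
})

test_that("registration check reports offsets and resolution differences", {
  ct <- VolumeGrid(array(0, c(10, 20, 20)), spacing = c(3, 1, 1))
  petSame <- VolumeGrid(array(0, c(10, 5, 5)), spacing = c(3, 4, 4),
                        origin = c(0, 1.5, 1.5), modality = "PET_SUV")
  r <- checkRegistration(ct, petSame, tolMm = 2)
  expect_true(r$aligned)
  expect_equal(r$maxOffsetMm, 0)
  expect_match(r$note, "different voxel resolutions")

  petShift <- VolumeGrid(array(0, c(10, 20, 20)), spacing = c(3, 1, 1),
                         origin = c(0, 10, 0), modality = "PET_SUV")
  r2 <- checkRegistration(ct, petShift, tolMm = 2)
  expect_false(r2$aligned)
  expect_equal(r2$maxOffsetMm, 10)

  petFar <- VolumeGrid(array(0, c(2, 2, 2)), origin = c(1000, 0, 0),
                       modality = "PET_SUV")
  expect_error(checkRegistration(ct, petFar), "disjoint")
})
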