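test_that("masked volume is count times voxel volume", {
  lab <- array(1L, c(10, 10, 10))
  expect_equal(maskedVolume(BinaryMask3D(lab)), 1)      # 1000 x 1 mm^3
  expect_equal(maskedVolume(BinaryMask3D(array(0L, c(3, 3, 3)))), 0)
  m <- array(0L, c(5, 10, 10)); m[1:5, , ] <- 1L        # 500 voxels
  expect_equal(maskedVolume(BinaryMask3D(m, spacing = c(3, 1, 1))), 1.5)
})

test_that("masked volume is additive over disjoint side labels", {
  set.seed(1)
  lab <- array(sample(0:2, 4 * 6 * 6, TRUE, prob = c(.6, .2, .2)),
               c(4, 6, 6))
  mk <- BinaryMask3D(lab, spacing = c(2, 1.5, 1.5))
  expect_equal(maskedVolume(mk),
               maskedVolume(mk, label = 1) + maskedVolume(mk, label = 2))
})

test_that("average attenuation pools both sides and rejects empty masks", {
  arr <- array(40, c(2, 4, 4))
  arr[1, 1, 1] <- 30; arr[1, 1, 2] <- 50
  ct <- VolumeGrid(arr)
  labU <- array(0L, c(2, 4, 4)); labU[2, , ] <- 1L
  expect_equal(averageAttenuation(ct, BinaryMask3D(labU)), 40)
  labM <- array(0L, c(2, 4, 4)); labM[1, 1, 1] <- 1L; labM[1, 1, 2] <- 2L
  expect_equal(averageAttenuation(ct, BinaryMask3D(labM)), 40)
  expect_error(averageAttenuation(ct, BinaryMask3D(array(0L, c(2, 4, 4)))),
               "empty")
})

test_that("N-SUV and VC-SUV follow their definitions", {
  arr <- array(0.9, c(2, 3, 3))
  suv <- VolumeGrid(arr, modality = "PET_SUV")
  lab <- array(1L, c(2, 3, 3))
  mk <- BinaryMask3D(lab)
  ns <- normalizedSUV(suv, mk, liverSuvMean = 2)
  expect_equal(ns$suvMean, 0.9)
  expect_equal(ns$nSuv, 0.45)
  expect_equal(normalizedSUV(suv, mk, 1)$nSuv, 0.9)
  expect_error(normalizedSUV(suv, mk, 0), "liverSuvMean")
  expect_equal(vcSuv(suv, mk, 2), 0)                    # uniform uptake

  v <- array(c(0.4, 0.5, 0.6), c(3, 1, 1))
  suv3 <- VolumeGrid(v, modality = "PET_SUV")
  mk3 <- BinaryMask3D(array(1L, c(3, 1, 1)))
  expect_equal(vcSuv(suv3, mk3, 1), 20)                 # sd .1 / mean .5
  # scale invariance: same on SUV or N-SUV voxels
  expect_equal(vcSuv(suv3, mk3, 1.7), 20)
  suvK <- VolumeGrid(3.2 * v, modality = "PET_SUV")
  expect_equal(vcSuv(suvK, mk3, 1), 20)
})

test_that("liver reference supports masks and spheres", {
  arr <- array(0.5, c(12, 20, 20))
  arr[2:11, 5:15, 5:15] <- 2
  suv <- VolumeGrid(arr, spacing = c(3, 4, 4), modality = "PET_SUV")
  sph <- liverReference(suv, center = c(6 * 3, 10 * 4, 10 * 4),
                        diameterMm = 20)
  expect_equal(sph, 2)
  labL <- array(0L, dim(arr)); labL[5, 8, 8] <- 1L
  expect_equal(liverReference(suv, liverMask = BinaryMask3D(labL)), 2)
  expect_error(liverReference(suv, center = c(-500, 0, 0),
                              diameterMm = 10), "empty|outside")
})

test_that("myocardial metrics enforce the 10 mL minimum VOI", {
  suv <- VolumeGrid(array(3, c(10, 10, 10)), spacing = c(3, 2, 2),
                    modality = "PET_SUV")
  big <- BinaryMask3D(array(1L, c(10, 10, 10)), spacing = c(3, 2, 2))
  mm <- myocardialMetrics(suv, big, liverSuvMean = 2)   # 12 mL VOI
  expect_equal(mm$nSuv, 1.5)
  expect_equal(mm$volumeML, 12)
  expect_equal(myocardialMetrics(suv, big, liverSuvMean = 3)$nSuv, 1)
  smallLab <- array(0L, c(10, 10, 10)); smallLab[1:7, 1, ] <- 1L  # 8.4 mL
  expect_error(myocardialMetrics(suv,
    BinaryMask3D(smallLab, spacing = c(3, 2, 2)), 2), "minimum")
})

test_that("Robinson ideal body weight and volume normalization", {
  expect_equal(idealBodyWeight("male", 177.8), 71)
  expect_equal(idealBodyWeight("female", 152.4), 49)
  expect_equal(idealBodyWeight("female", 120), 49)     # below 60 in
  expect_equal(idealBodyWeight("female", 170), 49 + 1.7 * (170 / 2.54 - 60))
  expect_error(idealBodyWeight("other", 170), "unknown sex")
  expect_equal(normalizeVolume(284, 71), 4)
  expect_error(normalizeVolume(100, 0), "ibwKg")
})

test_that("box-overlap downsampling matches threshold semantics", {
  # CT 4x4x4 @1mm tiling PET 1x1x1 @4mm exactly
  lab <- array(1L, c(4, 4, 4))
  ct <- VolumeGrid(array(0, c(4, 4, 4)))
  pet <- VolumeGrid(array(0, c(1, 1, 1)), spacing = c(4, 4, 4),
                    origin = c(1.5, 1.5, 1.5), modality = "PET_SUV")
  mk <- BinaryMask3D(lab, grid = ct, gridId = "ct")
  dn <- downsampleMaskToPet(mk, ct, pet)
  expect_equal(as.vector(maskLabels(dn)), 1L)
  # 25% coverage at threshold 0.5 -> excluded
  lab2 <- array(0L, c(4, 4, 4)); lab2[, , 1] <- 1L    # one 1-mm sheet
  mk2 <- BinaryMask3D(lab2, grid = ct, gridId = "ct")
  dn2 <- downsampleMaskToPet(mk2, ct, pet)
  expect_equal(as.vector(maskLabels(dn2)), 0L)
  expect_equal(as.vector(maskLabels(
    downsampleMaskToPet(mk2, ct, pet, fracThreshold = 0.25))), 1L)
})

test_that("downsampling equals the brute-force box-overlap oracle", {
  set.seed(7)
  ctDim <- c(10L, 10L, 10L)
  ctSp <- c(2, 1, 1); ctOr <- c(0, 0, 0)
  lab <- array(0L, ctDim)
  lab[2:7, 2:6, 3:8] <- 1L
  lab[5:9, 7:9, 2:5] <- 2L
  ct <- VolumeGrid(array(0, ctDim), spacing = ctSp, origin = ctOr)
  petDim <- c(4L, 5L, 3L)
  petSp <- c(5, 2.3, 3.1); petOr <- c(1.2, -0.4, 0.7)
  pet <- VolumeGrid(array(0, petDim), spacing = petSp, origin = petOr,
                    modality = "PET_SUV")
  mk <- BinaryMask3D(lab, grid = ct, gridId = "ct")
  for (frac in c(0.25, 0.5, 0.8)) {
    fast <- maskLabels(downsampleMaskToPet(mk, ct, pet, frac))
    slow <- bruteDownsample(lab, ctSp, ctOr, petDim, petSp, petOr, frac)
    expect_identical(fast, slow)
  }
})

test_that("downsampling is monotone in the inclusion threshold", {
  set.seed(9)
  lab <- array(sample(0:1, 1000, TRUE), c(10, 10, 10))
  ct <- VolumeGrid(array(0, c(10, 10, 10)))
  pet <- VolumeGrid(array(0, c(3, 3, 3)), spacing = c(3.3, 3.3, 3.3),
                    origin = c(1, 1, 1), modality = "PET_SUV")
  mk <- BinaryMask3D(lab, grid = ct, gridId = "ct")
  prev <- NULL
  for (frac in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- maskLabels(downsampleMaskToPet(mk, ct, pet, frac)) != 0L
    if (!is.null(prev)) expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("full metric extraction is deterministic on a phantom", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  cfg <- smallSegConfig(spec)
  mask <- buildMask(ph$ct, cfg)
  suv <- computeSUV(ph$pet, ph$meta)
  m1 <- extractRoiMetrics(ph$ct, suv, mask, ph$meta,
                          liverCenter = spec$liverCenter)
  m2 <- extractRoiMetrics(ph$ct, suv, mask, ph$meta,
                          liverCenter = spec$liverCenter)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_equal(m1@nSuv, m1@suvMean / m1@liverSuv)
  expect_gt(m1@volumeML, 0)
})
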