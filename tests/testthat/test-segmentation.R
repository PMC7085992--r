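test_that("histogram equalization follows the windowed CDF", {
  sl <- matrix(c(rep(40, 50), rep(-100, 50)), 10, 10)
  eq <- equalizeSlice(sl)
  expect_setequal(unique(as.vector(eq)), c(0.5, 1))
  expect_equal(eq[sl == -100][1], 0.5)   # lower level at CDF 0.5
  expect_equal(eq[sl == 40][1], 1)

  expect_message(eqc <- equalizeSlice(matrix(7, 5, 5)), "constant")
  expect_true(all(eqc == 0))
})

test_that("equalization preserves voxel ranks and is shift invariant", {
  set.seed(3)
  sl <- matrix(runif(400, -150, 250), 20, 20)
  eq <- equalizeSlice(sl)
  expect_equal(order(eq), order(sl))
  expect_true(all(eq >= 0 & eq <= 1))
  expect_equal(equalizeSlice(sl + 40), eq)  # still inside the window
})

test_that("Canny finds a disc boundary and nothing on flat input", {
  expect_equal(nrow(detectEdges(matrix(0.3, 40, 40))), 0)
  n <- 80
  ctr <- c(40.5, 40.5); rad <- 20
  d <- sqrt(outer((1:n - ctr[1])^2, (1:n - ctr[2])^2, `+`))
  img <- 0.2 + 0.6 * (d <= rad)
  ed <- detectEdges(img)
  expect_gt(nrow(ed), 40)
  rEdge <- sqrt((ed[, 1] - ctr[1])^2 + (ed[, 2] - ctr[2])^2)
  expect_true(all(abs(rEdge - rad) <= 2))
})

test_that("raising the high threshold weakly decreases the edge count", {
  set.seed(5)
  img <- matrix(runif(2500), 50, 50)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.8), function(h)
    nrow(detectEdges(img, low = 0.05, high = h)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("region selection picks the innermost admissible candidate", {
  mkRegion <- function(halfw, ctr = c(50, 50)) {
    poly <- rbind(ctr + c(-halfw, -halfw), ctr + c(-halfw, halfw),
                  ctr + c(halfw, halfw), ctr + c(halfw, -halfw))
    list(polygon = poly, area = (2 * halfw)^2, centroid = ctr, maxEdge = 1)
  }
  cfg <- SegmentationConfig(1, 3, rbind(c(50, 40), c(50, 60)))
  prev <- list(left = list(point = c(50, 50), area = NA_real_),
               right = list(point = c(50, 50), area = NA_real_))
  # unique candidate
  sel <- selectPsoasRegions(list(left = list(mkRegion(10)),
                                 right = list(mkRegion(10))), prev, cfg)
  expect_equal(sel$left$area, 400)
  # nested candidates: innermost containing the point wins
  sel2 <- selectPsoasRegions(
    list(left = list(mkRegion(20), mkRegion(8)), right = list()),
    prev, cfg)
  expect_equal(sel2$left$area, 256)
  expect_null(sel2$right)
  # area-ratio bound: candidate 5x the previous area is rejected
  prev5 <- list(left = list(point = c(50, 50), area = 80),
                right = list(point = c(50, 50), area = NA_real_))
  sel3 <- selectPsoasRegions(list(left = list(mkRegion(10)),
                                  right = list()), prev5, cfg)
  expect_null(sel3$left)
})

test_that("phantom segmentation recovers both psoas bodies", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  cfg <- smallSegConfig(spec)
  mask <- buildMask(ph$ct, cfg)
  tr <- truthInRange(ph$truth@ctMask, cfg@sliceStart, cfg@sliceStop)
  mm <- maskLabels(mask)
  expect_gte(diceCoefficient(mm == 1, tr == 1), 0.9)
  expect_gte(diceCoefficient(mm == 2, tr == 2), 0.9)
  # left/right labels sit on the correct sides of the midline
  for (s in cfg@sliceStart:(cfg@sliceStop - 1)) {
    lc <- mean(which(mm[s, , ] == 1, arr.ind = TRUE)[, 2])
    rc <- mean(which(mm[s, , ] == 2, arr.ind = TRUE)[, 2])
    expect_lt(lc, 128.5); expect_gt(rc, 128.5)
  }
  # nonzero voxels only inside the configured range
  outside <- setdiff(seq_len(dim(mm)[1]), cfg@sliceStart:(cfg@sliceStop - 1))
  expect_true(all(mm[outside, , ] == 0L))
})

test_that("segmentation is deterministic and invariant to HU shifts", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  cfg <- smallSegConfig(spec)
  m1 <- buildMask(ph$ct, cfg)
  m2 <- buildMask(ph$ct, cfg)
  expect_identical(maskLabels(m1), maskLabels(m2))
  ctShift <- VolumeGrid(voxelData(ph$ct) + 50, spacing = spacing(ph$ct),
                        origin = origin(ph$ct), modality = "CT_HU")
  m3 <- buildMask(ctShift, cfg)
  expect_identical(maskLabels(m3), maskLabels(m1))
})

test_that("a single-slice range yields a two-label mask", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  cfg <- smallSegConfig(spec)
  cfg@sliceStop <- cfg@sliceStart + 1L
  mask <- buildMask(ph$ct, cfg)
  mm <- maskLabels(mask)
  expect_setequal(unique(as.vector(mm)), c(0L, 1L, 2L))
  expect_true(all(mm[-cfg@sliceStart, , ] == 0L))
})

test_that("dropped slices are repaired up to kMissing, then error", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  cfg <- smallSegConfig(spec)
  ctArr <- voxelData(ph$ct)
  tm <- maskLabels(ph$truth@ctMask)
  s <- cfg@sliceStart + 2L
  ctArr[s, , ][tm[s, , ] == 1L] <- spec$backgroundHu  # erase left muscle
  ctHole <- VolumeGrid(ctArr, spacing = spacing(ph$ct),
                       origin = origin(ph$ct), modality = "CT_HU")
  expect_warning(mask <- buildMask(ctHole, cfg), "filled 1 missing left")
  qc <- attr(mask, "qc")
  expect_equal(qc$filled_from[qc$slice == s & qc$side == "left"], s - 1L)
  expect_gt(sum(maskLabels(mask)[s, , ] == 1L), 0)  # copied contour

  # erase more consecutive slices than kMissing tolerates
  for (ss in s:(s + cfg@kMissing)) ctArr[ss, , ][tm[ss, , ] == 1L] <-
    spec$backgroundHu
  ctBig <- VolumeGrid(ctArr, spacing = spacing(ph$ct),
                      origin = origin(ph$ct), modality = "CT_HU")
  expect_error(suppressWarnings(buildMask(ctBig, cfg)),
               "consecutive failures")
})

test_that("segmentation config validation names its constraints", {
  expect_error(SegmentationConfig(5, 5, rbind(c(1, 1), c(1, 2))),
               "sliceStart")
  expect_error(SegmentationConfig(1, 3, rbind(c(1, 1), c(1, 2)),
                                  cannyLow = 0.5, cannyHigh = 0.2),
               "cannyLow")
  expect_error(SegmentationConfig(1, 3, matrix(1, 3, 2)), "seeds")
})
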