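# Paired CT/PET digital phantoms with analytic ground truth. The anatomy
# is deliberately schematic: an elliptic body outline, a vertebral block,
# two tapered elliptic-cylinder psoas bodies lateral to it, and a liver
# ellipsoid, on a fine CT grid and a coarser, origin-shifted PET grid.

#' Parameters of the digital PET/CT phantom
#'
#' Defaults describe the grids and tissue values the package is calibrated
#' on: a 256 x 256 x 40 CT at 1 x 1 x 3 mm against a 64 x 64 x 40 PET at
#' 4 x 4 x 3 mm (the in-plane coarsening reflecting a ~4 mm PET
#' resolution), muscle attenuation 39.4 HU, liver SUV 2.0, muscle SUV 0.9
#' (N-SUV 0.45) with a voxel SD of 8\% of the mean (VC-SUV 8\%). The PET
#' origin is shifted against the CT grid so the box-overlap downsampler is
#' exercised on non-nested voxels. Noise SDs default to 0.
#'
#' @param ctDim,petDim integer(3) grid sizes (slice, row, col).
#' @param ctSpacing,petSpacing numeric(3) voxel sizes (dz, dy, dx), mm.
#' @param petOriginShift numeric(3) PET origin minus CT origin, mm.
#' @param muscleCenterX,muscleCenterY in-plane muscle centres, mm: the two
#'   bodies sit at x = 128 +/- \code{muscleCenterX}.
#' @param muscleSemiAxes numeric(2) in-plane semi-axes (x, y), mm, at the
#'   widest slice.
#' @param muscleTaper fractional in-plane shrinkage at the cranial/caudal
#'   muscle ends (linear taper).
#' @param muscleSliceRange 1-based inclusive slice range where the muscles
#'   exist.
#' @param muscleHuMean,muscleHuSd CT muscle attenuation, HU.
#' @param backgroundHu,airHu,vertebraHu,liverHu other tissue HU values.
#' @param liverCenter,liverAxes liver ellipsoid centre and semi-axes, mm,
#'   (z, y, x) order.
#' @param liverSuv,muscleSuvMean,muscleSuvSd,backgroundSuv,vertebraSuv PET
#'   SUV values; \code{muscleSuvSd} controls VC-SUV.
#' @param noiseSdCt,noiseSdPet additive Gaussian voxel noise (HU / SUV).
#' @param bodyWeightKg,injectedDoseMBq,sex,heightCm acquisition metadata.
#' @param seed RNG seed for the voxel draws.
#' @return list of class \code{"phantomSpec"}.
#' @seealso [generatePhantom()]
#' @export
phantomSpec <- function(ctDim = c(40L, 256L, 256L),
                        petDim = c(40L, 64L, 64L),
                        ctSpacing = c(3, 1, 1), petSpacing = c(3, 4, 4),
                        petOriginShift = c(0, 2.1, 0.7),
                        muscleCenterX = 37, muscleCenterY = 146,
                        muscleSemiAxes = c(24, 15), muscleTaper = 0.25,
                        muscleSliceRange = c(3L, 38L),
                        muscleHuMean = 39.4, muscleHuSd = 0,
                        backgroundHu = -80, airHu = -1000,
                        vertebraHu = 700, liverHu = 60,
                        liverCenter = c(27, 100, 70),
                        liverAxes = c(24, 28, 36),
                        liverSuv = 2, muscleSuvMean = 0.9,
                        muscleSuvSd = 0.072, backgroundSuv = 0.5,
                        vertebraSuv = 0.6,
                        noiseSdCt = 0, noiseSdPet = 0,
                        bodyWeightKg = 70, injectedDoseMBq = 350,
                        sex = "male", heightCm = 177.8, seed = 1L) {
  spec <- as.list(environment())
  # geometric sanity: muscles clear of the vertebral block and the liver
  vertX <- c(128 - 18, 128 + 18); vertY <- c(110 - 16, 110 + 16)
  musYlo <- muscleCenterY - muscleSemiAxes[2]
  if (musYlo <= vertY[2] + 1)
    stop("spec error: muscles intersect the vertebral block")
  livYhi <- liverCenter[2] + liverAxes[2]
  if (livYhi >= musYlo - 1)
    stop("spec error: liver not disjoint from muscles")
  structure(spec, class = "phantomSpec")
}

#' @export
print.phantomSpec <- function(x, ...) {
  cat(sprintf("phantomSpec: CT %s @ %s mm | PET %s @ %s mm\n",
              paste(x$ctDim, collapse = "x"),
              paste(x$ctSpacing, collapse = "x"),
              paste(x$petDim, collapse = "x"),
              paste(x$petSpacing, collapse = "x")))
  cat(sprintf("  muscle HU %.1f+/-%.1f, SUV %.2f+/-%.3f; liver SUV %.1f; seed %d\n",
              x$muscleHuMean, x$muscleHuSd, x$muscleSuvMean, x$muscleSuvSd,
              x$liverSuv, x$seed))
  invisible(x)
}

.muscleScale <- function(z, spec) {
  # linear in-plane taper over the muscle's z extent; 0 outside it
  zr <- (spec$muscleSliceRange - 1) * spec$ctSpacing[1]
  zmid <- mean(zr); zhalf <- diff(zr) / 2
  u <- abs(z - zmid) / zhalf
  ifelse(u <= 1, 1 - spec$muscleTaper * u, 0)
}

.muscleLabelSlice <- function(y, x, z, spec) {
  # 0/1/2 label matrix for one axial plane of voxel-centre coords (mm)
  s <- .muscleScale(z, spec)
  lab <- matrix(0L, length(y), length(x))
  if (s <= 0) return(lab)
  a <- spec$muscleSemiAxes[1] * s
  b <- spec$muscleSemiAxes[2] * s
  for (side in 1:2) {
    cx <- 128 + c(-1, 1)[side] * spec$muscleCenterX
    inEll <- outer(((y - spec$muscleCenterY) / b)^2,
                   ((x - cx) / a)^2, `+`) <= 1
    lab[inEll] <- side
  }
  lab
}

.truthMask <- function(dimv, spc, org, spec, gridId) {
  lab <- array(0L, dimv)
  y <- org[2] + (seq_len(dimv[2]) - 1) * spc[2]
  x <- org[3] + (seq_len(dimv[3]) - 1) * spc[3]
  for (i in seq_len(dimv[1])) {
    z <- org[1] + (i - 1) * spc[1]
    lab[i, , ] <- .muscleLabelSlice(y, x, z, spec)
  }
  BinaryMask3D(lab, spacing = spc, origin = org, gridId = gridId)
}

#' Analytic psoas volume of a phantom over a slice range
#'
#' Per side: the sum over CT slices of the tapered ellipse area times the
#' slice thickness, in mL.
#'
#' @param spec a [phantomSpec()].
#' @param sliceRange 1-based half-open \code{[start, stop)} CT slice range
#'   (default: the muscle's own extent).
#' @return volume of one psoas body in mL.
#' @export
phantomAnalyticVolume <- function(spec, sliceRange = NULL) {
  if (is.null(sliceRange))
    sliceRange <- c(spec$muscleSliceRange[1], spec$muscleSliceRange[2] + 1L)
  slices <- sliceRange[1]:(sliceRange[2] - 1L)
  z <- (slices - 1) * spec$ctSpacing[1]
  s <- .muscleScale(z, spec)
  areas <- pi * spec$muscleSemiAxes[1] * spec$muscleSemiAxes[2] * s^2
  sum(areas) * spec$ctSpacing[1] / 1000
}

#' Generate a paired CT/PET phantom with ground truth
#'
#' Deterministic given \code{spec$seed}. CT voxels are tissue HU plus
#' Gaussian noise; PET voxels are tissue SUV plus Gaussian noise (a voxel's
#' tissue is decided by its centre), converted to activity concentration
#' with the metadata so that [computeSUV()] round-trips exactly.
#'
#' @param spec a [phantomSpec()].
#' @return list with \code{ct} (\code{CT_HU} [VolumeGrid-class]),
#'   \code{pet} (\code{PET_KBQ_ML} [VolumeGrid-class]), \code{truth}
#'   (a [PhantomTruth-class]), and \code{meta} (a [ScanMeta-class]).
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  set.seed(spec$seed)
  ctOrg <- c(0, 0, 0)
  petOrg <- ctOrg + spec$petOriginShift
  fill <- function(dimv, spc, org, values) {
    # values: list(air, background, vertebra, liver, muscleMean, muscleSd)
    out <- array(values$air, dimv)
    y <- org[2] + (seq_len(dimv[2]) - 1) * spc[2]
    x <- org[3] + (seq_len(dimv[3]) - 1) * spc[3]
    for (i in seq_len(dimv[1])) {
      z <- org[1] + (i - 1) * spc[1]
      sl <- matrix(values$air, dimv[2], dimv[3])
      body <- outer(((y - 128) / 92)^2, ((x - 128) / 110)^2, `+`) <= 1
      sl[body] <- values$background
      vert <- outer(((y - 110) / 16)^2, ((x - 128) / 18)^2, `+`) <= 1
      sl[vert] <- values$vertebra
      lc <- spec$liverCenter; la <- spec$liverAxes
      liv <- outer(((y - lc[2]) / la[2])^2, ((x - lc[3]) / la[3])^2,
                   `+`) + ((z - lc[1]) / la[1])^2 <= 1
      sl[liv] <- values$liver
      mus <- .muscleLabelSlice(y, x, z, spec) > 0L
      nm <- sum(mus)
      if (nm > 0)
        sl[mus] <- values$muscleMean +
          if (values$muscleSd > 0) stats::rnorm(nm, 0, values$muscleSd) else 0
      out[i, , ] <- sl
    }
    out
  }
  ctArr <- fill(spec$ctDim, spec$ctSpacing, ctOrg,
                list(air = spec$airHu, background = spec$backgroundHu,
                     vertebra = spec$vertebraHu, liver = spec$liverHu,
                     muscleMean = spec$muscleHuMean,
                     muscleSd = spec$muscleHuSd))
  if (spec$noiseSdCt > 0)
    ctArr <- ctArr + stats::rnorm(length(ctArr), 0, spec$noiseSdCt)
  suvArr <- fill(spec$petDim, spec$petSpacing, petOrg,
                 list(air = 0, background = spec$backgroundSuv,
                      vertebra = spec$vertebraSuv, liver = spec$liverSuv,
                      muscleMean = spec$muscleSuvMean,
                      muscleSd = spec$muscleSuvSd))
  if (spec$noiseSdPet > 0)
    suvArr <- suvArr + stats::rnorm(length(suvArr), 0, spec$noiseSdPet)
  suvArr[suvArr < 0] <- 0
  meta <- ScanMeta(bodyWeightKg = spec$bodyWeightKg,
                   injectedDoseMBq = spec$injectedDoseMBq,
                   sex = spec$sex, heightCm = spec$heightCm)
  concArr <- suvArr * spec$injectedDoseMBq / spec$bodyWeightKg
  ct <- VolumeGrid(ctArr, spacing = spec$ctSpacing, origin = ctOrg,
                   modality = "CT_HU")
  pet <- VolumeGrid(concArr, spacing = spec$petSpacing, origin = petOrg,
                    modality = "PET_KBQ_ML")
  truth <- new("PhantomTruth",
               ctMask = .truthMask(spec$ctDim, spec$ctSpacing, ctOrg,
                                   spec, "ct"),
               petMask = .truthMask(spec$petDim, spec$petSpacing, petOrg,
                                    spec, "pet"),
               liverCenter = spec$liverCenter, liverAxes = spec$liverAxes,
               params = unclass(spec))
  list(ct = ct, pet = pet, truth = truth, meta = meta)
}

#' Default segmentation configuration for a phantom
#'
#' Seeds at the widest-slice muscle centres, slice bounds just inside the
#' muscle extent (standing in for the operator's D12 / L5-S1 bounds).
#'
#' @param spec a [phantomSpec()].
#' @param margin slices trimmed from each muscle end (default 2).
#' @return a [SegmentationConfig-class].
#' @export
phantomSegmentationConfig <- function(spec, margin = 2L) {
  sl <- spec$muscleSliceRange
  seeds <- rbind(c(spec$muscleCenterY / spec$ctSpacing[2] + 1,
                   (128 - spec$muscleCenterX) / spec$ctSpacing[3] + 1),
                 c(spec$muscleCenterY / spec$ctSpacing[2] + 1,
                   (128 + spec$muscleCenterX) / spec$ctSpacing[3] + 1))
  SegmentationConfig(sliceStart = sl[1] + margin,
                     sliceStop = sl[2] - margin + 1L,
                     seeds = seeds,
                     captureRadius = max(spec$muscleSemiAxes) + 12)
}
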