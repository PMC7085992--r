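#' @import methods
NULL

.MODALITIES <- c("CT_HU", "PET_KBQ_ML", "PET_SUV")

#' VolumeGrid: a 3D scalar image with voxel geometry
#'
#' Container for a single 3D image volume. The voxel array is stored in
#' \code{(slice, row, col)} order with slices along the cranio-caudal axis;
#' \code{spacing} and \code{origin} follow the same axis order
#' \code{(dz, dy, dx)} in millimetres. The \code{modality} slot records the
#' physical meaning of the voxel values: CT attenuation in Hounsfield units
#' (\code{"CT_HU"}), PET activity concentration in kBq/mL
#' (\code{"PET_KBQ_ML"}), or standardized uptake values (\code{"PET_SUV"}).
#'
#' The physical centre of voxel \code{(i, j, k)} (1-based) is
#' \code{origin + (i-1, j-1, k-1) * spacing}; each voxel occupies the closed
#' box of size \code{spacing} centred there.
#'
#' @slot data 3D numeric array, \code{(slice, row, col)}.
#' @slot spacing numeric(3), voxel size in mm, \code{(dz, dy, dx)}, all > 0.
#' @slot origin numeric(3), physical position (mm) of the first voxel centre.
#' @slot modality one of \code{"CT_HU"}, \code{"PET_KBQ_ML"}, \code{"PET_SUV"}.
#'
#' @seealso [VolumeGrid()], [readVolume()], [computeSUV()]
#' @export
setClass("VolumeGrid",
         representation(data = "array", spacing = "numeric",
                        origin = "numeric", modality = "character"))

setValidity("VolumeGrid", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (dz, dy, dx)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(object@modality) != 1L || !(object@modality %in% .MODALITIES))
    msg <- c(msg, sprintf("modality must be one of %s",
                          paste(.MODALITIES, collapse = ", ")))
  else if (object@modality == "CT_HU" && any(!is.finite(object@data)))
    msg <- c(msg, "CT_HU volumes must be finite everywhere")
  else if (object@modality != "CT_HU" && any(object@data < 0, na.rm = TRUE))
    msg <- c(msg, "PET volumes must be non-negative (clamp on construction)")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeGrid
#'
#' Negative PET voxel values (reconstruction artifacts) are clamped to zero;
#' the number of clamped voxels is reported via a message when non-zero.
#'
#' @param data 3D numeric array in \code{(slice, row, col)} order.
#' @param spacing numeric(3) voxel size in mm, \code{(dz, dy, dx)}.
#' @param origin numeric(3) physical position (mm) of voxel (1,1,1) centre.
#' @param modality \code{"CT_HU"}, \code{"PET_KBQ_ML"} or \code{"PET_SUV"}.
#' @return A [VolumeGrid-class] object.
#' @examples
#' vg <- VolumeGrid(array(0, c(4, 8, 8)), spacing = c(3, 1, 1))
#' spacing(vg)
#' @export
VolumeGrid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       modality = "CT_HU") {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (modality %in% c("PET_KBQ_ML", "PET_SUV")) {
    nneg <- sum(data < 0)
    if (nneg > 0) {
      message(sprintf("clamped %d negative PET voxel(s) to 0", nneg))
      data[data < 0] <- 0
    }
  }
  new("VolumeGrid", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality)
}

#' Acquisition metadata for one PET/CT study
#'
#' @slot bodyWeightKg body weight in kg (> 0).
#' @slot injectedDoseMBq injected FDG activity in MBq (> 0).
#' @slot sex \code{"male"} or \code{"female"} (used by the Robinson ideal
#'   body weight formula).
#' @slot heightCm standing height in cm (> 0).
#' @slot liverSuvMean optional precomputed mean liver SUV (NA if it is to be
#'   measured from the PET volume with [liverReference()]).
#' @seealso [ScanMeta()], [computeSUV()], [idealBodyWeight()]
#' @export
setClass("ScanMeta",
         representation(bodyWeightKg = "numeric", injectedDoseMBq = "numeric",
                        sex = "character", heightCm = "numeric",
                        liverSuvMean = "numeric"))

setValidity("ScanMeta", function(object) {
  msg <- character(0)
  if (!isTRUE(object@bodyWeightKg > 0))
    msg <- c(msg, "bodyWeightKg must be > 0")
  if (!isTRUE(object@injectedDoseMBq > 0))
    msg <- c(msg, "injectedDoseMBq must be > 0")
  if (!(object@sex %in% c("male", "female")))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (!isTRUE(object@heightCm > 0))
    msg <- c(msg, "heightCm must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ScanMeta-class
#' @param bodyWeightKg,injectedDoseMBq,sex,heightCm,liverSuvMean see slots.
#' @return A \code{ScanMeta} object.
#' @export
ScanMeta <- function(bodyWeightKg, injectedDoseMBq, sex = "male",
                     heightCm = 170, liverSuvMean = NA_real_) {
  new("ScanMeta", bodyWeightKg = as.numeric(bodyWeightKg),
      injectedDoseMBq = as.numeric(injectedDoseMBq), sex = sex,
      heightCm = as.numeric(heightCm),
      liverSuvMean = as.numeric(liverSuvMean))
}

#' Labeled 3D mask aligned to a named voxel grid
#'
#' Voxel labels are 0 (background), 1 (left psoas) and 2 (right psoas).
#' The mask carries a copy of the geometry of the grid it indexes plus a
#' free-form \code{gridId} naming that grid (e.g. \code{"ct"}, \code{"pet"}).
#'
#' @slot labels 3D integer array with values in \{0, 1, 2\}.
#' @slot spacing,origin geometry of the indexed grid (same conventions as
#'   [VolumeGrid-class]).
#' @slot gridId character scalar naming the grid the labels index.
#' @seealso [BinaryMask3D()], [buildMask()], [downsampleMaskToPet()]
#' @export
setClass("BinaryMask3D",
         representation(labels = "array", spacing = "numeric",
                        origin = "numeric", gridId = "character"))

setValidity("BinaryMask3D", function(object) {
  msg <- character(0)
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (!all(object@labels %in% c(0L, 1L, 2L)))
    msg <- c(msg, "labels must take values in {0, 1, 2}")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (length(msg)) msg else TRUE
})

#' @rdname BinaryMask3D-class
#' @param labels,spacing,origin,gridId see slots.
#' @param grid optional [VolumeGrid-class] supplying spacing/origin.
#' @return A \code{BinaryMask3D} object.
#' @export
BinaryMask3D <- function(labels, grid = NULL, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), gridId = "grid") {
  if (!is.null(grid)) {
    spacing <- spacing(grid)
    origin <- origin(grid)
  }
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  new("BinaryMask3D", labels = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), gridId = gridId)
}

#' Configuration of the psoas segmentation algorithm
#'
#' The visual-inspection step of the original slice-based workflow is made
#' explicit and reproducible: the operator supplies the cranial (D12) and
#' caudal (L5--S1) axial slice bounds and one seed point per psoas body on
#' the first analyzed slice; everything downstream is automatic.
#'
#' @slot sliceStart,sliceStop 1-based half-open slice range
#'   \code{[sliceStart, sliceStop)} to segment.
#' @slot seeds 2x2 numeric matrix, rows = (left, right) seed, columns =
#'   (row, col) pixel coordinates on slice \code{sliceStart}. Left means the
#'   smaller column index.
#' @slot alpha alpha-shape disc curvature (1/mm of the in-plane pixel unit);
#'   the closure uses discs of radius \code{1/alpha}. \code{NA} (default)
#'   auto-tunes per slice and side: the smallest disc radius whose
#'   alpha-complex has a closed face containing the tracking point.
#' @slot cannySigma Gaussian smoothing scale (px) of the Canny detector.
#' @slot cannyLow,cannyHigh hysteresis thresholds expressed as fractions of
#'   the slice's maximum gradient magnitude; \code{0 < low < high}. Defaults
#'   tuned on the package's digital phantoms.
#' @slot bodyWindow HU interval used to window the slice before histogram
#'   equalization (default \code{c(-200, 300)}, a soft-tissue body window).
#' @slot areaRatioBounds allowed per-slice area change of a tracked region
#'   relative to the previous slice (default \code{c(0.5, 2)}).
#' @slot kMissing maximum run of consecutive per-side segmentation failures
#'   repaired by copying the nearest selected contour (default 2).
#' @slot captureRadius half-width (px) of the square window of edge points
#'   around the tracking point fed to the alpha-shape closure.
#' @slot contourInset inward offset (px) applied to the selected contour
#'   before rasterization. The Canny ridge line is itself half a pixel
#'   wide; the default 0.5 takes the region to be the interior of the
#'   ridge, which keeps boundary attenuation samples inside the muscle.
#' @seealso [SegmentationConfig()], [buildMask()]
#' @export
setClass("SegmentationConfig",
         representation(sliceStart = "integer", sliceStop = "integer",
                        seeds = "matrix", alpha = "numeric",
                        cannySigma = "numeric", cannyLow = "numeric",
                        cannyHigh = "numeric", bodyWindow = "numeric",
                        areaRatioBounds = "numeric", kMissing = "integer",
                        captureRadius = "numeric",
                        contourInset = "numeric"))

setValidity("SegmentationConfig", function(object) {
  msg <- character(0)
  if (!isTRUE(object@sliceStart < object@sliceStop))
    msg <- c(msg, "sliceStart must be < sliceStop (half-open range)")
  if (object@sliceStart < 1L)
    msg <- c(msg, "sliceStart must be >= 1")
  if (!all(dim(object@seeds) == c(2L, 2L)))
    msg <- c(msg, "seeds must be a 2x2 matrix: rows (left, right), cols (row, col)")
  if (!is.na(object@alpha) && !isTRUE(object@alpha > 0))
    msg <- c(msg, "alpha must be > 0 (or NA for auto-tuning)")
  if (!isTRUE(object@cannyLow > 0 && object@cannyLow < object@cannyHigh))
    msg <- c(msg, "need 0 < cannyLow < cannyHigh")
  if (length(object@bodyWindow) != 2L ||
      !isTRUE(object@bodyWindow[1] < object@bodyWindow[2]))
    msg <- c(msg, "bodyWindow must be an increasing HU interval")
  if (length(object@areaRatioBounds) != 2L ||
      !isTRUE(object@areaRatioBounds[1] > 0) ||
      !isTRUE(object@areaRatioBounds[1] < object@areaRatioBounds[2]))
    msg <- c(msg, "areaRatioBounds must be an increasing positive interval")
  if (object@kMissing < 0L)
    msg <- c(msg, "kMissing must be >= 0")
  if (!isTRUE(object@captureRadius > 2))
    msg <- c(msg, "captureRadius must be > 2 px")
  if (!isTRUE(object@contourInset >= 0 && object@contourInset <= 2))
    msg <- c(msg, "contourInset must be in [0, 2] px")
  if (length(msg)) msg else TRUE
})

#' @rdname SegmentationConfig-class
#' @param sliceStart,sliceStop,seeds,alpha,cannySigma,cannyLow,cannyHigh
#'   see slots.
#' @param bodyWindow,areaRatioBounds,kMissing,captureRadius see slots.
#' @return A \code{SegmentationConfig} object.
#' @export
SegmentationConfig <- function(sliceStart, sliceStop, seeds,
                               alpha = NA_real_, cannySigma = 1.4,
                               cannyLow = 0.012, cannyHigh = 0.03,
                               bodyWindow = c(-200, 300),
                               areaRatioBounds = c(0.5, 2),
                               kMissing = 2L, captureRadius = 35,
                               contourInset = 0) {
  seeds <- as.matrix(seeds)
  if (!all(dim(seeds) == c(2L, 2L)))
    stop("seeds must be a 2x2 matrix: rows (left, right), cols (row, col)")
  # canonical order: left = smaller column
  if (seeds[1, 2] > seeds[2, 2]) seeds <- seeds[2:1, , drop = FALSE]
  dimnames(seeds) <- list(c("left", "right"), c("row", "col"))
  new("SegmentationConfig", sliceStart = as.integer(sliceStart),
      sliceStop = as.integer(sliceStop), seeds = seeds,
      alpha = as.numeric(alpha), cannySigma = as.numeric(cannySigma),
      cannyLow = as.numeric(cannyLow), cannyHigh = as.numeric(cannyHigh),
      bodyWindow = as.numeric(bodyWindow),
      areaRatioBounds = as.numeric(areaRatioBounds),
      kMissing = as.integer(kMissing),
      captureRadius = as.numeric(captureRadius),
      contourInset = as.numeric(contourInset))
}

#' Per-subject structural and metabolic psoas indices
#'
#' The subject-level outputs of the pipeline: psoas volume in mL and
#' normalized to Robinson ideal body weight (mL/kg), average attenuation
#' coefficient (AAC, HU), mean SUV, liver-normalized SUV (N-SUV) and the
#' voxelwise coefficient of variation of N-SUV (VC-SUV, %), with the voxel
#' counts on each grid they were measured on.
#'
#' @slot volumeML psoas volume, mL (CT grid).
#' @slot volumePerIbw volume / ideal body weight, mL/kg.
#' @slot aacHU mean attenuation over the CT-grid mask, HU.
#' @slot suvMean mean SUV over the PET-grid mask.
#' @slot nSuv \code{suvMean / liverSuv}.
#' @slot vcSuvPct 100 * sample SD / mean of per-voxel N-SUV, both psoas
#'   bodies pooled.
#' @slot liverSuv mean liver SUV used for normalization.
#' @slot nVoxelsCT,nVoxelsPET mask voxel counts.
#' @seealso [extractRoiMetrics()]
#' @export
setClass("RoiMetrics",
         representation(volumeML = "numeric", volumePerIbw = "numeric",
                        aacHU = "numeric", suvMean = "numeric",
                        nSuv = "numeric", vcSuvPct = "numeric",
                        liverSuv = "numeric", nVoxelsCT = "integer",
                        nVoxelsPET = "integer"))

setValidity("RoiMetrics", function(object) {
  msg <- character(0)
  if (isTRUE(object@volumeML < 0)) msg <- c(msg, "volumeML must be >= 0")
  if (isTRUE(object@vcSuvPct < 0)) msg <- c(msg, "vcSuvPct must be >= 0")
  if (is.finite(object@nSuv) && is.finite(object@suvMean) &&
      is.finite(object@liverSuv) &&
      abs(object@nSuv - object@suvMean / object@liverSuv) > 1e-12)
    msg <- c(msg, "nSuv must equal suvMean / liverSuv")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic PET/CT phantom
#'
#' @slot ctMask,petMask [BinaryMask3D-class] ground-truth psoas labels on
#'   the CT and PET grids.
#' @slot liverCenter,liverAxes geometry (mm) of the liver ellipsoid.
#' @slot params named list echoing the generative parameters
#'   (HU / SUV means and SDs, geometry, noise, seed).
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomTruth",
         representation(ctMask = "BinaryMask3D", petMask = "BinaryMask3D",
                        liverCenter = "numeric", liverAxes = "numeric",
                        params = "list"))
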