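# Per-subject structural and metabolic indices: CT-grid mask -> volume and
# AAC; exact box-overlap downsampling to the PET grid -> SUV, N-SUV, VC-SUV.

.axisOverlap <- function(nTo, sTo, oTo, nFrom, sFrom, oFrom) {
  # nTo x nFrom matrix of 1D box-overlap lengths divided by the target
  # voxel length (so rows of an all-covered target sum to 1)
  toLo <- oTo + (seq_len(nTo) - 1) * sTo - sTo / 2
  toHi <- toLo + sTo
  fromLo <- oFrom + (seq_len(nFrom) - 1) * sFrom - sFrom / 2
  fromHi <- fromLo + sFrom
  ov <- pmax(outer(toHi, fromHi, pmin) - outer(toLo, fromLo, pmax), 0)
  ov / sTo
}

#' Downsample a CT-grid label mask to the PET grid by exact box overlap
#'
#' For every PET voxel the exact fraction of its physical box covered by
#' CT mask voxels is computed (the grids are axis-aligned, so the overlap
#' volume separates into per-axis overlap lengths). A PET voxel is included
#' when the total covered fraction reaches \code{fracThreshold}, and takes
#' the side label (left/right) with the larger coverage.
#'
#' @param mask a [BinaryMask3D-class] on the CT grid.
#' @param ct,pet [VolumeGrid-class] objects defining the two grids.
#' @param fracThreshold minimum covered volume fraction for inclusion
#'   (default 0.5).
#' @return A [BinaryMask3D-class] on the PET grid.
#' @export
downsampleMaskToPet <- function(mask, ct, pet, fracThreshold = 0.5) {
  stopifnot(is(mask, "BinaryMask3D"), is(ct, "VolumeGrid"),
            is(pet, "VolumeGrid"))
  if (!all(dim(mask) == dim(ct)))
    stop("geometry error: mask is not on the CT grid")
  reg <- checkRegistration(ct, pet, tolMm = Inf)  # errors if disjoint
  dC <- dim(ct@data); dP <- dim(pet@data)
  W <- lapply(1:3, function(a)
    .axisOverlap(dP[a], pet@spacing[a], pet@origin[a],
                 dC[a], ct@spacing[a], ct@origin[a]))
  cover <- function(lab) {
    ind <- mask@labels == lab
    out <- array(0, dP)
    for (zp in seq_len(dP[1])) {
      wz <- W[[1]][zp, ]
      zc <- which(wz > 0)
      if (!length(zc)) next
      acc <- matrix(0, dP[2], dP[3])
      for (z in zc)
        acc <- acc + wz[z] * (W[[2]] %*% ind[z, , ] %*% t(W[[3]]))
      out[zp, , ] <- acc
    }
    out
  }
  c1 <- cover(1L)
  c2 <- cover(2L)
  tot <- c1 + c2
  labels <- array(0L, dP)
  inc <- tot >= fracThreshold - 1e-12
  labels[inc & c1 >= c2] <- 1L
  labels[inc & c2 > c1] <- 2L
  BinaryMask3D(labels, grid = pet, gridId = "pet")
}

#' Volume of a mask in mL
#'
#' Nonzero-voxel count times the voxel volume (mm^3) divided by 1000.
#'
#' @param mask a [BinaryMask3D-class].
#' @param label optional: restrict to one side label (1 or 2).
#' @return volume in mL.
#' @export
maskedVolume <- function(mask, label = NULL) {
  n <- if (is.null(label)) sum(mask@labels != 0L) else
    sum(mask@labels == as.integer(label))
  n * prod(mask@spacing) / 1000
}

#' Average attenuation coefficient (AAC) over a mask
#'
#' Arithmetic mean HU over the nonzero-mask voxels, both sides pooled.
#'
#' @param ct a [VolumeGrid-class] with modality \code{"CT_HU"}.
#' @param mask a [BinaryMask3D-class] aligned to the CT grid.
#' @return mean attenuation in HU.
#' @export
averageAttenuation <- function(ct, mask) {
  stopifnot(is(ct, "VolumeGrid"), is(mask, "BinaryMask3D"))
  if (ct@modality != "CT_HU")
    stop("input error: averageAttenuation expects a CT_HU volume")
  sel <- mask@labels != 0L
  if (!any(sel)) stop("input error: empty mask")
  mean(ct@data[sel])
}

#' Mean SUV and liver-normalized SUV over a mask
#'
#' @param petSuv a [VolumeGrid-class] with modality \code{"PET_SUV"}.
#' @param mask a [BinaryMask3D-class] on the PET grid.
#' @param liverSuvMean mean liver SUV (> 0) used as normalizer.
#' @return list with \code{suvMean} and \code{nSuv = suvMean /
#'   liverSuvMean}.
#' @export
normalizedSUV <- function(petSuv, mask, liverSuvMean) {
  stopifnot(is(petSuv, "VolumeGrid"), is(mask, "BinaryMask3D"))
  if (petSuv@modality != "PET_SUV")
    stop("input error: normalizedSUV expects a PET_SUV volume")
  if (!isTRUE(liverSuvMean > 0))
    stop("input error: liverSuvMean must be > 0")
  sel <- mask@labels != 0L
  if (!any(sel)) stop("input error: empty mask")
  m <- mean(petSuv@data[sel])
  list(suvMean = m, nSuv = m / liverSuvMean)
}

#' Variation coefficient of N-SUV over the psoas voxels (VC-SUV, %)
#'
#' 100 times the sample (n-1) standard deviation over the mean of the
#' per-voxel N-SUV, pooling the voxels of both psoas bodies. Because the
#' liver normalizer divides numerator and denominator alike, VC-SUV is
#' identical whether computed on SUV or N-SUV voxels.
#'
#' @inheritParams normalizedSUV
#' @return VC-SUV in percent.
#' @export
vcSuv <- function(petSuv, mask, liverSuvMean = 1) {
  stopifnot(is(petSuv, "VolumeGrid"), is(mask, "BinaryMask3D"))
  if (!isTRUE(liverSuvMean > 0))
    stop("input error: liverSuvMean must be > 0")
  sel <- mask@labels != 0L
  if (sum(sel) < 2L)
    stop("input error: need at least 2 mask voxels for VC-SUV")
  v <- petSuv@data[sel] / liverSuvMean
  if (mean(v) <= 0)
    stop("input error: VC-SUV undefined for non-positive mean uptake")
  100 * stats::sd(v) / mean(v)
}

#' Mean liver SUV from a mask or a configured sphere
#'
#' The liver reference region is either a supplied mask or a sphere
#' (default diameter 30 mm) at a configured physical centre.
#'
#' @param petSuv a [VolumeGrid-class] with modality \code{"PET_SUV"}.
#' @param liverMask optional [BinaryMask3D-class] on the PET grid (any
#'   nonzero label).
#' @param center numeric(3) physical centre (mm, slice/row/col axes) of the
#'   sphere, used when \code{liverMask} is NULL.
#' @param diameterMm sphere diameter in mm (default 30).
#' @return mean SUV over the region.
#' @export
liverReference <- function(petSuv, liverMask = NULL, center = NULL,
                           diameterMm = 30) {
  stopifnot(is(petSuv, "VolumeGrid"))
  if (!is.null(liverMask)) {
    sel <- liverMask@labels != 0L
  } else {
    if (is.null(center))
      stop("input error: supply liverMask or a sphere center")
    d <- dim(petSuv@data)
    cz <- petSuv@origin[1] + (seq_len(d[1]) - 1) * petSuv@spacing[1]
    cy <- petSuv@origin[2] + (seq_len(d[2]) - 1) * petSuv@spacing[2]
    cx <- petSuv@origin[3] + (seq_len(d[3]) - 1) * petSuv@spacing[3]
    r2 <- (diameterMm / 2)^2
    dz2 <- (cz - center[1])^2
    dy2 <- (cy - center[2])^2
    dx2 <- (cx - center[3])^2
    sel <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r2
  }
  if (!any(sel))
    stop("input error: liver region is empty or outside the volume")
  mean(petSuv@data[sel])
}

#' Myocardial N-SUV over a left-ventricular mask
#'
#' As [normalizedSUV()] over the supplied LV mask, with the minimum
#' volume-of-interest constraint of 10 mL enforced.
#'
#' @param petSuv a [VolumeGrid-class] with modality \code{"PET_SUV"}.
#' @param lvMask a [BinaryMask3D-class] on the PET grid.
#' @param liverSuvMean mean liver SUV (> 0).
#' @param minVolumeML minimum admissible mask volume (default 10 mL).
#' @return list with \code{suvMean}, \code{nSuv}, \code{volumeML}.
#' @export
myocardialMetrics <- function(petSuv, lvMask, liverSuvMean,
                              minVolumeML = 10) {
  vol <- maskedVolume(lvMask)
  if (vol < minVolumeML)
    stop(sprintf(
      "constraint error: myocardial VOI %.2f mL below the %.0f mL minimum",
      vol, minVolumeML))
  ns <- normalizedSUV(petSuv, lvMask, liverSuvMean)
  c(ns, list(volumeML = vol))
}

#' Robinson ideal body weight
#'
#' Robinson's formula: 52 kg (male) or 49 kg (female) at 60 inches, plus
#' 1.9 kg (male) or 1.7 kg (female) per inch of height above 60; heights at
#' or below 60 inches return the base weight.
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @param heightCm height in cm (> 0).
#' @return ideal body weight in kg.
#' @examples
#' idealBodyWeight("male", 177.8)  # 70 in -> 71 kg
#' @export
idealBodyWeight <- function(sex, heightCm) {
  if (!isTRUE(heightCm > 0)) stop("input error: heightCm must be > 0")
  inches <- heightCm / 2.54
  over <- max(0, inches - 60)
  if (identical(sex, "male")) 52 + 1.9 * over
  else if (identical(sex, "female")) 49 + 1.7 * over
  else stop("input error: unknown sex code '", sex, "'")
}

#' Normalize a muscle volume to ideal body weight
#'
#' @param volumeML volume in mL.
#' @param ibwKg ideal body weight in kg (> 0).
#' @return volume in mL/kg.
#' @export
normalizeVolume <- function(volumeML, ibwKg) {
  if (!isTRUE(ibwKg > 0)) stop("input error: ibwKg must be > 0")
  volumeML / ibwKg
}

#' Full per-subject ROI metric extraction
#'
#' Computes the structural indices (volume, IBW-normalized volume, AAC) on
#' the CT-grid mask and the metabolic indices (mean SUV, N-SUV, VC-SUV) on
#' the PET-grid mask obtained by exact box-overlap downsampling. The liver
#' normalizer comes from \code{meta} when present, else from
#' \code{liverMask}/\code{liverCenter}.
#'
#' @param ct CT [VolumeGrid-class]; \code{mask} must live on its grid.
#' @param petSuv PET SUV [VolumeGrid-class].
#' @param mask CT-grid psoas [BinaryMask3D-class].
#' @param meta a [ScanMeta-class] (sex/height for IBW; optional liver SUV).
#' @param liverMask,liverCenter,liverDiameterMm liver reference region (see
#'   [liverReference()]), used when \code{meta} has no liver SUV.
#' @param fracThreshold PET-voxel inclusion threshold (default 0.5).
#' @return A [RoiMetrics-class].
#' @export
extractRoiMetrics <- function(ct, petSuv, mask, meta, liverMask = NULL,
                              liverCenter = NULL, liverDiameterMm = 30,
                              fracThreshold = 0.5) {
  liver <- meta@liverSuvMean
  if (is.na(liver))
    liver <- liverReference(petSuv, liverMask = liverMask,
                            center = liverCenter,
                            diameterMm = liverDiameterMm)
  petMask <- downsampleMaskToPet(mask, ct, petSuv, fracThreshold)
  vol <- maskedVolume(mask)
  ibw <- idealBodyWeight(meta@sex, meta@heightCm)
  ns <- normalizedSUV(petSuv, petMask, liver)
  vc <- vcSuv(petSuv, petMask, liver)
  new("RoiMetrics", volumeML = vol,
      volumePerIbw = normalizeVolume(vol, ibw),
      aacHU = averageAttenuation(ct, mask),
      suvMean = ns$suvMean, nSuv = ns$nSuv, vcSuvPct = vc,
      liverSuv = liver, nVoxelsCT = sum(mask@labels != 0L),
      nVoxelsPET = sum(petMask@labels != 0L))
}
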