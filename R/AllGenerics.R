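#' Accessors for imaging containers
#'
#' @param x a [VolumeGrid-class] or [BinaryMask3D-class].
#' @return \code{voxelData}/\code{maskLabels}: the raw array;
#'   \code{spacing}, \code{origin}: numeric(3) in \code{(dz, dy, dx)} mm;
#'   \code{modality}: character scalar; \code{voxelVolumeML}: the volume of
#'   one voxel in mL.
#' @name volume-accessors
#' @examples
#' vg <- VolumeGrid(array(0, c(2, 3, 4)), spacing = c(3, 1, 1))
#' dim(voxelData(vg)); voxelVolumeML(vg)
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname volume-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname volume-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname volume-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelVolumeML", function(x) standardGeneric("voxelVolumeML"))
#' @rdname volume-accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "VolumeGrid", function(x) x@data)
#' @rdname volume-accessors
#' @export
setMethod("spacing", "VolumeGrid", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("spacing", "BinaryMask3D", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("origin", "VolumeGrid", function(x) x@origin)
#' @rdname volume-accessors
#' @export
setMethod("origin", "BinaryMask3D", function(x) x@origin)
#' @rdname volume-accessors
#' @export
setMethod("modality", "VolumeGrid", function(x) x@modality)
#' @rdname volume-accessors
#' @export
setMethod("voxelVolumeML", "VolumeGrid", function(x) prod(x@spacing) / 1000)
#' @rdname volume-accessors
#' @export
setMethod("voxelVolumeML", "BinaryMask3D", function(x) prod(x@spacing) / 1000)
#' @rdname volume-accessors
#' @export
setMethod("maskLabels", "BinaryMask3D", function(x) x@labels)

#' @export
setMethod("dim", "VolumeGrid", function(x) dim(x@data))
#' @export
setMethod("dim", "BinaryMask3D", function(x) dim(x@labels))

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid [%s]: %d x %d x %d (slice x row x col)\n",
              object@modality, d[1], d[2], d[3]))
  cat(sprintf("  spacing (dz,dy,dx): %s mm; origin: %s mm\n",
              paste(format(object@spacing), collapse = " x "),
              paste(format(object@origin), collapse = ", ")))
  rng <- range(object@data)
  cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "BinaryMask3D", function(object) {
  d <- dim(object@labels)
  cat(sprintf("BinaryMask3D on grid '%s': %d x %d x %d\n",
              object@gridId, d[1], d[2], d[3]))
  cat(sprintf("  voxels: left = %d, right = %d; volume = %.2f mL\n",
              sum(object@labels == 1L), sum(object@labels == 2L),
              sum(object@labels != 0L) * prod(object@spacing) / 1000))
})

setMethod("show", "ScanMeta", function(object) {
  cat(sprintf("ScanMeta: %s, %.1f kg, %.1f cm, dose %.1f MBq, liver SUV %s\n",
              object@sex, object@bodyWeightKg, object@heightCm,
              object@injectedDoseMBq,
              ifelse(is.na(object@liverSuvMean), "unset",
                     format(object@liverSuvMean))))
})

setMethod("show", "RoiMetrics", function(object) {
  cat("RoiMetrics\n")
  cat(sprintf("  volume: %.2f mL (%.2f mL/kg IBW)\n",
              object@volumeML, object@volumePerIbw))
  cat(sprintf("  AAC: %.1f HU\n", object@aacHU))
  cat(sprintf("  SUV mean: %.3f; N-SUV: %.3f (liver %.3f); VC-SUV: %.2f%%\n",
              object@suvMean, object@nSuv, object@liverSuv, object@vcSuvPct))
  cat(sprintf("  voxels: %d CT, %d PET\n",
              object@nVoxelsCT, object@nVoxelsPET))
})

#' Convert RoiMetrics to a one-row data.frame
#'
#' @param x a [RoiMetrics-class].
#' @param row.names,optional,... passed through for generic consistency.
#' @return one-row \code{data.frame} with the cohort-table columns.
#' @export
as.data.frame.RoiMetrics <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(volume_mL = x@volumeML, volume_mL_per_kg = x@volumePerIbw,
             aac_HU = x@aacHU, suv_mean = x@suvMean, n_suv = x@nSuv,
             vc_suv_pct = x@vcSuvPct, liver_suv = x@liverSuv,
             n_voxels_ct = x@nVoxelsCT, n_voxels_pet = x@nVoxelsPET,
             row.names = row.names)
}
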