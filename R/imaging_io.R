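#' Read a 3D volume from a NIfTI-1 file
#'
#' Loads a \code{.nii} / \code{.nii.gz} volume into a [VolumeGrid-class],
#' taking the voxel size and the position of the first voxel from the image
#' transform. Axes are normalized to the package convention: arrays are
#' \code{(slice, row, col)} with slices along the cranio-caudal axis, which
#' corresponds to NIfTI's \code{(x, y, z)} storage reversed.
#'
#' @param path NIfTI file path.
#' @param modalityHint modality to record: \code{"CT_HU"} (default),
#'   \code{"PET_KBQ_ML"} or \code{"PET_SUV"}.
#' @return A [VolumeGrid-class].
#' @seealso [writeVolume()], [applyRescale()]
#' @export
readVolume <- function(path, modalityHint = "CT_HU") {
  if (!file.exists(path))
    stop("input error: file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("input error: expected a 3D volume, got dims ",
         paste(dim(arr), collapse = "x"))
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("geometry error: non-positive voxel spacing in header")
  xf <- RNifti::xform(img)
  orig_xyz <- xf[1:3, 4]
  # (x, y, z) storage -> (slice, row, col)
  VolumeGrid(aperm(arr, c(3, 2, 1)), spacing = rev(pd),
             origin = rev(orig_xyz), modality = modalityHint)
}

#' Write a VolumeGrid to NIfTI-1
#'
#' Written as double precision so that \code{readVolume(writeVolume(x))}
#' round-trips data and geometry exactly.
#'
#' @param volume a [VolumeGrid-class].
#' @param path output file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VolumeGrid"))
  arr <- aperm(volume@data, c(3, 2, 1))
  sp <- rev(volume@spacing)   # (dx, dy, dz)
  or <- rev(volume@origin)    # (x0, y0, z0)
  img <- RNifti::asNifti(arr, reference = list(pixdim = c(-1, sp, 1, 1, 1, 1)),
                         datatype = "double")
  m <- diag(4)
  m[1, 1] <- sp[1]; m[2, 2] <- sp[2]; m[3, 3] <- sp[3]
  m[1:3, 4] <- or
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write / read a label mask as NIfTI
#'
#' Masks use integer labels \{0, 1, 2\} = background / left / right psoas.
#'
#' @param mask a [BinaryMask3D-class].
#' @param path NIfTI file path.
#' @param gridId grid name to record on read.
#' @return \code{writeMask}: \code{path} invisibly; \code{readMask}: a
#'   [BinaryMask3D-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask3D"))
  vg <- VolumeGrid(mask@labels, spacing = mask@spacing,
                   origin = mask@origin, modality = "CT_HU")
  writeVolume(vg, path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, gridId = "grid") {
  vg <- readVolume(path, modalityHint = "CT_HU")
  lab <- round(vg@data)
  if (!all(lab %in% c(0, 1, 2)))
    stop("input error: mask file contains labels outside {0, 1, 2}")
  BinaryMask3D(lab, spacing = vg@spacing, origin = vg@origin, gridId = gridId)
}

#' Apply a linear rescale (slope / intercept) to stored pixel values
#'
#' The affine transform used by CT DICOM to map stored integers to
#' Hounsfield units: \code{HU = slope * stored + intercept}.
#'
#' @param stored numeric stored pixel values.
#' @param slope,intercept rescale parameters.
#' @return numeric rescaled values.
#' @examples
#' applyRescale(1064, slope = 1, intercept = -1024)  # 40 HU
#' @export
applyRescale <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Convert a PET concentration volume to SUV
#'
#' Voxelwise standardized uptake value: the product of radiotracer
#' concentration (kBq/mL) and body weight (kg) divided by the injected FDG
#' dose (MBq). Units cancel because 1 MBq = 1000 kBq and 1 kg of tissue is
#' taken as 1000 mL.
#'
#' @param pet a [VolumeGrid-class] with modality \code{"PET_KBQ_ML"}.
#' @param meta a [ScanMeta-class] with positive weight and dose.
#' @return A [VolumeGrid-class] with modality \code{"PET_SUV"} on the same
#'   geometry.
#' @examples
#' pet <- VolumeGrid(array(5, c(2, 2, 2)), modality = "PET_KBQ_ML")
#' meta <- ScanMeta(bodyWeightKg = 70, injectedDoseMBq = 350)
#' range(voxelData(computeSUV(pet, meta)))  # SUV 1
#' @export
computeSUV <- function(pet, meta) {
  stopifnot(is(pet, "VolumeGrid"), is(meta, "ScanMeta"))
  if (pet@modality != "PET_KBQ_ML")
    stop("input error: computeSUV expects modality PET_KBQ_ML, got ",
         pet@modality)
  suv <- pet@data * meta@bodyWeightKg / meta@injectedDoseMBq
  VolumeGrid(suv, spacing = pet@spacing, origin = pet@origin,
             modality = "PET_SUV")
}

.physicalExtent <- function(v) {
  # closed physical box covered by the voxel boxes, per axis: (lo, hi)
  d <- dim(v)
  lo <- v@origin - v@spacing / 2
  hi <- v@origin + (d - 1) * v@spacing + v@spacing / 2
  rbind(lo = lo, hi = hi)
}

#' Check CT/PET co-registration geometry
#'
#' Verifies that two volumes describe overlapping physical extents and
#' reports the offset between their physical extent centres. An offset
#' beyond \code{tolMm} raises the misalignment flag; disjoint extents are an
#' error. Different voxel resolutions with matching extents pass, with a
#' note.
#'
#' @param ct,pet [VolumeGrid-class] objects.
#' @param tolMm tolerated centre offset in mm (default 2).
#' @return A list with \code{offsetMm} (numeric(3)), \code{maxOffsetMm},
#'   \code{aligned} (logical), \code{overlapFraction} (of the smaller
#'   extent) and \code{note}.
#' @export
checkRegistration <- function(ct, pet, tolMm = 2) {
  e1 <- .physicalExtent(ct)
  e2 <- .physicalExtent(pet)
  lo <- pmax(e1["lo", ], e2["lo", ])
  hi <- pmin(e1["hi", ], e2["hi", ])
  if (any(hi <= lo))
    stop("registration error: physical extents are disjoint")
  ovl <- prod(hi - lo)
  volMin <- min(prod(e1["hi", ] - e1["lo", ]), prod(e2["hi", ] - e2["lo", ]))
  c1 <- colMeans(e1)
  c2 <- colMeans(e2)
  off <- c2 - c1
  note <- if (any(abs(ct@spacing - pet@spacing) > 1e-9))
    sprintf("different voxel resolutions (CT %s mm vs PET %s mm)",
            paste(format(ct@spacing), collapse = "x"),
            paste(format(pet@spacing), collapse = "x")) else ""
  list(offsetMm = off, maxOffsetMm = max(abs(off)),
       aligned = max(abs(off)) <= tolMm,
       overlapFraction = ovl / volMin, note = note)
}
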