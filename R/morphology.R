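# Binary 3D morphology used by the body mask and the segmentation:
# connected components (compiled kernel), hole filling by background
# labelling, and surface-voxel extraction for distance metrics.

# label connected components of a 0/1 array; returns integer array
labelComponents <- function(arr, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  .label_components(as.double(arr), dim(arr), as.integer(connectivity))
}

# keep only the largest (by voxel count) connected component
largestComponent <- function(arr, connectivity = 26L) {
  lab <- labelComponents(arr, connectivity)
  if (max(lab) == 0L) return(array(0, dim(arr)))
  counts <- tabulate(lab[lab > 0L])
  array(as.double(lab == which.max(counts)), dim(arr))
}

# fill interior cavities: label the complement with 6-connectivity and
# keep as background only the components that touch the array border
fillHoles3d <- function(arr) {
  comp <- array(as.double(arr == 0), dim(arr))
  lab <- labelComponents(comp, 6L)
  border <- borderLabels(lab)
  hole <- arr == 0 & !(lab %in% border)
  out <- arr
  out[hole] <- 1
  out
}

# slice-wise (axial, i.e. per fixed z) 2D hole filling, 4-connectivity
fillHolesSlicewise <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (k in seq_len(d[3])) {
    sl <- array(arr[, , k], c(d[1], d[2], 1L))
    out[, , k] <- fillHoles3d(sl)[, , 1L]
  }
  out
}

borderLabels <- function(lab) {
  d <- dim(lab)
  unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
}

# logical array of mask voxels with at least one 6-neighbour outside the
# mask (voxels on the array border count as surface)
surfaceVoxels <- function(arr) {
  d <- dim(arr)
  inside <- arr > 0
  allNeighboursIn <- array(TRUE, d)
  shiftIn <- function(axis, by) {
    # value of `inside` at the 6-neighbour, FALSE outside the grid
    out <- array(FALSE, d)
    if (axis == 1L) {
      if (by > 0) out[seq_len(d[1] - 1), , ] <- inside[2:d[1], , ]
      else out[2:d[1], , ] <- inside[seq_len(d[1] - 1), , ]
    } else if (axis == 2L) {
      if (by > 0) out[, seq_len(d[2] - 1), ] <- inside[, 2:d[2], ]
      else out[, 2:d[2], ] <- inside[, seq_len(d[2] - 1), ]
    } else {
      if (by > 0) out[, , seq_len(d[3] - 1)] <- inside[, , 2:d[3]]
      else out[, , 2:d[3]] <- inside[, , seq_len(d[3] - 1)]
    }
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L))
    allNeighboursIn <- allNeighboursIn & shiftIn(axis, by)
  inside & !allNeighboursIn
}

# physical (mm) coordinates of the TRUE voxels of a logical array
voxelCoordsMm <- function(logicalArr, spacing, origin) {
  idx <- which(logicalArr, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

#' Delineate the patient body on a CT volume
#'
#' Thresholds the CT, keeps the largest 26-connected component and fills
#' interior cavities (air pockets, lungs on a phantom) in 3D and then per
#' axial slice. This reproduces the standard automatic body delineation
#' on the low-dose CT acquired with the SPECT; counts outside this mask
#' are excluded when scaling Ho-166 images to activity concentration.
#'
#' @param ct a [VoxelGrid] in Hounsfield units (or phantom pseudo-HU).
#' @param thresholdHu voxels strictly above this value are candidate body
#'   voxels; default -500 HU separates tissue from air.
#' @return A [BinaryMask] on the CT grid.
#' @seealso [countsToConcentration()]
#' @export
bodyMask <- function(ct, thresholdHu = -500) {
  stopifnot(is(ct, "VoxelGrid"))
  cand <- ct@values > thresholdHu
  if (!any(cand))
    stop("no voxel above the body threshold: empty body mask", call. = FALSE)
  m <- largestComponent(array(as.double(cand), dim(ct@values)), 26L)
  m <- fillHoles3d(m)
  m <- fillHolesSlicewise(m)
  binaryMask(m, like = ct)
}
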