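#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a scalar 3D NIfTI volume and returns it as a [VoxelGrid].
#' Spacing is taken from the column norms of the stored xform matrix and
#' the origin from its translation column; volumes are assumed
#' axis-aligned (see [VoxelGrid]).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask if `TRUE`, return a [BinaryMask] (values must be 0/1).
#' @return A [VoxelGrid] (or [BinaryMask]).
#' @export
readVolume <- function(path, mask = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  vals <- array(as.double(vals), dim(vals))
  if (length(dim(vals)) == 4L && dim(vals)[4] == 1L)
    vals <- array(vals, dim(vals)[1:3])
  if (length(dim(vals)) != 3L)
    stop("expected a 3D scalar volume, got ",
         length(dim(vals)), " dimensions", call. = FALSE)
  x <- RNifti::xform(img)
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  if (any(spacing <= 0)) spacing <- abs(RNifti::pixdim(img))[1:3]
  origin <- x[1:3, 4]
  storage.mode(vals) <- "double"
  if (mask) binaryMask(vals, spacing, origin)
  else voxelGrid(vals, spacing, origin)
}

#' Write a volume to a NIfTI-1 file
#'
#' Masks are stored as unsigned 8-bit, other volumes as float64, so the
#' read/write round trip is the identity on values, spacing and origin.
#'
#' @param grid a [VoxelGrid] or [BinaryMask].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory
#'   must exist.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(grid, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  dtype <- if (is(grid, "BinaryMask")) "uint8" else "double"
  img <- RNifti::asNifti(grid@values, datatype = dtype)
  attr(img, "pixdim") <- grid@spacing
  img <- RNifti::asNifti(img)
  m <- structure(rbind(cbind(diag(grid@spacing), grid@origin), c(0, 0, 0, 1)),
                 code = 2L)
  img <- RNifti::`sform<-`(img, m)
  RNifti::writeNifti(img, path)
  invisible(path)
}
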