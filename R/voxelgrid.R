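#' Construct a VoxelGrid
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric(3) voxel size in mm (a scalar is recycled).
#' @param origin numeric(3) world position of voxel (1,1,1) in mm.
#' @return A [VoxelGrid].
#' @examples
#' g <- voxelGrid(array(1, c(8, 8, 8)), spacing = 4.8)
#' voxelVolumeMl(g)
#' @export
voxelGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.vector(values)) stop("values must be a 3D array")
  storage.mode(values) <- "double"
  new("VoxelGrid", values = values,
      spacing = as.numeric(rep_len(spacing, 3L)),
      origin = as.numeric(rep_len(origin, 3L)))
}

#' Construct a BinaryMask
#'
#' @param values 3D array of 0/1 (logical arrays are accepted).
#' @param spacing,origin grid geometry, as for [voxelGrid()]; alternatively
#'   pass `like =` an existing grid to copy its geometry.
#' @param like optional [VoxelGrid] whose spacing/origin are reused.
#' @return A [BinaryMask].
#' @export
binaryMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       like = NULL) {
  if (!is.null(like)) {
    spacing <- gridSpacing(like)
    origin <- gridOrigin(like)
  }
  if (is.logical(values)) {
    d <- dim(values)
    values <- array(as.double(values), d)
  }
  storage.mode(values) <- "double"
  new("BinaryMask", values = values,
      spacing = as.numeric(rep_len(spacing, 3L)),
      origin = as.numeric(rep_len(origin, 3L)))
}

#' Grid accessors
#'
#' `gridValues`, `gridSpacing` and `gridOrigin` return the array, the
#' per-axis voxel size (mm) and the world position of the first voxel
#' (mm); `voxelVolumeMl` returns the volume of one voxel in ml
#' (`prod(spacing)/1000`).
#'
#' @param x a [VoxelGrid] (or subclass).
#' @return See description.
#' @rdname gridValues
#' @aliases gridValues gridSpacing gridOrigin voxelVolumeMl
#' @export
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @rdname gridValues
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname gridValues
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @rdname gridValues
#' @export
setMethod("voxelVolumeMl", "VoxelGrid", function(x) prod(x@spacing) / 1000)

#' Volume of a mask in ml
#'
#' Number of 1-voxels times the voxel volume.
#'
#' @param x a [BinaryMask].
#' @return Volume in ml.
#' @rdname maskVolumeMl
#' @export
setMethod("maskVolumeMl", "BinaryMask",
          function(x) sum(x@values) * voxelVolumeMl(x))

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(class(object), sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("| spacing %s mm | origin %s mm\n",
              paste(signif(object@spacing, 4), collapse = " x "),
              paste(signif(object@origin, 4), collapse = ", ")))
  rng <- range(object@values)
  cat(sprintf("  value range [%g, %g]\n", rng[1], rng[2]))
  if (is(object, "BinaryMask"))
    cat(sprintf("  VOI volume %.2f ml (%d voxels)\n",
                maskVolumeMl(object), as.integer(sum(object@values))))
})

#' Compare the geometry of two grids
#'
#' All voxelwise operations in the pipeline require their operands on one
#' common grid (the dual-isotope volumes are intrinsically registered).
#' This check compares shapes exactly and spacing/origin within a
#' tolerance (default 1e-6 mm, header round-off).
#'
#' @param a,b [VoxelGrid] objects.
#' @param tolMm tolerance in mm for spacing and origin.
#' @return A [GridMismatchReport]; query it with [isCompatible()].
#' @examples
#' g <- voxelGrid(array(0, c(4, 4, 4)))
#' isCompatible(checkSameGrid(g, g))
#' @export
checkSameGrid <- function(a, b, tolMm = 1e-6) {
  compatible <- identical(dim(a@values), dim(b@values)) &&
    all(abs(a@spacing - b@spacing) <= tolMm) &&
    all(abs(a@origin - b@origin) <= tolMm)
  new("GridMismatchReport",
      shapeA = dim(a@values), shapeB = dim(b@values),
      spacingA = a@spacing, spacingB = b@spacing,
      originA = a@origin, originB = b@origin,
      spacingTolMm = tolMm, compatible = compatible)
}

#' @rdname isCompatible
#' @param x a [GridMismatchReport].
#' @return `isCompatible` returns a logical flag.
#' @export
setMethod("isCompatible", "GridMismatchReport", function(x) x@compatible)

setMethod("show", "GridMismatchReport", function(object) {
  cat("GridMismatchReport:",
      if (object@compatible) "compatible\n" else "INCOMPATIBLE\n")
  cat(sprintf("  shape   %s vs %s\n", paste(object@shapeA, collapse = "x"),
              paste(object@shapeB, collapse = "x")))
  cat(sprintf("  spacing %s vs %s mm\n",
              paste(signif(object@spacingA, 6), collapse = "x"),
              paste(signif(object@spacingB, 6), collapse = "x")))
  cat(sprintf("  origin  %s vs %s mm\n",
              paste(signif(object@originA, 6), collapse = ","),
              paste(signif(object@originB, 6), collapse = ",")))
})

# internal: stop unless two grids share a geometry
assertSameGrid <- function(a, b, what = "volumes") {
  rep <- checkSameGrid(a, b)
  if (!rep@compatible)
    stop("grid mismatch: ", what, " must share shape, spacing and origin",
         call. = FALSE)
  invisible(TRUE)
}
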