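#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib duodose, .registration = TRUE
NULL

#' VoxelGrid: a 3D scalar volume with physical geometry
#'
#' The substrate for all images handled by the package: a 3D array of
#' scalar values together with the physical voxel size (mm per axis) and
#' the physical position of the first voxel. Arrays are indexed (x, y, z)
#' and assumed axis-aligned: the world coordinate of voxel (i, j, k)
#' (1-based) is \code{origin + (c(i, j, k) - 1) * spacing}. No orientation
#' matrix is supported; dual-isotope SPECT/CT volumes are co-acquired on a
#' common grid and phantom volumes are generated on one.
#'
#' @slot values numeric 3D array; all values must be finite.
#' @slot spacing numeric(3), voxel size in mm per axis; strictly positive.
#' @slot origin numeric(3), world position (mm) of voxel (1, 1, 1).
#'
#' @seealso [voxelGrid()], [readVolume()], [writeVolume()]
#' @export
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (mm)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a volume of interest on a voxel grid
#'
#' A [VoxelGrid] whose values are restricted to \{0, 1\}; the set of
#' 1-voxels defines a volume of interest (VOI) such as the liver, the
#' healthy-liver parenchyma, a tumor, or the patient body.
#'
#' @seealso [binaryMask()], [maskVolumeMl()]
#' @export
setClass("BinaryMask", contains = "VoxelGrid")

setValidity("BinaryMask", function(object) {
  v <- object@values
  if (!all(v == 0 | v == 1))
    return("mask values must be 0 or 1 only")
  TRUE
})

#' DoseImage: per-voxel absorbed dose in Gy
#'
#' A [VoxelGrid] holding nonnegative absorbed dose values in gray,
#' produced by [doseFromConcentration()].
#'
#' @export
setClass("DoseImage", contains = "VoxelGrid")

setValidity("DoseImage", function(object) {
  if (any(object@values < 0))
    return("dose values must be nonnegative")
  TRUE
})

#' GridMismatchReport: result of comparing two grids
#'
#' Records the shapes, spacings and origins of two grids plus a single
#' `compatible` flag. Two grids are compatible iff the array shapes are
#' identical and spacing and origin agree within 1e-6 mm (header
#' round-off tolerance).
#'
#' @slot shapeA,shapeB integer(3) array dimensions.
#' @slot spacingA,spacingB,spacingTolMm numeric, mm.
#' @slot originA,originB numeric(3), mm.
#' @slot compatible logical(1).
#' @seealso [checkSameGrid()]
#' @export
setClass("GridMismatchReport",
  representation(shapeA = "integer", shapeB = "integer",
                 spacingA = "numeric", spacingB = "numeric",
                 originA = "numeric", originB = "numeric",
                 spacingTolMm = "numeric", compatible = "logical"))

#' DVHCurve: cumulative dose-volume histogram
#'
#' For each dose edge d (ascending, starting at 0 Gy) stores the fraction
#' of the VOI receiving at least d. The curve starts at 1 and is
#' non-increasing.
#'
#' @slot doseEdges numeric, ascending dose edges in Gy, first edge 0.
#' @slot volumeFraction numeric in [0, 1], same length as `doseEdges`.
#' @seealso [cumulativeDvh()], [dMetric()], [vMetric()]
#' @export
setClass("DVHCurve",
  representation(doseEdges = "numeric", volumeFraction = "numeric"))

setValidity("DVHCurve", function(object) {
  msg <- character()
  if (length(object@doseEdges) != length(object@volumeFraction))
    msg <- c(msg, "doseEdges and volumeFraction must have equal length")
  if (is.unsorted(object@doseEdges, strictly = TRUE))
    msg <- c(msg, "doseEdges must be strictly ascending")
  if (length(object@doseEdges) && object@doseEdges[1] != 0)
    msg <- c(msg, "first dose edge must be 0")
  vf <- object@volumeFraction
  if (any(vf < 0 | vf > 1))
    msg <- c(msg, "volume fractions must lie in [0, 1]")
  if (length(vf) && vf[1] != 1)
    msg <- c(msg, "volume fraction at dose 0 must be 1")
  if (any(diff(vf) > 1e-12))
    msg <- c(msg, "volume fraction must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' BlandAltmanSummary: paired-difference agreement statistics
#'
#' Differences are taken as automatic minus manual (test minus reference).
#' The coefficient of reproducibility is 1.96 times the sample SD of the
#' paired differences; the limits of agreement are mean +/- CoR.
#'
#' @slot n integer, number of pairs.
#' @slot meanDifference,sdDifference numeric, in the metric's units.
#' @slot coefficientOfReproducibility numeric, 1.96 * sdDifference.
#' @slot upperLimit,lowerLimit numeric, limits of agreement.
#' @seealso [blandAltman()]
#' @export
setClass("BlandAltmanSummary",
  representation(n = "integer", meanDifference = "numeric",
                 sdDifference = "numeric",
                 coefficientOfReproducibility = "numeric",
                 upperLimit = "numeric", lowerLimit = "numeric"))

setValidity("BlandAltmanSummary", function(object) {
  msg <- character()
  if (object@coefficientOfReproducibility < 0)
    msg <- c(msg, "coefficient of reproducibility must be nonnegative")
  if (object@upperLimit < object@meanDifference ||
      object@meanDifference < object@lowerLimit)
    msg <- c(msg, "limits of agreement must bracket the mean difference")
  if (length(msg)) msg else TRUE
})

#' SegmentationConfig: parameters of the automatic healthy-liver method
#'
#' The automatic segmentation thresholds the original (spleen-removed)
#' Tc-99m image at `thresholdFraction` of the maximum of a Gaussian
#' smoothed copy. `spleenStrategy` selects how the Tc-avid spleen is
#' removed before the maximum is taken: with a user-provided mask
#' (`"provided_mask"`) or by keeping only the largest connected
#' high-uptake region (`"largest_component"`). Components of the final
#' mask smaller than `minComponentMl` are discarded; set 0 to disable.
#'
#' @seealso [segmentationConfig()], [automaticHealthyMask()]
#' @export
setClass("SegmentationConfig",
  representation(thresholdFraction = "numeric", smoothingFwhmMm = "numeric",
                 spleenStrategy = "character", minComponentMl = "numeric"))

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (object@thresholdFraction <= 0 || object@thresholdFraction >= 1)
    msg <- c(msg, "thresholdFraction must lie in (0, 1)")
  if (object@smoothingFwhmMm < 0)
    msg <- c(msg, "smoothingFwhmMm must be nonnegative")
  if (!object@spleenStrategy %in% c("provided_mask", "largest_component"))
    msg <- c(msg, "spleenStrategy must be 'provided_mask' or 'largest_component'")
  if (object@minComponentMl < 0)
    msg <- c(msg, "minComponentMl must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' DosimetryConfig: constants of the local-deposition dose model
#'
#' Absorbed dose is computed as
#' `energyPerActivity * concentration / tissueDensity`, i.e.
#' (mJ/MBq)(MBq/ml)/(g/ml) = mJ/g = Gy. The default 15.87 mJ/MBq is the
#' energy deposited by the beta decay of 1 MBq of Ho-166; the default
#' density 1.06 g/ml is soft tissue, assumed homogeneous.
#'
#' @seealso [dosimetryConfig()], [doseFromConcentration()]
#' @export
setClass("DosimetryConfig",
  representation(energyPerActivity = "numeric", tissueDensity = "numeric"))

setValidity("DosimetryConfig", function(object) {
  if (object@energyPerActivity <= 0 || object@tissueDensity <= 0)
    return("energyPerActivity and tissueDensity must be strictly positive")
  TRUE
})

#' PhantomSpec: geometry and simulation settings of the digital phantom
#'
#' Describes an abdominal phantom for the dual-isotope protocol: a liver
#' built from two overlapping ellipsoids, one spleen ellipsoid, spherical
#' tumors (optionally with a necrotic core), plus uptake ratios, SPECT
#' resolution/count settings and the rigid misregistration applied to the
#' manual-reference arm. All coordinates and sizes are in mm (world
#' coordinates, see [VoxelGrid]).
#'
#' @slot shape integer(3) grid dimensions.
#' @slot spacing numeric(3), voxel size mm.
#' @slot origin numeric(3), mm.
#' @slot liverCenters,liverSemiAxes 2x3 matrices, mm: the two liver ellipsoids.
#' @slot spleenCenter,spleenSemiAxes numeric(3), mm.
#' @slot tumors data.frame with columns cx, cy, cz, diameter_mm,
#'   necrosis_diameter_mm (NA for none); zero rows for a tumor-free liver.
#' @slot tcSpleenToLiverRatio numeric, Tc-99m concentration ratio spleen:liver.
#' @slot hoTumorToNormalRatio numeric, Ho-166 concentration ratio tumor:healthy.
#' @slot psfFwhmMm numeric, FWHM of the Gaussian SPECT point-spread model.
#' @slot tcTotalCounts,hoTotalCounts numeric, expected total counts per isotope.
#' @slot administeredActivityMBq numeric, Ho-166 activity (MBq).
#' @slot tcActivityMBq numeric, Tc-99m activity (MBq).
#' @slot misregTranslationMm numeric(3), mm.
#' @slot misregRotationDegZ numeric, degrees about z.
#' @slot seed integer master seed; per-stage seeds are derived from it.
#'
#' @seealso [phantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", origin = "numeric",
                 liverCenters = "matrix", liverSemiAxes = "matrix",
                 spleenCenter = "numeric", spleenSemiAxes = "numeric",
                 tumors = "data.frame",
                 tcSpleenToLiverRatio = "numeric",
                 hoTumorToNormalRatio = "numeric",
                 psfFwhmMm = "numeric",
                 tcTotalCounts = "numeric", hoTotalCounts = "numeric",
                 administeredActivityMBq = "numeric",
                 tcActivityMBq = "numeric",
                 misregTranslationMm = "numeric",
                 misregRotationDegZ = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 4L))
    msg <- c(msg, "shape must be 3 integers >= 4")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (object@tcSpleenToLiverRatio < 0 || object@hoTumorToNormalRatio < 0)
    msg <- c(msg, "uptake ratios must be nonnegative")
  if (object@psfFwhmMm < 0) msg <- c(msg, "psfFwhmMm must be nonnegative")
  if (object@tcTotalCounts <= 0 || object@hoTotalCounts <= 0)
    msg <- c(msg, "total counts must be positive")
  if (object@administeredActivityMBq <= 0)
    msg <- c(msg, "administeredActivityMBq must be positive")
  need <- c("cx", "cy", "cz", "diameter_mm", "necrosis_diameter_mm")
  if (!all(need %in% names(object@tumors)))
    msg <- c(msg, "tumors must have columns cx, cy, cz, diameter_mm, necrosis_diameter_mm")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: a generated phantom with its ground truth
#'
#' Everything the downstream pipeline needs, plus the noiseless truth it
#' is judged against: activity-concentration maps (MBq/ml), a pseudo-CT
#' (0 HU body in -1000 HU air), all truth masks, and the analytic mean
#' absorbed dose in the true healthy-liver VOI.
#'
#' @slot hoActivity,tcActivity [VoxelGrid], noiseless MBq/ml.
#' @slot ct [VoxelGrid], pseudo-HU.
#' @slot masks named list of [BinaryMask]: liver, spleen, tumors, necrosis,
#'   healthyTruth (= liver - tumors - necrosis), body.
#' @slot administeredActivityMBq numeric, MBq.
#' @slot trueMeanDoseGy numeric, analytic mean dose in healthyTruth (Gy),
#'   using the default dosimetry constants.
#' @slot spec the generating [PhantomSpec].
#' @seealso [makePhantom()]
#' @export
setClass("PhantomTruth",
  representation(hoActivity = "VoxelGrid", tcActivity = "VoxelGrid",
                 ct = "VoxelGrid", masks = "list",
                 administeredActivityMBq = "numeric",
                 trueMeanDoseGy = "numeric", spec = "PhantomSpec"))
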