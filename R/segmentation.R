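# Automatic healthy-liver segmentation on the Tc-99m image and the
# manual-reference healthy-VOI construction.

#' Construct a SegmentationConfig
#'
#' @param thresholdFraction fraction of the smoothed-image maximum used
#'   as the absolute threshold; default 0.40.
#' @param smoothingFwhmMm FWHM (mm) of the Gaussian used to stabilise the
#'   maximum; default 10.
#' @param spleenStrategy `"largest_component"` (default) or
#'   `"provided_mask"`; see [removeSpleen()].
#' @param minComponentMl connected components of the thresholded mask
#'   smaller than this are discarded (noise islands); 0 disables.
#' @return A [SegmentationConfig].
#' @export
segmentationConfig <- function(thresholdFraction = 0.40,
                               smoothingFwhmMm = 10,
                               spleenStrategy = c("largest_component",
                                                  "provided_mask"),
                               minComponentMl = 1.0) {
  new("SegmentationConfig",
      thresholdFraction = thresholdFraction,
      smoothingFwhmMm = smoothingFwhmMm,
      spleenStrategy = match.arg(spleenStrategy),
      minComponentMl = minComponentMl)
}

#' Remove the spleen from a Tc-99m count image
#'
#' Tc-99m stannous-phytate also accumulates in the spleen, which would
#' otherwise contaminate the healthy-liver segmentation (and, if hot
#' enough, set the threshold level). Two strategies:
#' \describe{
#'   \item{provided_mask}{zero all voxels inside `spleenMask`.}
#'   \item{largest_component}{compute a provisional segmentation (smooth,
#'     threshold at `thresholdFraction` of the smoothed maximum,
#'     26-connected components) and zero the count image inside every
#'     component except the largest by volume — the liver being the
#'     largest Tc-avid organ.}
#' }
#'
#' @param tcCounts a nonnegative [VoxelGrid] of Tc-99m counts.
#' @param config a [SegmentationConfig].
#' @param spleenMask a [BinaryMask], required for `provided_mask`.
#' @return A [VoxelGrid] on the same grid with spleen counts zeroed.
#' @export
removeSpleen <- function(tcCounts, config = segmentationConfig(),
                         spleenMask = NULL) {
  stopifnot(is(tcCounts, "VoxelGrid"))
  if (any(tcCounts@values < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (config@spleenStrategy == "provided_mask") {
    if (is.null(spleenMask))
      stop("spleenStrategy 'provided_mask' requires a spleen mask",
           call. = FALSE)
    assertSameGrid(tcCounts, spleenMask, "counts and spleen mask")
    vals <- tcCounts@values
    vals[spleenMask@values > 0] <- 0
    return(voxelGrid(vals, tcCounts@spacing, tcCounts@origin))
  }
  smoothed <- gaussianSmooth(tcCounts, config@smoothingFwhmMm)@values
  thr <- config@thresholdFraction * max(smoothed)
  lab <- labelComponents(array(as.double(smoothed >= thr), dim(smoothed)), 26L)
  k <- max(lab)
  if (k <= 1L) return(tcCounts)
  counts <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which.max(counts)
  vals <- tcCounts@values
  vals[lab > 0L & lab != keep] <- 0
  voxelGrid(vals, tcCounts@spacing, tcCounts@origin)
}

#' Automatic healthy-liver segmentation from the Tc-99m image
#'
#' The threshold method of the dual-isotope protocol: after spleen
#' removal, the maximum value of a Gaussian-smoothed copy of the Tc-99m
#' image is determined, and the original (unsmoothed, spleen-removed)
#' image is thresholded at `thresholdFraction` (default 40 percent) of
#' that maximum. Because the Tc-99m SPECT is intrinsically registered to
#' the Ho-166 SPECT, no registration step is required and the mask lives
#' on the input grid. Components smaller than `minComponentMl` are
#' discarded as noise islands.
#'
#' The threshold is relative, so the result is invariant to positive
#' rescaling of the count image.
#'
#' @inheritParams removeSpleen
#' @return A [BinaryMask]: the automatically segmented healthy liver.
#' @examples
#' cfg <- segmentationConfig(smoothingFwhmMm = 0)
#' v <- array(0, c(12, 12, 12)); v[4:9, 4:9, 4:9] <- 100
#' m <- automaticHealthyMask(voxelGrid(v, spacing = 4), cfg)
#' maskVolumeMl(m)  # the full uniform cube survives the 40% threshold
#' @export
automaticHealthyMask <- function(tcCounts, config = segmentationConfig(),
                                 spleenMask = NULL) {
  stopifnot(is(tcCounts, "VoxelGrid"))
  if (all(tcCounts@values == 0))
    stop("all-zero count image: nothing to segment", call. = FALSE)
  cleaned <- removeSpleen(tcCounts, config, spleenMask)
  smoothed <- gaussianSmooth(cleaned, config@smoothingFwhmMm)@values
  M <- max(smoothed)
  if (M <= 0)
    stop("smoothed image has no positive values", call. = FALSE)
  mask <- array(as.double(cleaned@values >= config@thresholdFraction * M),
                dim(cleaned@values))
  if (config@minComponentMl > 0 && any(mask > 0)) {
    lab <- labelComponents(mask, 26L)
    vv <- prod(tcCounts@spacing) / 1000
    sizesMl <- tabulate(lab[lab > 0L]) * vv
    drop <- which(sizesMl < config@minComponentMl)
    if (length(drop)) mask[lab %in% drop] <- 0
  }
  binaryMask(mask, like = tcCounts)
}

#' Manual-reference healthy-liver VOI
#'
#' The reference-standard construction: healthy liver = total liver minus
#' the union of (retained) tumors minus necrotic tissue. Tumors are
#' retained only if larger than `minTumorDiameterMm` (default 10 mm, the
#' 1 cm clinical rule); size is judged by the equivalent-sphere diameter
#' of the mask, \eqn{2 (3V/4\pi)^{1/3}}.
#'
#' @param liver a [BinaryMask] of the whole liver.
#' @param tumors a list of [BinaryMask] (possibly empty), one per tumor.
#' @param necrosis an optional [BinaryMask] of necrotic tissue.
#' @param minTumorDiameterMm tumors at or below this equivalent diameter
#'   are ignored.
#' @return A [BinaryMask]: liver minus retained tumors minus necrosis.
#' @export
referenceHealthyMask <- function(liver, tumors = list(), necrosis = NULL,
                                 minTumorDiameterMm = 10) {
  stopifnot(is(liver, "BinaryMask"))
  out <- liver@values
  for (tm in tumors) {
    assertSameGrid(liver, tm, "liver and tumor masks")
    volMm3 <- sum(tm@values) * prod(tm@spacing)
    eqDiam <- 2 * (3 * volMm3 / (4 * pi))^(1 / 3)
    if (eqDiam > minTumorDiameterMm)
      out[tm@values > 0] <- 0
  }
  if (!is.null(necrosis)) {
    assertSameGrid(liver, necrosis, "liver and necrosis masks")
    out[necrosis@values > 0] <- 0
  }
  binaryMask(out, like = liver)
}
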