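# Local-deposition voxel dosimetry for Ho-166 and DVH metrics.

#' Construct a DosimetryConfig
#'
#' @param energyPerActivity deposited beta energy per unit activity,
#'   mJ/MBq; default 15.87 for Ho-166.
#' @param tissueDensity soft-tissue density, g/ml; default 1.06, assumed
#'   homogeneous across the organ and across patients.
#' @return A [DosimetryConfig].
#' @export
dosimetryConfig <- function(energyPerActivity = 15.87, tissueDensity = 1.06) {
  new("DosimetryConfig", energyPerActivity = energyPerActivity,
      tissueDensity = tissueDensity)
}

#' Scale a Ho-166 count image to activity concentration
#'
#' Converts counts to MBq/ml under the assumption that all administered
#' activity is in the SPECT field of view: only counts inside the
#' patient-body mask are considered, and the count image is scaled so the
#' activity integrated over the body equals the administered activity.
#' Voxels outside the body are set to zero.
#'
#' @param hoCounts a nonnegative [VoxelGrid] of Ho-166 counts.
#' @param body a nonempty [BinaryMask] (see [bodyMask()]).
#' @param activityMBq administered activity in MBq (for pre-treatment
#'   scans of partial treatments, see [pretreatmentActivity()]).
#' @return A [VoxelGrid] in MBq/ml whose integral over the body equals
#'   `activityMBq`.
#' @export
countsToConcentration <- function(hoCounts, body, activityMBq) {
  stopifnot(is(hoCounts, "VoxelGrid"), is(body, "BinaryMask"))
  assertSameGrid(hoCounts, body, "counts and body mask")
  if (any(hoCounts@values < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (sum(body@values) == 0) stop("empty body mask", call. = FALSE)
  if (activityMBq <= 0) stop("activityMBq must be positive", call. = FALSE)
  inBody <- body@values > 0
  tot <- sum(hoCounts@values[inBody])
  if (tot == 0)
    stop("no counts inside the body mask", call. = FALSE)
  vv <- voxelVolumeMl(hoCounts)
  conc <- array(0, dim(hoCounts@values))
  conc[inBody] <- activityMBq * hoCounts@values[inBody] / tot / vv
  voxelGrid(conc, hoCounts@spacing, hoCounts@origin)
}

#' Activity to use when scaling a pre-treatment image
#'
#' Whole-liver treatments are scaled by the activity of the single
#' procedure. Patients treated in complementary partial sessions (e.g.
#' left and right lobe) share a `partial_treatment_group`; their
#' pre-treatment image is scaled by the summed activity of the group.
#'
#' @param records a data.frame with columns `administered_activity_MBq`
#'   and optionally `partial_treatment_group` (NA for non-partial).
#' @return Total activity in MBq.
#' @examples
#' pretreatmentActivity(data.frame(administered_activity_MBq = 3850))
#' pretreatmentActivity(data.frame(administered_activity_MBq = c(2000, 3000),
#'                                 partial_treatment_group = "p1"))
#' @export
pretreatmentActivity <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("at least one treatment record is required", call. = FALSE)
  act <- records$administered_activity_MBq
  if (is.null(act) || any(act <= 0))
    stop("records need positive administered_activity_MBq", call. = FALSE)
  if (nrow(records) == 1L) return(act)
  grp <- records$partial_treatment_group
  if (is.null(grp) || anyNA(grp) || length(unique(grp)) != 1L)
    stop("multiple records must share one partial_treatment_group",
         call. = FALSE)
  sum(act)
}

#' Absorbed dose from activity concentration
#'
#' The local-deposition model: each voxel's dose is proportional to its
#' activity concentration,
#' \deqn{D\,[\mathrm{Gy}] = E \left[\frac{\mathrm{mJ}}{\mathrm{MBq}}\right]
#'   \frac{C\,[\mathrm{MBq/ml}]}{\rho\,[\mathrm{g/ml}]},}
#' with E = 15.87 mJ/MBq (Ho-166 beta decay) and density 1.06 g/ml by
#' default; (mJ/MBq)(MBq/ml)/(g/ml) = mJ/g = Gy.
#'
#' @param conc a nonnegative [VoxelGrid] in MBq/ml.
#' @param config a [DosimetryConfig].
#' @return A [DoseImage] in Gy.
#' @export
doseFromConcentration <- function(conc, config = dosimetryConfig()) {
  stopifnot(is(conc, "VoxelGrid"))
  if (any(conc@values < 0))
    stop("concentration must be nonnegative", call. = FALSE)
  new("DoseImage",
      values = config@energyPerActivity * conc@values / config@tissueDensity,
      spacing = conc@spacing, origin = conc@origin)
}

voiDoses <- function(dose, voi) {
  stopifnot(is(dose, "DoseImage"), is(voi, "BinaryMask"))
  assertSameGrid(dose, voi, "dose and VOI")
  if (sum(voi@values) == 0) stop("empty VOI", call. = FALSE)
  dose@values[voi@values > 0]
}

#' Mean absorbed dose in a VOI
#'
#' @param dose a [DoseImage].
#' @param voi a nonempty [BinaryMask] on the same grid.
#' @return Mean dose in Gy.
#' @export
meanDose <- function(dose, voi) mean(voiDoses(dose, voi))

#' Cumulative dose-volume histogram
#'
#' For each dose edge d (0, binWidthGy, 2 binWidthGy, ...) the fraction
#' of the VOI receiving at least d Gy.
#'
#' @inheritParams meanDose
#' @param binWidthGy dose bin width in Gy; default 0.1.
#' @return A [DVHCurve].
#' @export
cumulativeDvh <- function(dose, voi, binWidthGy = 0.1) {
  if (binWidthGy <= 0) stop("binWidthGy must be positive", call. = FALSE)
  dv <- voiDoses(dose, voi)
  edges <- seq(0, max(dv) + binWidthGy, by = binWidthGy)
  frac <- vapply(edges, function(d) mean(dv >= d), numeric(1))
  new("DVHCurve", doseEdges = edges, volumeFraction = frac)
}

#' Minimum dose to the hottest fraction of a VOI (D metric)
#'
#' `dMetric(dose, voi, 0.70)` is D70: the minimum dose received by the
#' 70 percent of the VOI with the highest doses, i.e. the 30th percentile
#' of the voxel-dose distribution. Quantiles use linear interpolation
#' between order statistics (R quantile type 7), so results are
#' bit-reproducible.
#'
#' @inheritParams meanDose
#' @param volumeFraction f in (0, 1); D_f is the (1 - f) quantile.
#' @return Dose in Gy.
#' @export
dMetric <- function(dose, voi, volumeFraction) {
  if (volumeFraction <= 0 || volumeFraction >= 1)
    stop("volumeFraction must lie in (0, 1)", call. = FALSE)
  dv <- voiDoses(dose, voi)
  unname(stats::quantile(dv, probs = 1 - volumeFraction, type = 7))
}

#' Fraction of a VOI receiving at least a dose (V metric)
#'
#' `vMetric(dose, voi, 50)` is V50: the percentage of the VOI receiving
#' at least 50 Gy.
#'
#' @inheritParams meanDose
#' @param doseThresholdGy nonnegative dose threshold, Gy.
#' @return Percentage in [0, 100].
#' @export
vMetric <- function(dose, voi, doseThresholdGy) {
  if (doseThresholdGy < 0)
    stop("doseThresholdGy must be nonnegative", call. = FALSE)
  dv <- voiDoses(dose, voi)
  100 * mean(dv >= doseThresholdGy)
}

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve: %d edges, 0 to %.2f Gy\n",
              length(object@doseEdges), max(object@doseEdges)))
})

#' Export a DVH curve as a data.frame
#'
#' @param x a [DVHCurve].
#' @param ... ignored.
#' @return A data.frame with columns `dose_gy` and `volume_fraction`.
#' @export
as.data.frame.DVHCurve <- function(x, ...) {
  data.frame(dose_gy = x@doseEdges, volume_fraction = x@volumeFraction)
}
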