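# End-to-end orchestration of the two segmentation arms: the manual
# reference (truth masks rigidly misregistered) versus the automatic
# Tc-99m threshold segmentation, both evaluated against the same Ho-166
# dose map.

#' Run one manual-vs-automatic comparison on a phantom
#'
#' Executes the full workflow on a synthetic acquisition:
#' \enumerate{
#'   \item simulate Tc-99m and Ho-166 SPECT count volumes from the
#'     phantom truth ([simulateSpect()], stage seeds 1 and 2);
#'   \item delineate the body on the pseudo-CT ([bodyMask()]);
#'   \item automatic arm: [automaticHealthyMask()] on the Tc image;
#'   \item manual arm: [referenceHealthyMask()] from the truth masks,
#'     then [perturbMask()] with the spec's misregistration (stage 3) to
#'     emulate the residual CECT-to-SPECT registration error;
#'   \item scale Ho counts to MBq/ml ([countsToConcentration()]) and
#'     convert to dose ([doseFromConcentration()]);
#'   \item mean dose, D70, V50 and the DVH per arm; Dice, Hausdorff and
#'     volume difference between the arms; an energy-conservation check
#'     over the body.
#' }
#' Fully reproducible for a fixed spec (which carries the seed).
#'
#' @param spec a [PhantomSpec].
#' @param segConfig a [SegmentationConfig].
#' @param dosConfig a [DosimetryConfig].
#' @param outdir optional directory; when given, masks and the dose map
#'   are written as NIfTI, the two DVHs as CSV, and the report as
#'   `report.json`.
#' @param dvhBinWidthGy DVH bin width, Gy.
#' @return A list report (also serialised when `outdir` is set) with the
#'   per-arm dose metrics, the agreement indices, the threshold used, and
#'   the energy-conservation residual.
#' @export
runComparison <- function(spec = phantomSpec(),
                          segConfig = segmentationConfig(),
                          dosConfig = dosimetryConfig(),
                          outdir = NULL, dvhBinWidthGy = 0.1) {
  truth <- makePhantom(spec)

  tcCounts <- simulateSpect(truth@tcActivity, spec@psfFwhmMm,
                            spec@tcTotalCounts, stageSeed(spec@seed, 1))
  hoCounts <- simulateSpect(truth@hoActivity, spec@psfFwhmMm,
                            spec@hoTotalCounts, stageSeed(spec@seed, 2))

  body <- bodyMask(truth@ct)

  autoMask <- automaticHealthyMask(tcCounts, segConfig,
                                   spleenMask = NULL)

  manualMask <- truth@masks$healthyTruth
  if (any(spec@misregTranslationMm != 0) || spec@misregRotationDegZ != 0)
    manualMask <- perturbMask(manualMask, spec@misregTranslationMm,
                              spec@misregRotationDegZ,
                              stageSeed(spec@seed, 3))

  conc <- countsToConcentration(hoCounts, body, spec@administeredActivityMBq)
  dose <- doseFromConcentration(conc, dosConfig)

  # energy conservation over the body: sum(dose * mass) = E * A
  vv <- voxelVolumeMl(dose)
  massKg <- vv * dosConfig@tissueDensity / 1000
  energyJ <- sum(dose@values[body@values > 0]) * massKg
  expectedJ <- dosConfig@energyPerActivity / 1000 * spec@administeredActivityMBq
  energyResidual <- abs(energyJ - expectedJ) / expectedJ
  if (energyResidual > 1e-6)
    stop("energy conservation violated: relative residual ",
         format(energyResidual), call. = FALSE)

  armMetrics <- function(voi) {
    list(mean_dose_gy = meanDose(dose, voi),
         d70_gy = dMetric(dose, voi, 0.70),
         v50_pct = vMetric(dose, voi, 50),
         volume_ml = maskVolumeMl(voi))
  }
  report <- list(
    schema = "duodose-comparison-1",
    seed = spec@seed,
    administered_activity_MBq = spec@administeredActivityMBq,
    threshold_fraction = segConfig@thresholdFraction,
    manual = armMetrics(manualMask),
    automatic = armMetrics(autoMask),
    agreement = list(
      dice = diceCoefficient(autoMask, manualMask),
      hausdorff_cm = hausdorffDistance(autoMask, manualMask),
      volume_difference_ml = volumeDifference(autoMask, manualMask),
      mean_dose_difference_gy =
        meanDose(dose, autoMask) - meanDose(dose, manualMask)),
    dice_vs_truth = diceCoefficient(autoMask, truth@masks$healthyTruth),
    true_mean_dose_gy = truth@trueMeanDoseGy,
    energy_conservation_residual = energyResidual)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    maskDir <- file.path(outdir, "masks")
    doseDir <- file.path(outdir, "dose")
    dir.create(maskDir, showWarnings = FALSE)
    dir.create(doseDir, showWarnings = FALSE)
    writeVolume(autoMask, file.path(maskDir, "healthy_automatic.nii.gz"))
    writeVolume(manualMask, file.path(maskDir, "healthy_manual.nii.gz"))
    writeVolume(body, file.path(maskDir, "body.nii.gz"))
    writeVolume(dose, file.path(doseDir, "dose_gy.nii.gz"))
    utils::write.csv(
      as.data.frame(cumulativeDvh(dose, manualMask, dvhBinWidthGy)),
      file.path(outdir, "dvh_manual.csv"), row.names = FALSE)
    utils::write.csv(
      as.data.frame(cumulativeDvh(dose, autoMask, dvhBinWidthGy)),
      file.path(outdir, "dvh_auto.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Run a cohort of comparisons and aggregate paired statistics
#'
#' Runs [runComparison()] for each spec and aggregates the paired
#' per-arm metrics (mean dose, D70, V50) into Bland-Altman summaries,
#' Pearson correlations and two-sided paired t tests, mirroring a
#' clinical cohort analysis. An optional toxicity table is summarised
#' with [toxicitySummary()]. A zero-variance paired t test (identical
#' arms in every run) is reported as NA with a note rather than
#' propagating an error.
#'
#' @param specs a list of [PhantomSpec] objects (>= 2 for paired
#'   statistics).
#' @param toxicity optional data.frame for [toxicitySummary()].
#' @param segConfig,dosConfig shared configurations.
#' @return A list with `runs` (per-run reports), `metrics` (per metric:
#'   `blandAltman`, `pearson_r`, `t_test`), and optionally `toxicity`.
#' @export
runCohort <- function(specs, toxicity = NULL,
                      segConfig = segmentationConfig(),
                      dosConfig = dosimetryConfig()) {
  if (length(specs) < 2)
    stop("at least two runs are required for paired statistics",
         call. = FALSE)
  runs <- lapply(specs, runComparison, segConfig = segConfig,
                 dosConfig = dosConfig)
  pull <- function(arm, field)
    vapply(runs, function(r) r[[arm]][[field]], numeric(1))
  metricFields <- c(mean_dose_gy = "mean_dose_gy", d70_gy = "d70_gy",
                    v50_pct = "v50_pct")
  metrics <- lapply(metricFields, function(field) {
    a <- pull("automatic", field)
    m <- pull("manual", field)
    tt <- tryCatch(pairedTTest(a, m), error = function(e)
      list(t = NA_real_, df = NA_integer_, p = NA_real_,
           note = conditionMessage(e)))
    r <- tryCatch(pearsonR(a, m), error = function(e) NA_real_)
    list(blandAltman = blandAltman(a, m), pearson_r = r, t_test = tt)
  })
  out <- list(runs = runs, metrics = metrics)
  if (!is.null(toxicity)) out$toxicity <- toxicitySummary(toxicity)
  out
}
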