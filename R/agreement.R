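# Mask-agreement indices and paired cohort statistics used to compare
# the automatic segmentation against the manual reference.

#' Sorensen-Dice coefficient of two masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; symmetric, 1 for identical masks,
#' 0 for disjoint ones.
#'
#' @param a,b [BinaryMask] objects on the same grid, not both empty.
#' @return A number in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  assertSameGrid(a, b, "masks")
  na <- sum(a@values); nb <- sum(b@values)
  if (na + nb == 0)
    stop("both masks are empty", call. = FALSE)
  2 * sum(a@values * b@values) / (na + nb)
}

#' Hausdorff distance between two masks, in cm
#'
#' Classical symmetric Hausdorff distance
#' \eqn{\max(h(A,B),\, h(B,A))} with
#' \eqn{h(A,B) = \max_{a \in \partial A} \min_{b \in \partial B} \|a-b\|}
#' over surface voxels (6-connectivity boundary), with Euclidean
#' distances in physical mm (anisotropic spacing respected), reported in
#' cm.
#'
#' @param a,b nonempty [BinaryMask] objects on the same grid.
#' @return Distance in cm.
#' @export
hausdorffDistance <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  assertSameGrid(a, b, "masks")
  if (sum(a@values) == 0 || sum(b@values) == 0)
    stop("Hausdorff distance needs two nonempty masks", call. = FALSE)
  pa <- voxelCoordsMm(surfaceVoxels(a@values), a@spacing, a@origin)
  pb <- voxelCoordsMm(surfaceVoxels(b@values), b@spacing, b@origin)
  hAB <- max(.min_distances(pa, pb))
  hBA <- max(.min_distances(pb, pa))
  max(hAB, hBA) / 10
}

#' Signed volume difference between two masks, in ml
#'
#' `volume(auto) - volume(manual)`; positive when the automatic mask is
#' larger.
#'
#' @param auto,manual [BinaryMask] objects on the same grid.
#' @return Signed volume in ml.
#' @export
volumeDifference <- function(auto, manual) {
  stopifnot(is(auto, "BinaryMask"), is(manual, "BinaryMask"))
  assertSameGrid(auto, manual, "masks")
  maskVolumeMl(auto) - maskVolumeMl(manual)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are `autoValues - manualValues`. Reports the mean
#' difference, the sample SD (n - 1 denominator), the coefficient of
#' reproducibility CoR = 1.96 SD, and the limits of agreement
#' mean +/- CoR.
#'
#' @param autoValues,manualValues equal-length numeric vectors, n >= 2.
#' @return A [BlandAltmanSummary].
#' @examples
#' # a mean difference of 2 with CoR 6 gives limits of agreement 8 and -4
#' s <- blandAltman(c(20, 22, 24), c(18, 20, 22))
#' s@meanDifference
#' @export
blandAltman <- function(autoValues, manualValues) {
  if (length(autoValues) != length(manualValues))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(autoValues)
  if (n < 2) stop("at least two pairs are required", call. = FALSE)
  d <- autoValues - manualValues
  m <- mean(d)
  s <- stats::sd(d)
  cor <- 1.96 * s
  new("BlandAltmanSummary", n = as.integer(n), meanDifference = m,
      sdDifference = s, coefficientOfReproducibility = cor,
      upperLimit = m + cor, lowerLimit = m - cor)
}

setMethod("show", "BlandAltmanSummary", function(object) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean difference %.3f +/- %.3f (CoR),\n",
    object@n, object@meanDifference, object@coefficientOfReproducibility))
  cat(sprintf("  limits of agreement [%.3f, %.3f]\n",
              object@lowerLimit, object@upperLimit))
})

#' Pearson correlation of paired measurements
#'
#' Thin wrapper around [stats::cor()] with the contract checks the
#' pipeline relies on (n >= 3, nonconstant inputs).
#'
#' @param x,y equal-length numeric vectors.
#' @return Sample correlation coefficient in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3) stop("at least three pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided paired t test
#'
#' Tests the null hypothesis of zero mean paired difference:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of freedom.
#' Constant differences (zero variance) are a contract violation and
#' raise an error rather than returning an infinite statistic.
#'
#' @param autoValues,manualValues equal-length numeric vectors, n >= 2.
#' @return A list with elements `t`, `df`, `p`.
#' @export
pairedTTest <- function(autoValues, manualValues) {
  if (length(autoValues) != length(manualValues))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(autoValues)
  if (n < 2) stop("at least two pairs are required", call. = FALSE)
  d <- autoValues - manualValues
  s <- stats::sd(d)
  if (s == 0)
    stop("zero-variance differences: paired t test undefined", call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cumulative healthy-liver dose over multiple treatments
#'
#' Patients treated in several sessions accumulate healthy-liver dose;
#' the doses of all treatments up to the assessment time point are
#' summed.
#'
#' @param dosesPerTreatment nonempty vector of nonnegative doses (Gy).
#' @return Total dose, Gy.
#' @export
cumulativePatientDose <- function(dosesPerTreatment) {
  if (length(dosesPerTreatment) == 0)
    stop("at least one treatment dose is required", call. = FALSE)
  if (any(dosesPerTreatment < 0))
    stop("doses must be nonnegative", call. = FALSE)
  sum(dosesPerTreatment)
}

#' Dose-hepatotoxicity summary
#'
#' Groups patients by worst hepatotoxicity grade during follow-up
#' (0 to 5 on the standardised post-radioembolization scale; grade >= 3
#' is considered significant) and summarises the cumulative healthy-liver
#' dose per segmentation method: per-grade patient counts with median and
#' IQR, the list of significant patients, and the Spearman rank
#' correlation between grade and cumulative dose per method.
#'
#' @param records a data.frame with columns `patient_id`, `worst_grade`
#'   (integer 0-5), `cumulative_dose_manual_gy`,
#'   `cumulative_dose_automatic_gy`.
#' @return A list with elements `perGrade` (data.frame: grade, n, and
#'   median/IQR of dose per method), `significant` (records with grade >=
#'   3), and `spearman` (list per method with `rho` and `p`).
#' @export
toxicitySummary <- function(records) {
  need <- c("patient_id", "worst_grade", "cumulative_dose_manual_gy",
            "cumulative_dose_automatic_gy")
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("nonempty records data.frame required", call. = FALSE)
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  g <- records$worst_grade
  if (any(!g %in% 0:5))
    stop("worst_grade must be an integer in 0..5", call. = FALSE)

  summarise <- function(x) {
    if (length(x) == 0) return(c(median = NA_real_, iqr = NA_real_))
    c(median = stats::median(x), iqr = stats::IQR(x))
  }
  perGrade <- do.call(rbind, lapply(0:5, function(gr) {
    sel <- g == gr
    man <- summarise(records$cumulative_dose_manual_gy[sel])
    aut <- summarise(records$cumulative_dose_automatic_gy[sel])
    data.frame(grade = gr, n = sum(sel),
               median_dose_manual_gy = man["median"],
               iqr_dose_manual_gy = man["iqr"],
               median_dose_automatic_gy = aut["median"],
               iqr_dose_automatic_gy = aut["iqr"],
               row.names = NULL)
  }))

  spearman <- lapply(
    c(manual = "cumulative_dose_manual_gy",
      automatic = "cumulative_dose_automatic_gy"),
    function(col) {
      if (stats::sd(g) == 0 || stats::sd(records[[col]]) == 0)
        return(list(rho = NA_real_, p = NA_real_))
      ct <- suppressWarnings(
        stats::cor.test(g, records[[col]], method = "spearman",
                        exact = FALSE))
      list(rho = unname(ct$estimate), p = ct$p.value)
    })

  list(perGrade = perGrade,
       significant = records[g >= 3, , drop = FALSE],
       spearman = spearman)
}
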