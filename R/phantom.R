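# Digital abdominal phantom for the dual-isotope protocol.
#
# Physiology encoded in the truth maps: Tc-99m stannous-phytate is taken
# up by Kupffer cells, present only in healthy liver parenchyma and the
# spleen, so tumors and necrosis are Tc-cold; Ho-166 microspheres lodge
# preferentially in (vascularised) tumor tissue, with lower uptake in
# healthy liver and none in necrosis.

#' Construct a PhantomSpec
#'
#' Defaults describe a 64^3 grid at 4.8 mm isotropic voxels (the clinical
#' SPECT matrix resolution) holding a ~1.7 l liver made of two
#' overlapping ellipsoids, a Tc-avid spleen, one 40 mm tumor with a 16 mm
#' necrotic core and one 30 mm tumor. Uptake ratios default to 3:1
#' (Ho tumor:healthy) and 1:1 (Tc spleen:liver); PSF FWHM 10 mm; 1e7
#' expected counts per isotope; 5400 MBq Ho-166 and 52 MBq Tc-99m.
#' The manual-arm misregistration defaults to an (8, 4, 12) mm
#' translation (cranio-caudal dominated, as breathing-induced
#' registration error is) with a 3 degree rotation about z.
#'
#' @param shape integer(3) grid dimensions.
#' @param spacing numeric(3) or scalar, mm.
#' @param origin numeric(3), mm.
#' @param liverCenters,liverSemiAxes 2x3 matrices (mm): liver ellipsoids.
#' @param spleenCenter,spleenSemiAxes numeric(3) (mm).
#' @param tumors data.frame with columns cx, cy, cz, diameter_mm,
#'   necrosis_diameter_mm (NA = no necrotic core). Zero rows = no tumors.
#' @param tcSpleenToLiverRatio,hoTumorToNormalRatio unitless ratios.
#' @param psfFwhmMm SPECT point-spread FWHM, mm.
#' @param tcTotalCounts,hoTotalCounts expected total counts per isotope.
#' @param administeredActivityMBq Ho-166 activity, MBq.
#' @param tcActivityMBq Tc-99m activity, MBq.
#' @param misregTranslationMm numeric(3), mm.
#' @param misregRotationDegZ degrees.
#' @param seed master seed; stage seeds are derived via [stageSeed()].
#' @return A [PhantomSpec].
#' @export
phantomSpec <- function(shape = c(64L, 64L, 64L),
                        spacing = c(4.8, 4.8, 4.8),
                        origin = c(0, 0, 0),
                        liverCenters = rbind(c(115, 150, 160),
                                             c(175, 120, 145)),
                        liverSemiAxes = rbind(c(85, 70, 60),
                                              c(60, 55, 50)),
                        spleenCenter = c(245, 196, 150),
                        spleenSemiAxes = c(28, 24, 32),
                        tumors = data.frame(
                          cx = c(120, 185), cy = c(160, 125),
                          cz = c(170, 150), diameter_mm = c(40, 30),
                          necrosis_diameter_mm = c(16, NA)),
                        tcSpleenToLiverRatio = 1,
                        hoTumorToNormalRatio = 3,
                        psfFwhmMm = 10,
                        tcTotalCounts = 1e7,
                        hoTotalCounts = 1e7,
                        administeredActivityMBq = 5400,
                        tcActivityMBq = 52,
                        misregTranslationMm = c(8, 4, 12),
                        misregRotationDegZ = 3,
                        seed = 1L) {
  new("PhantomSpec",
      shape = as.integer(rep_len(shape, 3L)),
      spacing = as.numeric(rep_len(spacing, 3L)),
      origin = as.numeric(rep_len(origin, 3L)),
      liverCenters = liverCenters, liverSemiAxes = liverSemiAxes,
      spleenCenter = spleenCenter, spleenSemiAxes = spleenSemiAxes,
      tumors = tumors,
      tcSpleenToLiverRatio = tcSpleenToLiverRatio,
      hoTumorToNormalRatio = hoTumorToNormalRatio,
      psfFwhmMm = psfFwhmMm,
      tcTotalCounts = tcTotalCounts, hoTotalCounts = hoTotalCounts,
      administeredActivityMBq = administeredActivityMBq,
      tcActivityMBq = tcActivityMBq,
      misregTranslationMm = misregTranslationMm,
      misregRotationDegZ = misregRotationDegZ,
      seed = as.integer(seed))
}

# world coordinates (mm) of all voxel centres, as three 3D arrays
worldCoords <- function(shape, spacing, origin) {
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  list(x = array(xs, shape),
       y = array(rep(ys, each = shape[1]), shape),
       z = array(rep(zs, each = shape[1] * shape[2]), shape))
}

ellipsoidArray <- function(w, center, semi) {
  ((w$x - center[1]) / semi[1])^2 + ((w$y - center[2]) / semi[2])^2 +
    ((w$z - center[3]) / semi[3])^2 <= 1
}

# stop unless center +/- semi axes fit in the world extent of the grid
assertInsideGrid <- function(center, semi, shape, spacing, origin, what) {
  lo <- origin
  hi <- origin + (shape - 1) * spacing
  if (any(center - semi < lo) || any(center + semi > hi))
    stop(what, " extends outside the grid", call. = FALSE)
}

#' Generate a phantom with ground truth
#'
#' Deterministic given the spec: geometry carries no randomness
#' (randomness enters only through [simulateSpect()] and
#' [perturbMask()]). Builds the truth masks, noiseless Tc-99m and Ho-166
#' activity-concentration maps (MBq/ml), and the pseudo-CT (body 0 HU in
#' -1000 HU air). The Ho map is normalised so that its integral over the
#' volume equals the administered activity; the Tc map likewise
#' integrates to the injected Tc activity. The analytic mean dose in the
#' true healthy VOI is recorded with the default dosimetry constants.
#'
#' @param spec a [PhantomSpec].
#' @return A [PhantomTruth].
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  sh <- spec@shape; sp <- spec@spacing; og <- spec@origin
  w <- worldCoords(sh, sp, og)

  assertInsideGrid(spec@liverCenters[1, ], spec@liverSemiAxes[1, ],
                   sh, sp, og, "liver ellipsoid 1")
  assertInsideGrid(spec@liverCenters[2, ], spec@liverSemiAxes[2, ],
                   sh, sp, og, "liver ellipsoid 2")
  assertInsideGrid(spec@spleenCenter, spec@spleenSemiAxes, sh, sp, og,
                   "spleen")

  liver <- ellipsoidArray(w, spec@liverCenters[1, ], spec@liverSemiAxes[1, ]) |
    ellipsoidArray(w, spec@liverCenters[2, ], spec@liverSemiAxes[2, ])
  spleen <- ellipsoidArray(w, spec@spleenCenter, spec@spleenSemiAxes)

  tumors <- array(FALSE, sh)
  necrosis <- array(FALSE, sh)
  for (i in seq_len(nrow(spec@tumors))) {
    t <- spec@tumors[i, ]
    ctr <- c(t$cx, t$cy, t$cz)
    r <- t$diameter_mm / 2
    assertInsideGrid(ctr, rep(r, 3), sh, sp, og, sprintf("tumor %d", i))
    tumors <- tumors | ellipsoidArray(w, ctr, rep(r, 3))
    if (!is.na(t$necrosis_diameter_mm)) {
      rn <- t$necrosis_diameter_mm / 2
      necrosis <- necrosis | ellipsoidArray(w, ctr, rep(rn, 3))
    }
  }
  healthy <- liver & !tumors & !necrosis
  tumors <- tumors & !necrosis   # necrotic cores are not viable tumor

  # pseudo-CT and body
  halfExtent <- (sh - 1) * sp / 2
  bodySemi <- pmin(c(146, 140, 146), 0.97 * halfExtent)
  bodyCenter <- og + halfExtent
  body <- ellipsoidArray(w, bodyCenter, bodySemi)
  if (any((liver | spleen) & !body))
    stop("organs extend outside the phantom body", call. = FALSE)
  ct <- array(-1000, sh)
  ct[body] <- 0

  vv <- prod(sp) / 1000  # ml

  # Tc-99m: uniform in healthy liver, ratio in spleen, cold elsewhere
  tc <- array(0, sh)
  tc[healthy] <- 1
  tc[spleen] <- spec@tcSpleenToLiverRatio
  tcTot <- sum(tc) * vv
  if (tcTot > 0) tc <- tc * (spec@tcActivityMBq / tcTot)

  # Ho-166: tumors hot, healthy lower, necrosis and outside liver cold
  ho <- array(0, sh)
  ho[healthy] <- 1
  ho[tumors] <- spec@hoTumorToNormalRatio
  hoTot <- sum(ho) * vv
  if (hoTot <= 0)
    stop("phantom has no Ho-166 uptake volume", call. = FALSE)
  ho <- ho * (spec@administeredActivityMBq / hoTot)

  cfg <- dosimetryConfig()
  healthyConc <- spec@administeredActivityMBq / hoTot  # MBq/ml in healthy
  trueMeanDose <- cfg@energyPerActivity * healthyConc / cfg@tissueDensity

  mk <- function(a) binaryMask(array(as.double(a), sh), sp, og)
  new("PhantomTruth",
      hoActivity = voxelGrid(ho, sp, og),
      tcActivity = voxelGrid(tc, sp, og),
      ct = voxelGrid(ct, sp, og),
      masks = list(liver = mk(liver), spleen = mk(spleen),
                   tumors = mk(tumors), necrosis = mk(necrosis),
                   healthyTruth = mk(healthy), body = mk(body)),
      administeredActivityMBq = spec@administeredActivityMBq,
      trueMeanDoseGy = trueMeanDose, spec = spec)
}

#' Derive a per-stage seed from the master seed
#'
#' Multi-stage simulations draw from independent streams: stage k uses
#' `(seed * 7919 + k) mod (2^31 - 1)`. Stages are numbered 1 (Tc SPECT),
#' 2 (Ho SPECT), 3 (mask perturbation); cohort run r offsets the master
#' seed by `100 * r` first.
#'
#' @param seed master integer seed.
#' @param stage integer stage number.
#' @return An integer seed.
#' @export
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage) %% 2147483647)
}

# run code under a seed, restoring the caller's RNG state afterwards
withSeed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a SPECT count volume from an activity map
#'
#' Image-domain SPECT model: the activity map is blurred with an
#' isotropic Gaussian point-spread function, rescaled so its expected
#' total equals `totalCounts`, and Poisson noise is drawn per voxel.
#' Projection-domain effects (collimator response, scatter, attenuation,
#' reconstruction) are not modelled; the volumes stand in for already
#' reconstructed, scatter-corrected images.
#'
#' @param activity a [VoxelGrid] of nonnegative activity concentration.
#' @param psfFwhmMm Gaussian PSF FWHM, mm; 0 disables blurring.
#' @param totalCounts expected total counts (> 0).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @return A [VoxelGrid] of counts on the same grid.
#' @export
simulateSpect <- function(activity, psfFwhmMm, totalCounts, seed) {
  stopifnot(is(activity, "VoxelGrid"))
  if (any(activity@values < 0))
    stop("activity must be nonnegative", call. = FALSE)
  if (totalCounts <= 0) stop("totalCounts must be positive", call. = FALSE)
  tot <- sum(activity@values)
  if (tot == 0)
    stop("all-zero activity: nothing to image", call. = FALSE)
  expected <- gaussianSmooth(activity, psfFwhmMm)@values
  lambda <- expected * (totalCounts / sum(expected))
  counts <- withSeed(seed, rpois(length(lambda), lambda))
  voxelGrid(array(as.double(counts), dim(lambda)),
            activity@spacing, activity@origin)
}

#' Apply a rigid misregistration to a mask
#'
#' Emulates the residual error of manually registering a CECT-derived
#' delineation onto the SPECT frame: a rigid translation plus rotation
#' about the z axis, applied about the mask centroid, resampled with
#' nearest-neighbour interpolation onto the same grid. The operation is
#' deterministic; `seed` is accepted for pipeline-interface uniformity
#' and ignored.
#'
#' @param mask a nonempty [BinaryMask].
#' @param translationMm numeric(3), mm.
#' @param rotationDegZ rotation about z, degrees (counter-clockwise in
#'   the xy plane).
#' @param seed ignored (kept for a uniform stage signature).
#' @return A [BinaryMask] on the same grid. If the transform pushes part
#'   of the mask outside the grid the result is clipped, with a warning.
#' @export
perturbMask <- function(mask, translationMm = c(0, 0, 0), rotationDegZ = 0,
                        seed = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  if (sum(mask@values) == 0) stop("mask is empty", call. = FALSE)
  tr <- as.numeric(rep_len(translationMm, 3L))
  if (all(tr == 0) && rotationDegZ == 0) return(mask)

  d <- dim(mask@values)
  sp <- mask@spacing; og <- mask@origin
  idx <- which(mask@values > 0, arr.ind = TRUE)
  centroid <- og + (colMeans(idx) - 1) * sp

  th <- rotationDegZ * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))

  # forward-map the mask voxels to detect clipping
  src <- sweep(sweep(idx - 1, 2, sp, "*"), 2, og, "+")
  fwd <- sweep(sweep(src, 2, centroid, "-") %*% t(R), 2, centroid + tr, "+")
  hi <- og + (d - 1) * sp
  if (any(fwd < rep(og - sp / 2, each = nrow(fwd))) ||
      any(fwd > rep(hi + sp / 2, each = nrow(fwd))))
    warning("rigid transform moves part of the mask outside the grid; clipped")

  # inverse mapping for every output voxel
  w <- worldCoords(d, sp, og)
  tgt <- cbind(as.vector(w$x), as.vector(w$y), as.vector(w$z))
  srcPt <- sweep(sweep(tgt, 2, centroid + tr, "-") %*% R, 2, centroid, "+")
  srcIdx <- round(sweep(sweep(srcPt, 2, og, "-"), 2, sp, "/")) + 1
  ok <- srcIdx[, 1] >= 1 & srcIdx[, 1] <= d[1] &
        srcIdx[, 2] >= 1 & srcIdx[, 2] <= d[2] &
        srcIdx[, 3] >= 1 & srcIdx[, 3] <= d[3]
  out <- numeric(prod(d))
  lin <- (srcIdx[ok, 3] - 1) * d[1] * d[2] + (srcIdx[ok, 2] - 1) * d[1] +
    srcIdx[ok, 1]
  out[ok] <- mask@values[lin]
  binaryMask(array(out, d), sp, og)
}
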