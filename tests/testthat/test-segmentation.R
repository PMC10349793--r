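# Gaussian smoothing, spleen removal, the 40% threshold segmentation and
# the manual-reference healthy-VOI rules.

test_that("smoothing: identity at fwhm 0, analytic impulse response,
           integral conservation", {
  g <- voxelGrid(array(runif(10^3), c(10, 10, 10)), spacing = 2)
  expect_identical(gridValues(gaussianSmooth(g, 0)), gridValues(g))
  expect_error(gaussianSmooth(g, -1), "nonnegative")

  # delta impulse, fwhm 10 mm on 2 mm voxels: matches the sampled
  # analytic Gaussian with sigma = 4.2466 mm near the centre
  sh <- c(33, 33, 33)
  imp <- array(0, sh); imp[17, 17, 17] <- 1
  sm <- gridValues(gaussianSmooth(voxelGrid(imp, spacing = 2), 10))
  sigma <- 10 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 4.2466, tolerance = 1e-4)
  analytic <- function(dxyz)
    prod(2 * stats::dnorm(dxyz * 2, sd = sigma))  # density x voxel length
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(0, 2, 2))) {
    got <- sm[17 + off[1], 17 + off[2], 17 + off[3]]
    expect_equal(got, analytic(off), tolerance = 1e-3)
  }

  # interior blob: total preserved to 1e-6 relative
  blob <- array(0, sh); blob[14:20, 14:20, 14:20] <- 3.7
  smB <- gaussianSmooth(voxelGrid(blob, spacing = 2), 10)
  expect_equal(sum(gridValues(smB)), sum(blob), tolerance = 1e-9)
})

test_that("spleen removal by mask and by largest component", {
  spec <- phantomSpec(tcSpleenToLiverRatio = 1.2)
  ph <- makePhantom(spec)
  tc <- simulateSpect(ph@tcActivity, 8, 1e7, seed = 2)
  spleen <- ph@masks$spleen

  # provided mask: spleen voxels zeroed, others untouched
  cfg <- segmentationConfig(spleenStrategy = "provided_mask")
  out <- removeSpleen(tc, cfg, spleenMask = spleen)
  sv <- gridValues(spleen) == 1
  expect_true(all(gridValues(out)[sv] == 0))
  expect_identical(gridValues(out)[!sv], gridValues(tc)[!sv])
  expect_error(removeSpleen(tc, cfg), "requires a spleen mask")

  # an empty provided mask leaves the image unchanged
  empty <- binaryMask(array(0, dim(gridValues(tc))), like = tc)
  expect_identical(gridValues(removeSpleen(tc, cfg, empty)), gridValues(tc))

  # largest component: the liver survives, the spleen region is zeroed
  cfgL <- segmentationConfig(spleenStrategy = "largest_component")
  outL <- removeSpleen(tc, cfgL)
  liver <- gridValues(ph@masks$liver) == 1
  expect_identical(gridValues(outL)[liver], gridValues(tc)[liver])
  expect_lt(sum(gridValues(outL)[sv]), sum(gridValues(tc)[sv]))
  # and the final segmentation stays clear of the spleen
  mFull <- automaticHealthyMask(tc, cfgL)
  expect_equal(sum(gridValues(mFull) * gridValues(spleen)), 0)

  # a single connected uptake region passes through unchanged
  sph <- sphereArray(c(16, 16, 16), c(8, 8, 8), 5) * 100
  single <- voxelGrid(sph, spacing = 4)
  expect_identical(gridValues(removeSpleen(single, cfgL)),
                   gridValues(single))
})

test_that("threshold segmentation: forced threshold, relative maximum,
           rescaling invariance, threshold monotonicity", {
  cfg0 <- segmentationConfig(smoothingFwhmMm = 0, minComponentMl = 0)
  sph <- sphereArray(c(16, 16, 16), c(8, 8, 8), 5)
  img <- voxelGrid(sph * 80, spacing = 4)
  m <- automaticHealthyMask(img, cfg0)
  expect_identical(gridValues(m), sph)   # V >= 0.4 V everywhere inside

  # two disjoint spheres with peaks 100 and 30: only the hot one passes
  two <- sphereArray(c(24, 12, 12), c(6, 6, 6), 3) * 100 +
    sphereArray(c(24, 12, 12), c(18, 6, 6), 3) * 30
  m2 <- automaticHealthyMask(voxelGrid(two, spacing = 4), cfg0)
  expect_identical(gridValues(m2),
                   sphereArray(c(24, 12, 12), c(6, 6, 6), 3))

  # positive rescaling leaves the mask unchanged
  spec <- phantomSpec()
  ph <- makePhantom(spec)
  tc <- simulateSpect(ph@tcActivity, 10, 1e7, seed = 4)
  cfg <- segmentationConfig()
  mA <- automaticHealthyMask(tc, cfg)
  tcScaled <- voxelGrid(gridValues(tc) * 37.5, gridSpacing(tc),
                        gridOrigin(tc))
  expect_identical(gridValues(automaticHealthyMask(tcScaled, cfg)),
                   gridValues(mA))

  # lowering the threshold never shrinks the mask
  mLow <- automaticHealthyMask(tc, segmentationConfig(thresholdFraction = 0.25))
  expect_true(all(gridValues(mA) <= gridValues(mLow)))

  expect_error(automaticHealthyMask(voxelGrid(array(0, c(4, 4, 4))), cfg0),
               "all-zero")
})

test_that("threshold segmentation matches a naive loop oracle on small grids", {
  # isolate the smooth-max-threshold contract: no spleen removal
  # (empty provided mask), no component cleanup
  cfg <- segmentationConfig(smoothingFwhmMm = 6, minComponentMl = 0,
                            spleenStrategy = "provided_mask")
  set.seed(71)
  for (rep in 1:3) {
    sh <- c(12, 12, 12)
    arr <- sphereArray(sh, sample(5:8, 3, replace = TRUE), runif(1, 2.5, 4)) *
      runif(1, 50, 150)
    arr <- arr + sphereArray(sh, sample(4:9, 3, replace = TRUE), 2) *
      runif(1, 10, 60)
    img <- voxelGrid(arr, spacing = 3)
    empty <- binaryMask(array(0, sh), like = img)
    got <- gridValues(automaticHealthyMask(img, cfg, spleenMask = empty))
    want <- bruteAutoMask(arr, 3, 6, 0.40)
    expect_identical(got, want)
  }
})

test_that("manual-reference healthy VOI follows the subtraction rules", {
  sh <- c(20, 20, 20); sp <- 5  # 0.125 ml voxels
  liver <- binaryMask(sphereArray(sh, c(10, 10, 10), 8), spacing = sp)
  expect_identical(gridValues(referenceHealthyMask(liver)),
                   gridValues(liver))

  tumor <- binaryMask(sphereArray(sh, c(10, 10, 10), 4), spacing = sp)
  out <- referenceHealthyMask(liver, list(tumor))
  expect_equal(maskVolumeMl(out), maskVolumeMl(liver) - maskVolumeMl(tumor),
               tolerance = 1e-12)
  expect_true(all(gridValues(out) * gridValues(tumor) == 0))
  expect_true(all(gridValues(out) <= gridValues(liver)))

  # a 0.4 ml lesion (equivalent diameter ~9.1 mm < 10 mm) is ignored
  small <- array(0, sh)
  small[9:11, 10, 10] <- 1    # 3 voxels = 0.375 ml, eq. diam 8.96 mm
  smallMask <- binaryMask(small, spacing = sp)
  eqDiam <- 2 * (3 * sum(small) * sp^3 / (4 * pi))^(1 / 3)
  expect_lt(eqDiam, 10)
  out2 <- referenceHealthyMask(liver, list(smallMask))
  expect_identical(gridValues(out2), gridValues(liver))

  # necrosis is always excluded
  nec <- binaryMask(sphereArray(sh, c(12, 10, 10), 2), spacing = sp)
  out3 <- referenceHealthyMask(liver, list(), necrosis = nec)
  expect_true(all(gridValues(out3) * gridValues(nec) == 0))

  # grid mismatch is an error
  other <- binaryMask(sphereArray(sh, c(10, 10, 10), 4), spacing = 4)
  expect_error(referenceHealthyMask(liver, list(other)), "grid mismatch")
})
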