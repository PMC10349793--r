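# Count-to-concentration scaling, the local-deposition dose model and
# DVH metrics.

uniformDose <- function(gy, sh = c(6, 6, 6), sp = 2) {
  doseFromConcentration(
    voxelGrid(array(gy * 1.06 / 15.87, sh), spacing = sp))
}

fullMask <- function(sh = c(6, 6, 6), sp = 2)
  binaryMask(array(1, sh), spacing = sp)

test_that("counts are scaled to concentration inside the body only", {
  sh <- c(10, 10, 10)
  body <- binaryMask(array(1, sh), spacing = 10)       # 1 ml voxels
  counts <- voxelGrid(array(5, sh), spacing = 10)      # uniform
  conc <- countsToConcentration(counts, body, 100)
  expect_equal(unique(as.vector(gridValues(conc))), 0.1)  # 100 MBq / 1000 ml

  # an external hot voxel changes nothing inside the body
  bodyVals <- array(1, sh); bodyVals[1, 1, 1] <- 0
  body2 <- binaryMask(bodyVals, spacing = 10)
  hot <- gridValues(counts); hot[1, 1, 1] <- 1e6
  conc2 <- countsToConcentration(voxelGrid(hot, spacing = 10), body2, 100)
  inside <- bodyVals == 1
  expect_equal(gridValues(conc2)[inside],
               rep(100 / 999, sum(inside)), tolerance = 1e-12)
  expect_equal(gridValues(conc2)[1, 1, 1], 0)

  # integral over the body recovers the administered activity
  set.seed(9)
  noisy <- voxelGrid(array(rpois(1000, 40), sh), spacing = 10)
  conc3 <- countsToConcentration(noisy, body, 4982)
  expect_equal(sum(gridValues(conc3)) * voxelVolumeMl(conc3), 4982,
               tolerance = 1e-9)

  expect_error(countsToConcentration(voxelGrid(array(0, sh), spacing = 10),
                                     body, 100), "no counts")
})

test_that("pre-treatment scaling activity: single and partial treatments", {
  expect_equal(pretreatmentActivity(
    data.frame(administered_activity_MBq = 3850)), 3850)
  expect_equal(pretreatmentActivity(
    data.frame(administered_activity_MBq = 4982)), 4982)
  expect_equal(pretreatmentActivity(
    data.frame(administered_activity_MBq = c(2000, 3000),
               partial_treatment_group = "lobes")), 5000)
  expect_error(pretreatmentActivity(data.frame()), "at least one")
  expect_error(pretreatmentActivity(
    data.frame(administered_activity_MBq = c(2000, 3000))), "group")
})

test_that("dose formula: constants, zero map, linearity", {
  conc1 <- voxelGrid(array(1, c(4, 4, 4)), spacing = 2)
  d <- doseFromConcentration(conc1)
  expect_equal(unique(as.vector(gridValues(d))), 15.87 / 1.06)
  expect_equal(gridValues(d)[1, 1, 1], 14.9717, tolerance = 1e-5)

  d0 <- doseFromConcentration(voxelGrid(array(0, c(4, 4, 4))))
  expect_true(all(gridValues(d0) == 0))

  conc2 <- voxelGrid(array(2, c(4, 4, 4)), spacing = 2)
  expect_identical(gridValues(doseFromConcentration(conc2)),
                   2 * gridValues(d))
})

test_that("mean dose over a VOI", {
  expect_equal(meanDose(uniformDose(20), fullMask()), 20, tolerance = 1e-12)
  sh <- c(2, 1, 1)
  dd <- new("DoseImage", values = array(c(10, 30), sh),
            spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_equal(meanDose(dd, binaryMask(array(1, sh))), 20)
  expect_error(meanDose(uniformDose(20), binaryMask(array(0, c(6, 6, 6)),
                                                    spacing = 2)), "empty")
})

test_that("cumulative DVH: step functions and monotonicity", {
  dvh <- cumulativeDvh(uniformDose(20), fullMask(), 0.5)
  df <- as.data.frame(dvh)
  expect_equal(df$volume_fraction[df$dose_gy <= 20], rep(1, 41))
  expect_equal(df$volume_fraction[df$dose_gy > 20], 0)

  sh <- c(4, 1, 1)
  dd <- new("DoseImage", values = array(c(10, 10, 30, 30), sh),
            spacing = c(1, 1, 1), origin = c(0, 0, 0))
  dvh2 <- cumulativeDvh(dd, binaryMask(array(1, sh)), 1)
  df2 <- as.data.frame(dvh2)
  mid <- df2$dose_gy > 10 & df2$dose_gy <= 30
  expect_equal(df2$volume_fraction[mid], rep(0.5, sum(mid)))

  # random dose fields: curve equals the brute-force fraction per edge
  set.seed(12)
  for (i in 1:20) {
    vals <- array(rexp(27, 1 / 20), c(3, 3, 3))
    dr <- new("DoseImage", values = vals, spacing = c(1, 1, 1),
              origin = c(0, 0, 0))
    dvh3 <- cumulativeDvh(dr, binaryMask(array(1, c(3, 3, 3))), 2)
    expect_equal(dvh3@volumeFraction, bruteDvh(vals, dvh3@doseEdges))
    expect_true(all(diff(dvh3@volumeFraction) <= 0))
  }
})

test_that("D metric is the interpolated quantile of the hottest fraction", {
  sh <- c(10, 1, 1)
  dd <- new("DoseImage", values = array(as.double(1:10), sh),
            spacing = c(1, 1, 1), origin = c(0, 0, 0))
  voi <- binaryMask(array(1, sh))
  expect_equal(dMetric(dd, voi, 0.70), 3.7)
  expect_equal(dMetric(uniformDose(20), fullMask(), 0.70), 20)

  # monotone non-increasing in the volume fraction
  fs <- seq(0.1, 0.9, by = 0.1)
  ds <- sapply(fs, function(f) dMetric(dd, voi, f))
  expect_true(all(diff(ds) <= 0))

  # agrees with the hand-written interpolation oracle
  set.seed(5)
  vals <- rexp(40, 1 / 15)
  dr <- new("DoseImage", values = array(vals, c(40, 1, 1)),
            spacing = c(1, 1, 1), origin = c(0, 0, 0))
  voi40 <- binaryMask(array(1, c(40, 1, 1)))
  for (f in c(0.3, 0.5, 0.7, 0.95))
    expect_equal(dMetric(dr, voi40, f), bruteQuantile(vals, 1 - f),
                 tolerance = 1e-12)
})

test_that("V metric is the percentage at or above the threshold", {
  expect_equal(vMetric(uniformDose(60), fullMask(), 50), 100)
  expect_equal(vMetric(uniformDose(20), fullMask(), 50), 0)
  sh <- c(4, 1, 1)
  dd <- new("DoseImage", values = array(c(60, 60, 40, 40), sh),
            spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_equal(vMetric(dd, binaryMask(array(1, sh)), 50), 50)
  expect_equal(vMetric(dd, binaryMask(array(1, sh)), 0), 100)
})

test_that("scaling the administered activity scales all dose metrics", {
  spec <- phantomSpec()
  ph <- makePhantom(spec)
  ho <- simulateSpect(ph@hoActivity, 10, 1e6, seed = 8)
  body <- bodyMask(ph@ct)
  voi <- ph@masks$healthyTruth
  d1 <- doseFromConcentration(countsToConcentration(ho, body, 1000))
  d3 <- doseFromConcentration(countsToConcentration(ho, body, 3000))
  expect_equal(meanDose(d3, voi), 3 * meanDose(d1, voi), tolerance = 1e-12)
  expect_equal(dMetric(d3, voi, 0.7), 3 * dMetric(d1, voi, 0.7),
               tolerance = 1e-12)
})

test_that("deposited energy over the body matches the administered activity", {
  spec <- phantomSpec()
  ph <- makePhantom(spec)
  ho <- simulateSpect(ph@hoActivity, 10, 2e6, seed = 21)
  body <- bodyMask(ph@ct)
  cfg <- dosimetryConfig()
  dose <- doseFromConcentration(
    countsToConcentration(ho, body, ph@administeredActivityMBq), cfg)
  massKg <- voxelVolumeMl(dose) * cfg@tissueDensity / 1000
  energyJ <- sum(gridValues(dose)[gridValues(body) > 0]) * massKg
  expectedJ <- cfg@energyPerActivity / 1000 * ph@administeredActivityMBq
  expect_equal(energyJ, expectedJ, tolerance = 1e-6)
})
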