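test_that("centre of mass recovers known geometries", {
  # uniform square: geometric centre
  cm <- centerOfMass(matrix(1, 5, 5), 65)
  expect_equal(c(cm$x_nm, cm$y_nm), c(2, 2) * 65)
  # two equal point sources: midpoint
  m <- matrix(0, 9, 9); m[3, 2] <- 7; m[7, 8] <- 7
  cm2 <- centerOfMass(m, 1)
  expect_equal(c(cm2$x_nm, cm2$y_nm), c((1 + 7) / 2, (2 + 6) / 2))
  # noiseless Gaussian at sub-pixel position: within 0.05 px
  g <- gaussSpot(40, 40, 20.30, 15.70, 2.3, 1000)
  cm3 <- centerOfMass(g, 1)
  expect_lt(abs(cm3$x_nm - 20.30), 0.05)
  expect_lt(abs(cm3$y_nm - 15.70), 0.05)
  # zero intensity is a QC failure, not an error
  expect_false(centerOfMass(matrix(0, 5, 5), 65)$valid)
})

test_that("border-ring background subtraction removes a constant offset", {
  expect_equal(subtractBackground(matrix(7, 9, 9)), matrix(0, 9, 9))
  spot <- gaussSpot(21, 21, 10, 10, 2, 5000)
  # tails below the ring median are clamped; deviations stay negligible
  expect_lt(max(abs(subtractBackground(spot + 3) - spot)), 1e-3)
  # centroid of a noisy spot moves < 0.1 px after background handling
  set.seed(21)
  noisy <- spot + 20 + matrix(rnorm(441, 0, 2), 21)
  cm <- centerOfMass(subtractBackground(noisy), 1)
  clean <- centerOfMass(spot, 1)
  expect_lt(abs(cm$x_nm - clean$x_nm), 0.1)
  expect_lt(abs(cm$y_nm - clean$y_nm), 0.1)
})

test_that("the LQ is the signed axis projection", {
  cis <- c(0, 0); trans <- c(60, 80)
  expect_equal(computeLQ(cis, cis, trans)$lq, 0)
  expect_equal(computeLQ(trans, cis, trans)$lq, 1)
  # worked dot product: (80*60 + (-20)*80) / 10000
  r <- computeLQ(c(80, -20), cis, trans)
  expect_equal(r$lq, 0.32)
  expect_equal(r$d_axis_nm, 100)
  # degenerate axis flags instead of crashing
  expect_false(computeLQ(c(1, 1), cis, cis)$valid)
})

test_that("perpendicular cargo offsets leave the LQ unchanged", {
  cis <- c(10, 20); trans <- c(310, 420)
  b <- trans - cis
  perp <- c(-b[2], b[1]) / sqrt(sum(b^2))
  cargo <- cis + 0.4 * b
  for (off in c(-120, 55, 300))
    expect_equal(computeLQ(cargo + off * perp, cis, trans)$lq, 0.4,
                 tolerance = 1e-6)
  # and through the full measurement chain, noiselessly
  base <- simulationConfig(nStacks = 6, noise = FALSE, seed = 8)
  offs <- simulationConfig(nStacks = 6, noise = FALSE, seed = 8,
                           lateralOffsetNm = 100)
  lq0 <- measureMinistacks(simulateMinistackField(base)$image)
  lq1 <- measureMinistacks(simulateMinistackField(offs)$image)
  expect_equal(mean(lq1$lq[lq1$pass_qc]), mean(lq0$lq[lq0$pass_qc]),
               tolerance = 1e-3)
})

test_that("Golgi regions use lower-inclusive half-open intervals", {
  expect_equal(as.character(classifyRegion(c(-0.26, -0.25, 0.24, 0.25,
                                             0.74, 0.75, 1.24, 1.25, 2))),
               c("ERES_ERGIC", "CIS", "CIS", "MEDIAL", "MEDIAL", "TRANS",
                 "TRANS", "TGN", "TGN"))
  expect_equal(as.character(classifyRegion(0.40)), "MEDIAL")
  expect_error(classifyRegion(NA_real_), "finite")
  expect_error(classifyRegion(Inf), "finite")
})

test_that("analyzability gates catch degenerate axes and dark channels", {
  rec <- data.frame(d_axis_nm = c(0, 300, 300, 2000, 300),
                    intensity_cis = c(10, 10, 0, 10, 10),
                    intensity_trans = 10, intensity_cargo = 10)
  out <- filterAnalyzable(rec)
  expect_equal(out$pass_qc, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # noiseless synthetic field passes wholesale under the defaults
  sim <- simulateMinistackField(simulationConfig(nStacks = 8, noise = FALSE,
                                                 seed = 6))
  expect_true(all(measureMinistacks(sim$image)$pass_qc))
})

test_that("ROI detection finds isolated stacks and drops crowded pairs", {
  sim <- simulateMinistackField(simulationConfig(nStacks = 10,
                                                 noise = FALSE,
                                                 stackAngleDeg = 0,
                                                 seed = 11))
  expect_equal(nrow(detectROIs(sim$image)), 10)
  # blank field: nothing above the noise floor
  set.seed(4)
  blank <- MinistackImage(array(20 + rnorm(3 * 128^2, 0, 2),
                                c(128, 128, 3)),
                          c("cis", "trans", "cargo"), 65)
  expect_equal(nrow(detectROIs(blank)), 0)
  # two stacks closer than the box size: both discarded
  m <- matrix(20, 128, 128) + gaussSpot(128, 128, 60, 60, 2.3, 5000) +
    gaussSpot(128, 128, 72, 60, 2.3, 5000) +
    gaussSpot(128, 128, 30, 100, 2.3, 5000)
  crowded <- MinistackImage(array(rep(m, 3), c(128, 128, 3)),
                            c("cis", "trans", "cargo"), 65)
  rois <- detectROIs(crowded)
  expect_equal(nrow(rois), 1)
  expect_equal(attr(rois, "nOverlapDropped"), 2L)
  expect_error(detectROIs("not an image"))
})

test_that("chromatic models recover known shifts", {
  sh <- shiftMatrix(trans = c(2, -1.5), cargo = c(-1.5, 0.5))
  # noiseless: essentially exact
  cfg0 <- simulationConfig(nStacks = 12, imageShape = c(320L, 320L),
                           chromaticShiftPx = sh, noise = FALSE, seed = 2)
  cm0 <- fitChromaticModel(simulateBeadField(cfg0)$image)
  expect_lt(max(abs(cm0@shiftsPx - sh)), 5e-3)
  # zero shift: identity transform
  cfgI <- simulationConfig(nStacks = 12, imageShape = c(320L, 320L),
                           noise = FALSE, seed = 2)
  cmI <- fitChromaticModel(simulateBeadField(cfgI)$image)
  expect_lt(max(abs(cmI@shiftsPx)), 5e-3)
  expect_equal(unname(cmI@shiftsPx["cis", ]), c(0, 0))
  # noisy 25-bead field: within 0.05 px
  cfgN <- simulationConfig(nStacks = 25, imageShape = c(320L, 320L),
                           chromaticShiftPx = sh, seed = 1)
  cmN <- fitChromaticModel(simulateBeadField(cfgN)$image)
  expect_lt(max(abs(cmN@shiftsPx - sh)), 0.05)
  # correction reduces the residual RMS relative to no correction
  uncorrected <- sqrt(sum(sh["trans", ]^2) / 2)
  expect_lt(cmN@residualRmsPx["trans"], uncorrected)
  expect_error(fitChromaticModel(simulateBeadField(
    simulationConfig(nStacks = 2, noise = FALSE, seed = 3))$image),
    "3 matched beads")
})

test_that("corrected coordinates undo the simulated chromatic shift", {
  sh <- shiftMatrix(trans = c(1.2, -0.8))
  cfg <- simulationConfig(nStacks = 10, imageShape = c(320L, 320L),
                          chromaticShiftPx = sh, noise = FALSE, seed = 9)
  sim <- simulateBeadField(cfg)
  cm <- fitChromaticModel(sim$image)
  shifted <- c(100 + 1.2, 50 - 0.8)
  expect_equal(correctCoordinates(cm, shifted, "trans"), c(100, 50),
               tolerance = 1e-2)
})

test_that("noiseless end-to-end measurement returns the true LQ", {
  for (lq in c(-0.3, 0.4, 1.2)) {
    sim <- simulateMinistackField(
      simulationConfig(nStacks = 8, cargoLqTrue = lq, noise = FALSE,
                       seed = 13))
    r <- measureMinistacks(sim$image)
    expect_gt(sum(r$pass_qc), 0)
    expect_lt(max(abs(r$lq[r$pass_qc] - lq)), 1e-3)
  }
})

test_that("noisy measurement is unbiased within two standard errors", {
  lqs <- unlist(lapply(1:7, function(s) {
    sim <- simulateMinistackField(simulationConfig(nStacks = 25,
                                                   seed = 100 + s))
    r <- measureMinistacks(sim$image)
    r$lq[r$pass_qc]
  }))
  expect_gte(length(lqs), 100)
  sem <- sd(lqs) / sqrt(length(lqs))
  expect_lt(abs(mean(lqs) - 0.4), 2 * sem)
})

test_that("the markers are self-consistent anchors of the LQ scale", {
  sim <- simulateMinistackField(simulationConfig(nStacks = 3, noise = FALSE,
                                                 seed = 17))
  s1 <- sim$truth[sim$truth$stack_id == 1, ]
  co <- function(ch) unlist(s1[s1$channel == ch, c("x_nm", "y_nm")])
  expect_identical(computeLQ(co("cis"), co("cis"), co("trans"))$lq, 0)
  expect_identical(computeLQ(co("trans"), co("cis"), co("trans"))$lq, 1)
})
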