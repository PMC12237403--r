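test_that("rotated copies average back to the template", {
  tmpl <- simulateSideViewStack(nImages = 1, rotate = FALSE,
                                scaleJitter = 0, noise = FALSE, seed = 2)
  rot <- simulateSideViewStack(nImages = 12, rotate = TRUE,
                               scaleJitter = 0, noise = FALSE, seed = 2)
  a0 <- sideAverage(tmpl$stack)
  a1 <- sideAverage(rot$stack)
  for (k in seq_along(a0@channels)) {
    d <- a1@data[, , k] - a0@data[, , k]
    expect_lt(sqrt(mean(d^2)), 0.05 * max(a0@data[, , k]))
  }
  expect_equal(a1@nAveraged, 12L)
})

test_that("a single image side-averages to its normalized self", {
  one <- simulateSideViewStack(nImages = 1, rotate = FALSE,
                               scaleJitter = 0, noise = FALSE, seed = 9)
  avg <- sideAverage(one$stack)
  expect_equal(avg@nAveraged, 1L)
  for (k in seq_along(avg@channels))
    expect_equal(max(avg@data[, , k]), 1, tolerance = 1e-9)
})

test_that("mirror-symmetric templates stay symmetric after averaging", {
  sim <- simulateSideViewStack(nImages = 8, rotate = TRUE, scaleJitter = 0,
                               noise = FALSE, seed = 12)
  avg <- sideAverage(sim$stack)
  m <- avg@data[, , 2]
  # the template is symmetric about the vertical stack axis
  d <- m - m[, rev(seq_len(ncol(m)))]
  expect_lt(sqrt(mean(d^2)), 0.05 * max(m))
})

test_that("the side-view LQ is the axial position ratio", {
  expect_equal(lqSide(250, 100, 400), 0.5)
  expect_equal(lqSide(100, 100, 400), 0)
  expect_equal(lqSide(400, 100, 400), 1)
  expect_error(lqSide(1, 2, 2), "degenerate")
})

test_that("axial profiles sum rows and locate bands", {
  data <- array(0, c(40, 30, 1))
  data[11:21, , 1] <- 2   # uniform band, rows 10-20 (0-based)
  avg <- new("SideAverageImage", data = data, channels = "cis",
             pixelSizeNm = 45, nAveraged = 1L, axialYNm = c(cis = 15 * 45))
  p <- axialProfile(avg, "cis")
  expect_equal(p$intensity[11:21], rep(60, 11))
  expect_equal(sum(p$intensity > 0), 11)
  expect_equal(p$axial_nm[which.max(p$intensity)], 10 * 45)
})

test_that("axial Gaussian fits find the peak centre", {
  x <- seq(0, 2000, by = 45)
  clean <- data.frame(axial_nm = x,
                      intensity = 1.5 + 4 * exp(-(x - 300)^2 / (2 * 130^2)))
  f <- fitAxialGaussian(clean)
  expect_lt(abs(f@centerNm - 300), 1)
  expect_equal(f@baseline, 1.5, tolerance = 1e-3)
  set.seed(8)
  noisy <- clean
  noisy$intensity <- noisy$intensity + rnorm(length(x), 0, 0.05)
  expect_lt(abs(fitAxialGaussian(noisy)@centerNm - 300), 5)
  flat <- data.frame(axial_nm = x, intensity = rep(2, length(x)))
  expect_error(fitAxialGaussian(flat), "peak|converge")
})

test_that("marker distances are signed and antisymmetric", {
  a <- new("GaussianPeakFit", centerNm = 100, widthNm = 100, amplitude = 1,
           baseline = 0, adjR2 = 1)
  b <- new("GaussianPeakFit", centerNm = 400, widthNm = 100, amplitude = 1,
           baseline = 0, adjR2 = 1)
  expect_equal(markerDistance(a, b), 300)
  expect_equal(markerDistance(b, a), -300)
  expect_equal(markerDistance(a, a), 0)
})

test_that("simulated 300 nm stacks measure 300±10 nm by side averaging", {
  sim <- simulateSideViewStack(c(giantin = 150, cis = 0, trans = 300),
                               nImages = 20, seed = 5)
  avg <- sideAverage(sim$stack)
  d <- markerDistance(fitAxialGaussian(axialProfile(avg, "cis")),
                      fitAxialGaussian(axialProfile(avg, "trans")))
  expect_lt(abs(d - 300), 10)
})

test_that("side-average LQs track the prescribed cargo position", {
  for (lq in c(0.2, 0.7)) {
    sim <- simulateSideViewStack(
      c(giantin = 150, cis = 0, trans = 300, cargo = 300 * lq),
      nImages = 20, seed = 31)
    ax <- axialPositions(sideAverage(sim$stack))
    expect_lt(abs(lqSide(ax["cargo"], ax["cis"], ax["trans"]) - lq), 0.05)
  }
})

test_that("en-face averaging centres rings and preserves symmetry", {
  sim <- simulateEnFaceStack(nImages = 12, radiusJitter = 0, noise = FALSE,
                             seed = 6)
  ea <- enFaceAverage(sim$images, sim$annotations)
  expect_equal(ea$nAveraged, 12)
  # compare to an ideally centred noiseless single ring
  ref <- simulateEnFaceStack(nImages = 1, offsetMaxPx = 0,
                             radiusJitter = 0, noise = FALSE, seed = 1)
  er <- enFaceAverage(ref$images, ref$annotations)
  for (k in 1:2) {
    d <- ea$image[, , k] - er$image[, , k]
    expect_lt(sqrt(mean(d^2)), 0.05 * max(er$image[, , k]))
  }
  # zero-radius annotations are skipped, not fatal
  ann <- sim$annotations; ann$r[1] <- 0
  ea2 <- enFaceAverage(sim$images, ann)
  expect_equal(ea2$nSkipped, 1)
  expect_equal(ea2$nAveraged, 11)
})

test_that("radial profiles peak where the structure lives", {
  # thin ring of radius R peaks at normalized radius 1
  h <- 81; w <- 81; R <- 20
  xs <- matrix(rep(0:(w - 1), each = h), h); ys <- matrix(rep(0:(h - 1), w), h)
  r <- sqrt((xs - 40)^2 + (ys - 40)^2)
  ring <- exp(-(r - R)^2 / 2)
  pr <- radialMeanProfile(ring, c(40, 40), R)
  expect_equal(pr$radius_norm[1], 0)
  expect_equal(pr$radius_norm[which.max(pr$intensity)], 1, tolerance = 0.03)
  # centred Gaussian spot: maximum at the centre
  spot <- exp(-r^2 / (2 * 6^2))
  ps <- radialMeanProfile(spot, c(40, 40), R)
  expect_equal(ps$radius_norm[which.max(ps$intensity)], 0)
  expect_true(all(diff(ps$intensity[1:15]) < 0))
  # uniform disk: half-maximum crossing near the disk edge
  disk <- 1 * (r <= R)
  pd <- radialMeanProfile(disk, c(40, 40), R)
  cross <- pd$radius_norm[min(which(pd$intensity < 0.5))]
  expect_lt(abs(cross - 1), 0.1)
  expect_error(radialMeanProfile(disk, c(40, 40), 0), "positive")
})
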