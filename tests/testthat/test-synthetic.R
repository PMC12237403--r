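test_that("identical config and seed give bit-identical fields", {
  cfg <- simulationConfig(nStacks = 5, seed = 42)
  a <- simulateMinistackField(cfg)
  b <- simulateMinistackField(cfg)
  expect_identical(a$image@data, b$image@data)
  expect_identical(a$truth, b$truth)
  c <- simulateMinistackField(simulationConfig(nStacks = 5, seed = 43))
  expect_false(identical(a$image@data, c$image@data))
  bead <- simulateBeadField(cfg)
  expect_identical(bead$image@data, simulateBeadField(cfg)$image@data)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulateMinistackField(simulationConfig(nStacks = 3, seed = 7)))
  expect_identical(runif(1), before)
})

test_that("ground-truth geometry places cargo at the prescribed LQ", {
  for (lq in c(0, 0.4, 1)) {
    sim <- simulateMinistackField(
      simulationConfig(nStacks = 4, cargoLqTrue = lq, noise = FALSE,
                       seed = 3))
    for (id in 1:4)
      expect_equal(truthLQ(sim$truth, id), lq, tolerance = 1e-6)
  }
  # lq 0: cargo coincides with the cis spot; lq 1: with the trans spot
  sim0 <- simulateMinistackField(
    simulationConfig(nStacks = 2, cargoLqTrue = 0, noise = FALSE, seed = 5))
  t0 <- sim0$truth
  expect_equal(t0[t0$channel == "cargo", c("x_nm", "y_nm")],
               t0[t0$channel == "cis", c("x_nm", "y_nm")],
               tolerance = 1e-9, ignore_attr = TRUE)
  sim1 <- simulateMinistackField(
    simulationConfig(nStacks = 2, cargoLqTrue = 1, noise = FALSE, seed = 5))
  t1 <- sim1$truth
  expect_equal(t1[t1$channel == "cargo", c("x_nm", "y_nm")],
               t1[t1$channel == "trans", c("x_nm", "y_nm")],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rendered spots conserve the configured photon count", {
  # noiseless single spot integrates to photonScale
  cfg <- simulationConfig(imageShape = c(64L, 64L), nStacks = 1L,
                          axisLengthNm = 0.001, cargoLqTrue = 0,
                          backgroundLevel = 0, readNoiseSd = 0,
                          noise = FALSE, seed = 1)
  sim <- simulateMinistackField(cfg)
  expect_equal(sum(channelMatrix(sim$image, "cis")), 5000, tolerance = 5e-3)
  # with Poisson noise, the mean over 100 repeats stays within sampling error
  tot <- vapply(1:100, function(s) {
    cfg@seed <- s; cfg@noise <- TRUE
    sum(channelMatrix(simulateMinistackField(cfg)$image, "cis"))
  }, numeric(1))
  z <- (mean(tot) - 5000) / (sd(tot) / sqrt(length(tot)))
  expect_lt(abs(z), 4)
})

test_that("overcrowded fields fail with the density limit named", {
  cfg <- simulationConfig(imageShape = c(64L, 64L), nStacks = 50L, seed = 1)
  expect_error(simulateMinistackField(cfg), "separation")
})

test_that("LQ series follow the kinetic model exactly when noiseless", {
  tp <- kineticTimepoints
  s <- simulateLQSeries(1.0, 1.2, 8, tp, noiseSd = 0, seed = 1)
  expect_equal(s$mean_lq, lqKinetic(tp, 1.0, 1.2, 8), tolerance = 1e-12)
  expect_equal(s$sem_lq, rep(0, length(tp)))
  # asymptote: LQ approaches y0
  late <- simulateLQSeries(1.0, 1.2, 8, c(1, 1e6), noiseSd = 0, seed = 1)
  expect_equal(late$mean_lq[2], 1.0, tolerance = 1e-9)
  expect_error(simulateLQSeries(1, 1, 8, numeric(0)), "non-empty")
  expect_error(simulateLQSeries(1, 1, 8, c(10, 5)), "increasing")
})

test_that("decay traces match the exponential at key points", {
  tr <- simulateDecayTrace(10, 100, 10, durationMin = 40, dtMin = 10,
                           noiseSd = 0)
  expect_equal(tr$intensity[tr$t_min == 0], 110)
  expect_equal(tr$intensity[tr$t_min == 10], 10 + 100 / exp(1),
               tolerance = 1e-12)
  expect_error(simulateDecayTrace(10, 100, 10, 40, dtMin = 0), "dtMin")
  expect_error(simulateDecayTrace(10, 100, -1, 40), "t1Min")
})

test_that("side-view copies without jitter reproduce a single template", {
  one <- simulateSideViewStack(nImages = 1, rotate = FALSE,
                               scaleJitter = 0, noise = FALSE, seed = 1)
  many <- simulateSideViewStack(nImages = 6, rotate = FALSE,
                                scaleJitter = 0, noise = FALSE, seed = 1)
  avgOne <- sideAverage(one$stack)
  avgMany <- sideAverage(many$stack)
  # copies differ only by sub-pixel placement; after alignment the average
  # must match the single template to interpolation accuracy
  rms <- sqrt(mean((avgMany@data - avgOne@data)^2))
  expect_lt(rms, 0.02 * max(avgOne@data))
  ann <- many$stack@annotations
  expect_true(all((ann$x2 - ann$x1)^2 + (ann$y2 - ann$y1)^2 > 0))
})
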