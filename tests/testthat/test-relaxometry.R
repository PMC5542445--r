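test_that("signal model evaluates the saturation-recovery expression", {
  # ideal saturation limit
  expect_equal(modelSignal(1000, 800, 0, t = 800, tr = 1500),
               1000 * (1 - exp(-1)), tolerance = 1e-12)
  # frozen independent evaluation of the full expression
  expect_equal(modelSignal(1000, 800, 0.2, t = 1200, tr = 1500),
               722.756815, tolerance = 1e-8)
  # both exponentials vanish: signal -> S0 within 0.01%
  expect_equal(modelSignal(1000, 800, 0.2, t = 5e5, tr = 5e4), 1000,
               tolerance = 1e-4)
  expect_error(modelSignal(1000, 800, 0.2, t = -5, tr = 1500), "positive")
})

test_that("voxel fit recovers its generator on noiseless data", {
  d <- c(77, 200, 350, 500, 1200)
  s <- modelSignal(1000, 1200, 0, d, 1500)
  f <- fitVoxel(s, d, 1500)
  expect_lt(abs(f@t1 - 1200) / 1200, 0.001)
  expect_true(f@converged)

  # non-finite input and too few points are errors
  expect_error(fitVoxel(c(1, NA, 3), c(77, 200, 350), 1500), "non-finite")
  expect_error(fitVoxel(c(1, 2), c(77, 200), 1500), "at least 3")
  f2 <- fitVoxel(modelSignal(900, 700, 0.1, c(200, 1200), 1500),
                 c(200, 1200), 1500, bFixed = 0.1)
  expect_lt(abs(f2@t1 - 700) / 700, 1e-4)
})

test_that("LM solution matches the dense grid-search oracle", {
  d <- c(77, 200, 350, 500, 1200)
  s <- modelSignal(800, 600, 0.25, d, 1500)
  basis <- srOracleBasis(d, 1500, t1Grid = seq(100, 3000, by = 1),
                         bGrid = seq(0, 0.45, by = 0.005))
  g <- srGridOracle(s, d, 1500, Fmat = basis)
  f <- fitVoxel(s, d, 1500)
  expect_lte(abs(f@t1 - g[["t1"]]), 1)
  expect_lte(abs(f@b - g[["b"]]), 0.005)
})

test_that("B = 0 fits match log-linear inversion to 0.01%", {
  d <- c(77, 200, 350, 500, 1200)
  set.seed(11)
  for (k in 1:20) {
    t1 <- runif(1, 300, 2500); s0 <- runif(1, 500, 1500)
    s <- modelSignal(s0, t1, 0, d, 1500)
    # independent closed form: regress log(S0 - s) on t
    t1Log <- -1 / coef(lm(log(s0 - s) ~ d))[[2]]
    f <- fitVoxel(s, d, 1500)
    expect_lt(abs(f@t1 - t1Log) / t1Log, 1e-4)
  }
})

test_that("map fitting honours masks, passes and degenerate inputs", {
  ser <- blockSeries(t1 = 1100, b = 0)
  # B == 0 phantom: multi-pass equals single pass exactly
  m1 <- fitMap(ser, passes = 1)
  m3 <- fitMap(ser, passes = 3)
  expect_equal(t1Map(m3), t1Map(m1), tolerance = 1e-6)

  # all-background mask: no fit attempted
  empty <- fitMap(ser, mask = array(FALSE, gridDim(ser)))
  expect_true(all(is.na(t1Map(empty))))

  short <- new("ImageSeries", volumes = ser@volumes[, , , 1:2, drop = FALSE],
               delays = c(77, 200), tr = 1500,
               voxelSize = voxelSize(ser), fovOrigin = fovOrigin(ser))
  expect_error(fitMap(short), "at least 3 delays")
})

test_that("multi-pass B smoothing lowers T1 error under noise", {
  # smooth-B1 block at 2% noise: 3-pass RMSE below 1-pass RMSE (averaged
  # over seeds)
  rmse <- function(map, t1) sqrt(mean((t1Map(map) - t1)^2, na.rm = TRUE))
  d1 <- d3 <- numeric(4)
  for (k in 1:4) {
    ser <- blockSeries(t1 = 1100, b = 0.2, noiseSigma = 0.02, seed = 100 + k)
    m <- fitMap(ser, passes = 3, noiseSd = 20, keepPasses = TRUE)
    pass <- attr(m, "passT1")
    d1[k] <- sqrt(mean((pass[[1]] - 1100)^2))
    d3[k] <- rmse(m, 1100)
  }
  expect_lt(mean(d3), mean(d1))
})

test_that("R1 conversion and delta-R1 maps follow their definitions", {
  t1 <- array(c(1000, 500, 357.142857, -3), c(4, 1, 1))
  expect_message(r1 <- r1FromT1(t1), "nonpositive")
  expect_equal(r1[1:3], c(1, 2, 2.8), tolerance = 1e-6)
  expect_true(is.na(r1[4]))

  gt <- buildGroundTruth(smallPlaqueSpec(noiseSigma = 0))
  ser <- simulateSRSeries(gt, noiseSigma = 0)
  mask <- compartmentLabels(gt) > 0L
  pre <- fitMap(ser, passes = 1, mask = mask)

  # r1 * t1 == 1000 within the mask (self-consistency)
  expect_equal(r1Map(pre)[pre@mask] * t1Map(pre)[pre@mask],
               rep(1000, sum(pre@mask)), tolerance = 1e-9)

  # post == pre gives an identically zero difference
  d0 <- deltaR1(pre, pre)
  expect_true(all(deltaR1Values(d0)[d0@mask] == 0))

  # grid mismatch demands resampling
  shifted <- pre; shifted@fovOrigin <- pre@fovOrigin + 1
  expect_error(deltaR1(pre, shifted), "different grids")

  # noiseless phantom: mean plaque delta-R1 equals r1 * C within 1%,
  # and the agent-free wall is near zero
  post <- fitMap(simulateSRSeries(gt, noiseSigma = 0, state = "post"),
                 passes = 1, mask = mask)
  dm <- deltaR1(pre, post)
  plq <- compartmentLabels(gt) == 3L
  rois <- roiSet(plq, voxelSize(gt), fovOrigin(gt))
  expect_equal(roiMeanDeltaR1(dm, rois), 1.8, tolerance = 0.01)
  wall <- compartmentLabels(gt) == 2L
  expect_lt(abs(mean(deltaR1Values(dm)[wall])), 1e-6)

  # uniform ROI mean and the empty-ROI error
  u <- dm; u@deltaR1[u@mask] <- 2
  expect_identical(roiMeanDeltaR1(u, rois), 2)
  expect_error(roiMeanDeltaR1(dm, roiSet(array(FALSE, gridDim(gt)),
                                         voxelSize(gt), fovOrigin(gt))),
               "empty ROI")
})
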