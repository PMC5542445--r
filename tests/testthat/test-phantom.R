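test_that("contrast agent shortens T1 per R1_post = R1_pre + r1 * C", {
  # no agent anywhere: post equals pre exactly
  spec0 <- phantomSpec(gdConcentration = c(background = 0, blood = 0,
                                           wall = 0, plaque = 0),
                       plaques = data.frame(cx = 2.9, cy = 2.2, cz = 1.1,
                                            ax = 0.6, ay = 0.5, az = 0.5))
  gt0 <- buildGroundTruth(spec0)
  expect_identical(t1Map(gt0, "post"), t1Map(gt0, "pre"))

  # hand arithmetic: plaque T1 1000 ms, C 0.1 mmol/L, r1 18 -> 357.14 ms
  spec <- smallPlaqueSpec()
  spec@t1Tissue[["plaque"]] <- 1000
  gt <- buildGroundTruth(spec)
  plq <- compartmentLabels(gt) == compartmentCodes()[["plaque"]]
  expect_true(any(plq))
  expect_equal(unique(t1Map(gt, "post")[plq]), 1000 / 2.8, tolerance = 1e-12)
  expect_equal(unique(1000 / t1Map(gt, "post")[plq] -
                        1000 / t1Map(gt, "pre")[plq]), 1.8,
               tolerance = 1e-12)

  # Gd linearity across a range of concentrations
  for (cgd in c(0.01, 0.05, 0.3, 1)) {
    s <- smallPlaqueSpec(cGd = cgd)
    g <- buildGroundTruth(s)
    m <- compartmentLabels(g) == 3L
    dR1 <- 1000 / t1Map(g, "post")[m] - 1000 / t1Map(g, "pre")[m]
    expect_equal(unique(round(dR1, 10)), 18 * cgd, tolerance = 1e-9)
  }
})

test_that("voxelized plaque volume approximates analytic ellipsoid volume", {
  # two non-overlapping ellipsoids placed away from the lumen
  ell <- data.frame(cx = c(1.6, 6.0), cy = c(1.6, 6.0), cz = c(1.2, 1.2),
                    ax = c(0.7, 0.8), ay = c(0.6, 0.7), az = c(0.55, 0.6))
  spec <- phantomSpec(gridShape = c(48L, 48L, 14L),
                      voxelSize = c(0.18, 0.18, 0.18),
                      lumenRadius = 0.3, wallThickness = 0.1,
                      vesselCenter = c(4, 1), plaques = ell)
  gt <- suppressWarnings(buildGroundTruth(spec))
  vAnalytic <- sum(4 / 3 * pi * ell$ax * ell$ay * ell$az)
  expect_lt(abs(plaqueVolume(gt) - vAnalytic) / vAnalytic, 0.05)

  # a blob fully outside the grid is an error naming the blob
  bad <- phantomSpec(plaques = data.frame(cx = 50, cy = 50, cz = 50,
                                          ax = 0.3, ay = 0.3, az = 0.3))
  expect_error(buildGroundTruth(bad), "blob 1.*outside the grid")
})

test_that("simulated series follows the signal model and delay scheme", {
  spec <- phantomSpec(b1Mean = 0, b1Amplitude = 0, noiseSigma = 0)
  gt <- buildGroundTruth(spec)

  # saturation-recovery plateau: t and tr >> T1 recovers S0 to 0.01%
  long <- simulateSRSeries(gt, delays = 25000, tr = 25000, noiseSigma = 0)
  blood <- compartmentLabels(gt) == 1L
  expect_equal(long@volumes[, , , 1][blood],
               rep(1000, sum(blood)), tolerance = 1e-4)

  # canonical protocol: five volumes in the given order
  ser <- simulateSRSeries(gt, delays = c(77, 200, 350, 500, 1200), tr = 1500,
                          noiseSigma = 0)
  expect_identical(delays(ser), c(77, 200, 350, 500, 1200))
  expect_identical(dim(ser@volumes)[4], 5L)
  for (i in 1:5)
    expect_equal(ser@volumes[, , , i][blood],
                 rep(modelSignal(1000, 2200, 0, delays(ser)[i], 1500),
                     sum(blood)), tolerance = 1e-12)

  # determinism: same seed twice is bit-identical
  s1 <- simulateSRSeries(gt, seed = 99, noiseSigma = 0.02)
  s2 <- simulateSRSeries(gt, seed = 99, noiseSigma = 0.02)
  expect_identical(s1@volumes, s2@volumes)
  expect_error(simulateSRSeries(gt, noiseSigma = -0.1), "noiseSigma")
})

test_that("magnitude noise approaches sigma * S0 at high SNR", {
  spec <- phantomSpec(b1Mean = 0, b1Amplitude = 0)
  gt <- buildGroundTruth(spec)
  blood <- which(compartmentLabels(gt) == 1L)[1]
  draws <- vapply(1:300, function(k)
    simulateSRSeries(gt, delays = 1200, tr = 1500, noiseSigma = 0.02,
                     seed = k)@volumes[, , , 1][blood], numeric(1))
  expect_equal(sd(draws), 20, tolerance = 0.15)
})

test_that("labels are invariant to B1 parameters and noise", {
  a <- buildGroundTruth(smallPlaqueSpec(seed = 5))
  s2 <- smallPlaqueSpec(seed = 5)
  s2@b1Mean <- 0.25; s2@b1Amplitude <- 0.05; s2@noiseSigma <- 0.1
  b <- buildGroundTruth(s2)
  expect_identical(compartmentLabels(a), compartmentLabels(b))
  expect_identical(plaqueVolume(a), plaqueVolume(b))
})

test_that("anatomy simulation resamples geometry and preserves contrast", {
  gt <- buildGroundTruth(smallPlaqueSpec(noiseSigma = 0))

  # factor 1, zero shift: grid identical to the SR grid
  an <- simulateAnatomy(gt, ti = 250, tr = 650, hiResFactor = 1,
                        noiseSigma = 0, fovShift = c(0, 0, 0))
  expect_identical(gridDim(an), gridDim(gt))
  expect_equal(voxelSize(an), voxelSize(gt))
  expect_equal(fovOrigin(an), fovOrigin(gt))

  # refined grid: each axis subdivided, FOV span preserved
  an2 <- simulateAnatomy(gt, hiResFactor = 2, noiseSigma = 0)
  expect_identical(gridDim(an2), 2L * gridDim(gt))
  expect_equal(voxelSize(an2), voxelSize(gt) / 2)

  # post-contrast plaque brighter than wall at matched S0
  anPost <- simulateAnatomy(gt, ti = 250, tr = 650, noiseSigma = 0,
                            state = "post", fovShift = c(0, 0, 0))
  lab <- compartmentLabels(gt)
  expect_gt(mean(anPost@volumes[, , , 1][lab == 3]),
            mean(anPost@volumes[, , , 1][lab == 2]))
})

test_that("paired studies bundle the acquisitions and round-trip to disk", {
  # wildtype preset: no plaque anywhere
  wt <- phantomPreset("wildtype", 9, seed = 3)
  expect_identical(plaqueVolume(buildGroundTruth(wt)), 0)

  # progression preset ladder grows monotonically (no animal variability)
  vols <- vapply(c(9, 13, 17, 21), function(w)
    plaqueVolume(buildGroundTruth(
      phantomPreset("progression", w, seed = 3, variability = 0))),
    numeric(1))
  expect_true(all(diff(vols) > 0))

  dir <- withr::local_tempdir()
  study <- makePairedStudy(smallPlaqueSpec(), outDir = dir)
  expect_s4_class(study, "PairedStudy")
  reread <- readImageSeries(file.path(dir, "sr_pre"))
  expect_equal(reread@volumes, study@pre@volumes, tolerance = 1e-6)
  expect_identical(delays(reread), delays(study@pre))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$plaque_volume_mm3, plaqueVolume(study@truth))
})
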