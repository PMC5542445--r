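test_that("total plaque volume sums per-slice areas times slice thickness", {
  vs <- c(0.18, 0.18, 0.18)
  empty <- roiSet(array(FALSE, c(4, 4, 3)), vs)
  expect_identical(totalPlaqueVolume(empty)@tpv, 0)

  one <- array(FALSE, c(4, 4, 3)); one[2, 3, 2] <- TRUE
  res <- totalPlaqueVolume(roiSet(one, vs))
  expect_equal(res@tpv, 5.832e-3, tolerance = 1e-12)
  expect_equal(res@perSliceArea, c(0, 0.18^2, 0))

  sph <- sphereMask(r = 0.9, vox = 0.18)
  vol <- totalPlaqueVolume(roiSet(sph, vs))@tpv
  expect_lt(abs(vol - 4 / 3 * pi * 0.9^3) / (4 / 3 * pi * 0.9^3), 0.05)

  # additive over disjoint sets and invariant to slice order
  two <- one; two[1, 1, 1] <- TRUE
  expect_equal(totalPlaqueVolume(roiSet(two, vs))@tpv,
               2 * res@tpv, tolerance = 1e-12)
  perm <- two[, , c(3, 1, 2)]
  expect_equal(totalPlaqueVolume(roiSet(perm, vs))@tpv,
               totalPlaqueVolume(roiSet(two, vs))@tpv)
})

test_that("threshold segmentation is monotone and prunes small components", {
  set.seed(21)
  vol <- array(rnorm(16 * 16 * 6, 10, 1), c(16, 16, 6))
  vol[4:9, 4:9, 2:4] <- 100          # big blob (~108 voxels)
  vol[14, 14, 6] <- 100              # isolated voxel
  vs <- c(0.18, 0.18, 0.22)

  expect_warning(res <- thresholdSegment(vol, 1e5, voxelSize = vs),
                 "outside")
  expect_identical(sum(imageMask(res)), 0L)

  seg <- thresholdSegment(vol, 50, minComponent = 5, voxelSize = vs)
  expect_identical(sum(imageMask(seg)), 6L * 6L * 3L)  # singleton pruned
  segAll <- thresholdSegment(vol, 50, minComponent = 1, voxelSize = vs)
  expect_identical(sum(imageMask(segAll)), 6L * 6L * 3L + 1L)

  # raising the threshold never grows the segmented volume
  vols <- vapply(c(5, 20, 50, 99, 101), function(th)
    sum(imageMask(suppressWarnings(
      thresholdSegment(vol, th, voxelSize = vs)))), integer(1))
  expect_true(all(diff(vols) <= 0))

  # 26-connectivity joins diagonal neighbours into one component
  dv <- array(0, c(5, 5, 5)); dv[2, 2, 2] <- 1; dv[3, 3, 3] <- 1
  segD <- thresholdSegment(dv, 0.5, minComponent = 2, voxelSize = vs)
  expect_identical(sum(imageMask(segD)), 2L)
})

test_that("ROI transfer maps masks through world space", {
  sph <- sphereMask(r = 0.9, vox = 0.18)
  src <- roiSet(sph, rep(0.18, 3), c(0, 0, 0))

  # identity on matched grids
  idGrid <- list(dim = dim(sph), voxelSize = rep(0.18, 3),
                 fovOrigin = c(0, 0, 0))
  expect_identical(imageMask(transferROIs(src, idGrid)), imageMask(src))

  # integer-voxel translation preserves the voxel count
  shGrid <- list(dim = dim(sph), voxelSize = rep(0.18, 3),
                 fovOrigin = c(0.18, -0.36, 0.18))
  expect_identical(sum(imageMask(transferROIs(src, shGrid))),
                   sum(imageMask(src)))

  # changed slice thickness (0.18 iso -> 0.18 x 0.18 x 0.22): volume
  # preserved within one slice-voxel layer
  tg <- list(dim = c(dim(sph)[1:2], ceiling(dim(sph)[3] * 0.18 / 0.22)),
             voxelSize = c(0.18, 0.18, 0.22), fovOrigin = c(0, 0, 0))
  vSrc <- totalPlaqueVolume(src)@tpv
  vTgt <- totalPlaqueVolume(transferROIs(src, tg))@tpv
  layer <- max(totalPlaqueVolume(src)@perSliceArea) * 0.22
  expect_lt(abs(vTgt - vSrc), layer)

  # transfer there and back loses at most the boundary layer
  back <- transferROIs(transferROIs(src, tg), idGrid)
  symDiff <- sum(xor(imageMask(back), imageMask(src)))
  erode3 <- function(m) {
    out <- m
    for (ax in 1:3) for (s in c(-1, 1)) {
      sh <- array(FALSE, dim(m))
      idx <- seq_len(dim(m)[ax])
      take <- pmin(pmax(idx + s, 1L), dim(m)[ax])
      sh <- switch(ax, m[take, , , drop = FALSE], m[, take, , drop = FALSE],
                   m[, , take, drop = FALSE])
      out <- out & sh
    }
    out
  }
  boundary <- sum(imageMask(src)) - sum(erode3(imageMask(src)))
  expect_lte(symDiff, boundary)

  # disjoint fields of view are an error
  farGrid <- list(dim = c(4L, 4L, 4L), voxelSize = rep(0.18, 3),
                  fovOrigin = c(100, 100, 100))
  expect_error(transferROIs(src, farGrid), "do not overlap")
})

test_that("interobserver agreement behaves like paired readers", {
  vs <- c(0.18, 0.18, 0.22)
  mkCase <- function(n) {   # growing square ROI ladder
    m <- array(FALSE, c(20, 20, 4))
    m[seq_len(n) + 4, seq_len(n) + 4, 2:3] <- TRUE
    roiSet(m, vs)
  }
  ladder <- lapply(2:9, mkCase)

  # identical ROI lists correlate perfectly
  expect_equal(interobserverAgreement(ladder, ladder)@r, 1, tolerance = 1e-12)

  # a systematically dilating reader stays near r = 1 with offset TPV
  readerB <- lapply(ladder, function(x) {
    m <- imageMask(x)
    for (k in seq_len(dim(m)[3])) m[, , k] <- plaqueR1:::.morph2d(m[, , k], TRUE)
    roiSet(m, vs)
  })
  resB <- interobserverAgreement(ladder, readerB)
  expect_gt(resB@r, 0.95)
  expect_gt(mean(vapply(readerB, function(r) totalPlaqueVolume(r)@tpv,
                        numeric(1))),
            mean(vapply(ladder, function(r) totalPlaqueVolume(r)@tpv,
                        numeric(1))))

  # unrelated random readers: |r| is small for most seeds
  rnull <- vapply(1:60, function(sd_) {
    set.seed(sd_)
    mk <- function() lapply(1:20, function(i) {
      m <- array(FALSE, c(12, 12, 3))
      m[sample(length(m), sample(20, 1))] <- TRUE
      roiSet(m, vs)
    })
    a <- mk(); b <- mk()
    interobserverAgreement(a, b)@r
  }, numeric(1))
  expect_gte(mean(abs(rnull) < 0.45), 0.88)

  expect_error(interobserverAgreement(ladder[1:2], ladder[1:2]),
               "at least 3")
  expect_error(interobserverAgreement(ladder, ladder[1:3]), "paired")
})
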