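test_that("mean and SEM follow the textbook definitions", {
  ms <- meanSEM(c(2, 4, 6))
  expect_equal(ms[["mean"]], 4)
  expect_equal(ms[["sem"]], 2 / sqrt(3), tolerance = 1e-12)
  expect_identical(meanSEM(rep(7, 5))[["sem"]], 0)
  expect_equal(meanSEM(c(6, 2, 4)), meanSEM(c(2, 4, 6)))
  expect_error(meanSEM(3), "at least 2")
})

test_that("Mann-Whitney exact branch matches exhaustive enumeration", {
  # complete separation, 5 vs 5: p = 2 / choose(10, 5)
  sep <- mannWhitney(1:5, 6:10)
  expect_true(sep$exact)
  expect_equal(sep$p, 2 / 252, tolerance = 1e-12)

  # identical multisets: p at (or near, under tie handling) 1
  same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p, 0.95)

  # symmetry in the group order
  set.seed(31)
  a <- rnorm(5); b <- rnorm(7) + 1
  expect_equal(mannWhitney(a, b)$p, mannWhitney(b, a)$p, tolerance = 1e-12)
  expect_error(mannWhitney(numeric(), 1:3), "nonempty")

  # exact branch equals the brute-force permutation oracle for all
  # group sizes up to 5 vs 5 (tie-free draws)
  set.seed(37)
  for (na in 2:5) for (nb in 2:5) {
    x <- sample(seq(1, 200), na + nb)  # distinct values, no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    got <- mannWhitney(a, b)
    oracle <- mwEnumOracle(a, b)
    expect_true(got$exact)
    expect_equal(got$p, oracle$p, tolerance = 1e-12,
                 label = sprintf("p for n=(%d,%d)", na, nb))
    expect_equal(got$U, oracle$U, label = sprintf("U for n=(%d,%d)", na, nb))
  }
})

test_that("Pearson correlation and its strength bands match convention", {
  x <- 1:10
  expect_equal(pearsonCorrelation(x, 2 * x + 1)@r, 1, tolerance = 1e-12)
  expect_equal(pearsonCorrelation(x, -x)@r, -1, tolerance = 1e-12)

  # affine invariance; sign flips with negative slope
  set.seed(5)
  u <- rnorm(20); v <- rnorm(20)
  r0 <- pearsonCorrelation(u, v)@r
  expect_equal(pearsonCorrelation(3 * u - 2, v)@r, r0, tolerance = 1e-12)
  expect_equal(pearsonCorrelation(-u, v)@r, -r0, tolerance = 1e-12)

  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearsonCorrelation(1:2, 2:3), "at least 3")

  # the p-value is the t-transform with n - 2 df
  ct <- pearsonCorrelation(u, v)
  tt <- ct@r * sqrt((20 - 2) / (1 - ct@r^2))
  expect_equal(ct@p, 2 * pt(-abs(tt), 18), tolerance = 1e-9)

  # strength categories, boundaries closed at the top of the lower band
  expect_identical(classifyCorrelation(0.85), "strong")
  expect_identical(classifyCorrelation(0.71), "substantial")
  expect_identical(classifyCorrelation(-0.3), "fair")
  expect_identical(classifyCorrelation(-0.4), "fair")
  expect_identical(classifyCorrelation(0.8), "substantial")
  expect_identical(classifyCorrelation(0.6), "moderate")
  expect_identical(classifyCorrelation(0.2), "almost non-existent")
  for (r in c(-0.95, -0.5, 0.33, 0.77))
    expect_identical(classifyCorrelation(r), classifyCorrelation(-r))
  expect_error(classifyCorrelation(1.2), "exceed")
})

test_that("group trajectories summarize weeks with sequential tests", {
  mkTab <- function(means, group) do.call(rbind, lapply(seq_along(means),
    function(i) data.frame(animal_id = 1:5, group = group,
                           week = c(9, 13, 17, 21)[i],
                           tpv = means[i] + seq(-0.02, 0.02, length.out = 5))))
  tab <- mkTab(c(0.44, 0.63, 1.36, 1.91), "progression")
  tr <- groupTrajectory(tab, "tpv")
  expect_identical(nrow(tr), 4L)
  expect_true(all(diff(tr$mean) > 0))
  expect_true(is.na(tr$p_vs_prev[1]))
  expect_true(all(tr$significant[-1]))   # separated ladder: p = 2/252 < 0.05

  # equal groups show no significance
  flat <- mkTab(c(1, 1, 1, 1), "progression")
  flat$tpv <- flat$tpv + rep(seq(-0.02, 0.02, length.out = 5), 4)
  trFlat <- groupTrajectory(flat, "tpv")
  expect_true(all(!trFlat$significant))

  # wildtype: all plaque measures zero, summaries degenerate but defined
  wt <- mkTab(c(0, 0, 0, 0), "wildtype"); wt$tpv <- 0
  trWt <- groupTrajectory(wt, "tpv")
  expect_true(all(trWt$mean == 0))

  expect_error(groupTrajectory(tab, "nope"), "not found")
  expect_error(groupTrajectory(tab[tab$week == 9, ], "tpv"), "2 time points")
})
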