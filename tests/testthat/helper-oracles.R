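# Independent oracles and small fixture builders used across the suite.

# Dense grid search over (T1, B) with S0 eliminated by variable
# projection: for each grid point the optimal S0 is closed-form, so the
# argmin over the grid is an exhaustive least-squares oracle independent
# of the package's LM path.
srGridOracle <- function(signal, delays, tr,
                         t1Grid = seq(100, 3000, by = 1),
                         bGrid = seq(0, 0.45, by = 0.005),
                         Fmat = NULL) {
  if (is.null(Fmat)) Fmat <- srOracleBasis(delays, tr, t1Grid, bGrid)
  proj <- as.numeric(Fmat$F %*% signal)
  score <- proj^2 / Fmat$e
  i <- which.max(score)
  c(s0 = proj[i] / Fmat$e[i], t1 = Fmat$t1[i], b = Fmat$b[i])
}

srOracleBasis <- function(delays, tr, t1Grid = seq(100, 3000, by = 1),
                          bGrid = seq(0, 0.45, by = 0.005)) {
  g <- expand.grid(t1 = t1Grid, b = bGrid)
  n <- nrow(g)
  F <- matrix(NA_real_, n, length(delays))
  for (j in seq_along(delays)) {
    etr <- exp(-delays[j] / tr)
    F[, j] <- abs(1 - (1 - g$b) * exp(-delays[j] / g$t1) -
                    g$b * etr / (1 - g$b * etr))
  }
  list(F = F, e = rowSums(F^2), t1 = g$t1, b = g$b)
}

# Exhaustive Mann-Whitney enumeration: every assignment of the pooled
# observations to the two groups, two-tailed p as twice the smaller tail
# (capped at 1), matching the exact-test convention.
mwEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  uFor <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  uObs <- uFor(seq_len(na))
  us <- apply(utils::combn(n, na), 2, uFor)
  p <- 2 * min(mean(us <= uObs), mean(us >= uObs))
  list(U = uObs, p = min(p, 1))
}

# Small phantom with one wall-attached plaque blob, quick to simulate.
smallPlaqueSpec <- function(seed = 1L, noiseSigma = 0.02, cGd = 0.1,
                            gridShape = c(24L, 24L, 6L)) {
  ctr <- (gridShape[1:2] - 1) / 2 * 0.18
  phantomSpec(gridShape = gridShape,
              plaques = data.frame(cx = ctr[1] + 0.75, cy = ctr[2],
                                   cz = (gridShape[3] - 1) / 2 * 0.22,
                                   ax = 0.55, ay = 0.5, az = 0.45),
              gdConcentration = c(background = 0, blood = 0, wall = 0,
                                  plaque = cGd),
              noiseSigma = noiseSigma, seed = seed)
}

# Uniform single-compartment block series (for fit-accuracy studies).
blockSeries <- function(t1, b, s0 = 1000, noiseSigma = 0, seed = 1L,
                        dims = c(8L, 8L, 4L),
                        delays = c(77, 200, 350, 500, 1200), tr = 1500) {
  t1a <- array(t1, dims); ba <- array(b, dims)
  vols <- array(NA_real_, c(dims, length(delays)))
  set.seed(seed)
  sg <- noiseSigma * s0
  for (i in seq_along(delays)) {
    s <- modelSignal(s0, t1a, ba, delays[i], tr)
    vols[, , , i] <- if (sg > 0)
      sqrt((s + rnorm(length(s), 0, sg))^2 + rnorm(length(s), 0, sg)^2)
    else abs(s)
  }
  new("ImageSeries", volumes = vols, delays = delays, tr = tr,
      voxelSize = c(0.18, 0.18, 0.22), fovOrigin = c(0, 0, 0))
}

# Digitized sphere mask of radius r (mm) on an isotropic grid.
sphereMask <- function(r = 0.9, vox = 0.18, pad = 3L) {
  n <- 2L * (ceiling(r / vox) + pad) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * vox
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  array(d2 <= r^2, dim = c(n, n, n))
}
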