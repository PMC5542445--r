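## Pixel-wise saturation-recovery T1 relaxometry.
##
## Signal model (C fixed to 1 by default):
##   S(t) = S0 * [1 - (1-B) exp(-t/T1) - B exp(-t/TR) / (1 - B C exp(-t/TR))]
## B is the cosine of the effective saturation flip angle (B = 0 means
## perfect saturation, reducing the model to S0 (1 - exp(-t/T1))); C is
## the cosine of the excitation pulse.  Fitting is per voxel by
## Levenberg-Marquardt, optionally in several passes with neighbourhood
## smoothing of B between passes (the B1 field varies slowly in space).

#' Per-voxel result of one saturation-recovery fit
#'
#' @slot s0 equilibrium signal, a.u.
#' @slot t1 longitudinal relaxation time, ms.
#' @slot b saturation-efficiency parameter (dimensionless).
#' @slot c excitation-pulse parameter, fixed to 1 by default.
#' @slot residualNorm Euclidean norm of the final residuals, a.u.
#' @slot nIter iterations used.
#' @slot converged logical convergence flag.
#' @export
setClass("FitResult", representation(
  s0 = "numeric", t1 = "numeric", b = "numeric", c = "numeric",
  residualNorm = "numeric", nIter = "integer", converged = "logical"
))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: S0 = %.4g, T1 = %.4g ms, B = %.4g (C = %g)\n",
              object@s0, object@t1, object@b, object@c))
  cat(sprintf("  residual norm %.4g, %d iterations, converged: %s\n",
              object@residualNorm, object@nIter, object@converged))
})

#' Saturation-recovery signal model
#'
#' Evaluates
#' `S0 * (1 - (1 - B) exp(-t/T1) - B exp(-t/TR) / (1 - B C exp(-t/TR)))`,
#' vectorized over any argument.  With `b = 0` this reduces exactly to the
#' ideal-saturation form `S0 * (1 - exp(-t/T1))`.
#'
#' @param s0 equilibrium signal (a.u.).
#' @param t1 longitudinal relaxation time, ms.
#' @param b saturation-efficiency parameter in `[0, 1)`.
#' @param t saturation delay, ms (> 0).
#' @param tr repetition time, ms (> 0).
#' @param cParam excitation-pulse parameter; fixed to 1 by default.
#' @return Signal intensity, same shape as the broadcast arguments.
#' @export
#' @examples
#' modelSignal(1000, 800, 0, t = 800, tr = 1500)    # 1000 * (1 - exp(-1))
#' modelSignal(1000, 800, 0.2, t = 1200, tr = 1500)
modelSignal <- function(s0, t1, b, t, tr, cParam = 1) {
  if (any(t <= 0) || any(tr <= 0)) stop("t and tr must be positive (ms)")
  etr <- exp(-t / tr)
  den <- 1 - b * cParam * etr
  if (any(abs(den) < 1e-12))
    stop("singular model denominator: B * C * exp(-t/TR) == 1")
  s0 * (1 - (1 - b) * exp(-t / t1) - b * etr / den)
}

## residuals shared by the fitters.  Magnitude data are compared with
## the magnitude of the model: with imperfect saturation (B > 0) the
## signed model dips slightly below zero at very short delays, which a
## magnitude image folds upward.
.srResiduals <- function(p, signal, delays, tr, bFixed, cParam) {
  if (is.null(bFixed))
    signal - abs(modelSignal(p[1], p[2], p[3], delays, tr, cParam))
  else signal - abs(modelSignal(p[1], p[2], bFixed, delays, tr, cParam))
}

## analytic Jacobian of the residuals: the (T1, B) cost surface has a
## long flat ridge on which forward-difference derivatives are too
## inaccurate and stall the LM iteration short of the minimum
.srJacobian <- function(p, signal, delays, tr, bFixed, cParam) {
  s0 <- p[1]; t1 <- p[2]
  b <- if (is.null(bFixed)) p[3] else bFixed
  e1 <- exp(-delays / t1)
  u <- exp(-delays / tr)
  den <- 1 - b * cParam * u
  shape <- 1 - (1 - b) * e1 - b * u / den
  sgn <- ifelse(s0 * shape >= 0, 1, -1)
  dS0 <- shape
  dT1 <- -s0 * (1 - b) * e1 * delays / t1^2
  if (is.null(bFixed)) {
    dB <- s0 * (e1 - u / den^2)
    -sgn * cbind(dS0, dT1, dB)
  } else -sgn * cbind(dS0, dT1)
}

## one LM fit; returns c(s0, t1, b, residualNorm, nIter, converged)
.lmFitOne <- function(signal, delays, tr, init, bFixed = NULL, cParam = 1,
                      maxIter = 200L, ftol = 1e-8) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxIter, ftol = ftol)
  if (is.null(bFixed)) {
    p0 <- c(init[1], init[2], init[3])
    lower <- c(0, 1, 0); upper <- c(Inf, 10000, 0.99)
  } else {
    p0 <- c(init[1], init[2])
    lower <- c(0, 1); upper <- c(Inf, 10000)
  }
  ## iteration-cap warnings are redundant: non-convergence is reported
  ## through the converged flag
  fit <- suppressWarnings(
    minpack.lm::nls.lm(p0, lower = lower, upper = upper,
                       fn = .srResiduals, jac = .srJacobian,
                       signal = signal,
                       delays = delays, tr = tr, bFixed = bFixed,
                       cParam = cParam, control = ctrl))
  b <- if (is.null(bFixed)) fit$par[3] else bFixed
  c(fit$par[1], fit$par[2], b, sqrt(fit$deviance), fit$niter,
    as.numeric(fit$info %in% 1:4))
}

## data-driven T1 start: match the ratio s(t_min)/s(t_max) against the
## ideal-saturation recovery curve over a log-spaced T1 grid
.t1RatioInit <- function(signal, delays) {
  i1 <- which.min(delays); i2 <- which.max(delays)
  if (signal[i2] <= 0) return(1000)
  obs <- signal[i1] / signal[i2]
  grid <- exp(seq(log(30), log(8000), length.out = 60))
  theo <- (1 - exp(-delays[i1] / grid)) / (1 - exp(-delays[i2] / grid))
  grid[which.min(abs(theo - obs))]
}

## coarse (T1, B) grid with S0 eliminated by variable projection, used
## to start the LM fit in the global basin: the cost surface has a local
## minimum near the B = 0 bound for short-T1 voxels, so a single generic
## start is not reliable.
.makeFitGrid <- function(delays, tr, cParam = 1,
                         t1Grid = exp(seq(log(30), log(8000),
                                          length.out = 40)),
                         bGrid = seq(0, 0.6, by = 0.05)) {
  g <- expand.grid(t1 = t1Grid, b = bGrid)
  F_ <- t(vapply(seq_len(nrow(g)),
                 function(i) abs(modelSignal(1, g$t1[i], g$b[i], delays, tr,
                                             cParam)),
                 numeric(length(delays))))
  list(F = F_, t1 = g$t1, b = g$b, e = rowSums(F_^2))
}

## up to nStarts well-separated high-score grid points: the cost surface
## can hold several competing basins, and the coarse-grid winner is not
## always in the global one
.gridStarts <- function(signal, grid, nStarts = 3L) {
  proj <- as.numeric(grid$F %*% signal)
  score <- proj^2 / grid$e
  ord <- order(score, decreasing = TRUE)
  picked <- integer()
  for (i in ord) {
    if (length(picked) >= nStarts) break
    far <- all(abs(log(grid$t1[i] / grid$t1[picked])) > 0.25 |
                 abs(grid$b[i] - grid$b[picked]) > 0.075)
    if (!length(picked) || far) picked <- c(picked, i)
  }
  lapply(picked, function(i)
    c(max(proj[i] / grid$e[i], 0), grid$t1[i], min(grid$b[i], 0.99)))
}

## LM fit with automatic initialization; best deviance over the grid
## start plus a generic fallback start
.lmFitBest <- function(signal, delays, tr, bFixed = NULL, cParam = 1,
                       maxIter = 200L, ftol = 1e-8, grid = NULL) {
  s0g <- max(signal)
  if (is.null(bFixed)) {
    if (is.null(grid)) grid <- .makeFitGrid(delays, tr, cParam)
    starts <- c(.gridStarts(signal, grid), list(c(s0g, 1000, 0.1)))
  } else {
    ## 1-D variable-projection grid over T1 (S0 closed-form) for a start
    ## in the right basin; a bad S0/T1 start can strand LM at the T1
    ## lower bound
    t1Grid <- exp(seq(log(30), log(8000), length.out = 40))
    F_ <- vapply(t1Grid,
                 function(t1) abs(modelSignal(1, t1, bFixed, delays, tr,
                                              cParam)),
                 numeric(length(delays)))
    proj <- colSums(F_ * signal); e <- colSums(F_^2)
    i <- which.max(proj^2 / e)
    starts <- list(c(max(proj[i] / e[i], 0), t1Grid[i]), c(s0g, 1000))
  }
  best <- NULL
  for (p0 in starts) {
    r <- .lmFitOne(signal, delays, tr, p0, bFixed, cParam, maxIter, ftol)
    if (is.null(best) || r[4] < best[4]) best <- r
    if (best[4] <= 1e-10 * max(1, s0g)) break
  }
  best
}

#' Fit the saturation-recovery model to one voxel's signal
#'
#' Levenberg-Marquardt least squares over the free parameters
#' (S0, T1, B), with bounds T1 in `[1, 10000]` ms, B in `[0, 0.99]`,
#' S0 >= 0.  When `bFixed` is supplied, B is excluded from the free set
#' and only (S0, T1) are fitted.  Non-convergence is reported through the
#' `converged` flag, not as an error.
#'
#' @param signal measured intensities, one per delay.
#' @param delays saturation delays, ms.
#' @param tr repetition time, ms.
#' @param init optional starting values as a named list or numeric
#'   `c(s0, t1, b)`.  The default uses S0 = max(signal) with a
#'   data-driven T1 start and a small set of multistart points, keeping
#'   the best solution (the cost surface has a local minimum near the
#'   B = 0 bound for short T1).
#' @param bFixed optional fixed value for B.
#' @param cParam excitation parameter, default 1.
#' @param maxIter,ftol LM iteration cap and relative cost tolerance.
#' @return A [FitResult].
#' @export
#' @examples
#' d <- c(77, 200, 350, 500, 1200)
#' s <- modelSignal(1000, 1200, 0, d, 1500)
#' fitVoxel(s, d, 1500)
fitVoxel <- function(signal, delays, tr, init = NULL, bFixed = NULL,
                     cParam = 1, maxIter = 200L, ftol = 1e-8) {
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  if (length(signal) != length(delays))
    stop("signal and delays lengths differ")
  need <- if (is.null(bFixed)) 3L else 2L
  if (length(delays) < need)
    stop(sprintf("need at least %d delay points for this fit", need))
  if (is.null(init)) {
    r <- .lmFitBest(signal, delays, tr, bFixed, cParam, maxIter, ftol)
  } else {
    if (is.list(init))
      init <- c(init$s0, init$t1, if (is.null(init$b)) 0.1 else init$b)
    r <- .lmFitOne(signal, delays, tr, init, bFixed, cParam, maxIter, ftol)
  }
  new("FitResult", s0 = r[1], t1 = r[2], b = r[3], c = cParam,
      residualNorm = r[4], nIter = as.integer(r[5]),
      converged = as.logical(r[6]))
}

## masked box-mean filter; radius r voxels, optionally in-plane only
.boxMeanMasked <- function(arr, mask, r = 1L, inPlane = FALSE) {
  d <- dim(arr)
  acc <- array(0, d); cnt <- array(0, d)
  vals <- array(ifelse(mask, arr, 0), d)
  w <- array(as.numeric(mask), d)
  zr <- if (inPlane) 0L else seq(-r, r)
  for (dx in seq(-r, r)) for (dy in seq(-r, r)) for (dz in zr) {
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    ## clamp at the edges rather than shrink: replicate-border mean
    acc <- acc + vals[sx, sy, sz, drop = FALSE]
    cnt <- cnt + w[sx, sy, sz, drop = FALSE]
  }
  out <- arr
  ok <- mask & cnt > 0
  out[ok] <- acc[ok] / cnt[ok]
  out
}

## neighbourhood mean of arr over 'valid' voxels, evaluated everywhere;
## NA where the neighbourhood holds no valid voxel
.boxMeanValid <- function(arr, valid, r = 1L, inPlane = FALSE) {
  d <- dim(arr)
  acc <- array(0, d); cnt <- array(0, d)
  vals <- array(ifelse(valid, arr, 0), d)
  w <- array(as.numeric(valid), d)
  zr <- if (inPlane) 0L else seq(-r, r)
  for (dx in seq(-r, r)) for (dy in seq(-r, r)) for (dz in zr) {
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    acc <- acc + vals[sx, sy, sz, drop = FALSE]
    cnt <- cnt + w[sx, sy, sz, drop = FALSE]
  }
  out <- array(NA_real_, d)
  out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  out
}

#' Pixelwise multi-pass T1 mapping
#'
#' Pass 1 fits (S0, T1, B) freely in every masked voxel.  Each later pass
#' replaces every voxel's B by the mean of B over its neighbourhood
#' (within the mask) and refits (S0, T1) with B fixed — exploiting the
#' slow spatial variation of the B1 field to stabilize T1.
#'
#' @param series an [ImageSeries] with at least 3 delays.
#' @param passes number of fit passes (>= 1); default 3.
#' @param smoothRadius neighbourhood radius in voxels for the B smoothing
#'   (1 gives 3x3x3, or 3x3 with `inPlane = TRUE`).
#' @param mask optional logical array of voxels to fit; default all.
#' @param inPlane smooth B within slices only.
#' @param cParam excitation parameter, default 1.
#' @param noiseSd absolute per-channel noise SD of the magnitude data;
#'   when positive, the Rician noise floor is removed before fitting via
#'   the power-image correction `sqrt(max(M^2 - 2 sd^2, 0))`, which
#'   debiases the near-zero short-delay samples.
#' @param bField optional known B field (array on the series grid).  The
#'   B1 profile is a hardware property, so a field estimated from one
#'   acquisition (e.g. pre-contrast) can be fixed for another of the same
#'   session; only (S0, T1) are then fitted, in a single pass.
#' @param keepPasses return the intermediate per-pass T1 maps in
#'   `attr(result, "passT1")` (list of arrays), for convergence studies.
#' @return A [RelaxationMap]; voxels outside the mask are NA.
#' @export
fitMap <- function(series, passes = 3L, smoothRadius = 1L, mask = NULL,
                   inPlane = FALSE, cParam = 1, noiseSd = 0, bField = NULL,
                   keepPasses = FALSE) {
  stopifnot(is(series, "ImageSeries"))
  if (length(series@delays) < 3L)
    stop("T1 mapping needs a series with at least 3 delays")
  if (passes < 1L) stop("passes must be >= 1")
  d <- dim(series@volumes)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  stopifnot(identical(dim(mask), d))

  nv <- prod(d)
  sig <- matrix(series@volumes, nrow = nv)   # voxels x delays
  if (noiseSd > 0) sig <- sqrt(pmax(sig^2 - 2 * noiseSd^2, 0))
  idx <- which(mask)
  t1 <- s0 <- b <- res <- array(NA_real_, d)
  conv <- array(NA, d)
  passT1 <- vector("list", passes)

  if (length(idx) && !is.null(bField)) {
    stopifnot(identical(dim(bField), d))
    dl <- series@delays; tr <- series@tr
    for (v in idx) {
      s <- sig[v, ]
      r <- .lmFitBest(s, dl, tr, bFixed = bField[v], cParam = cParam)
      s0[v] <- r[1]; t1[v] <- r[2]; b[v] <- r[3]
      res[v] <- r[4]; conv[v] <- as.logical(r[6])
    }
    passT1 <- list(t1)
  } else if (length(idx)) {
    dl <- series@delays; tr <- series@tr
    fitGrid <- .makeFitGrid(dl, tr, cParam)
    for (v in idx) {
      s <- sig[v, ]
      r <- .lmFitBest(s, dl, tr, NULL, cParam, grid = fitGrid)
      s0[v] <- r[1]; t1[v] <- r[2]; b[v] <- r[3]
      res[v] <- r[4]; conv[v] <- as.logical(r[6])
    }
    passT1[[1]] <- t1
    if (passes > 1L) for (p in seq(2L, passes)) {
      ## average B only over trustworthy fits.  Excluded contributors:
      ## voxels at the T1 bounds or recovering slower than TR (the two
      ## exponentials are nearly collinear there, leaving B unidentified)
      ## and voxels with implausibly poor saturation (B > 0.45), the
      ## signature of the degenerate basin in which the TR-recovery term
      ## mimics the T1 recovery.  Voxels without a valid neighbour take
      ## the mean over growing neighbourhoods, honouring the slow spatial
      ## variation of the field.
      valid <- mask & is.finite(t1) & t1 > 30 & t1 < min(9500, 1.2 * tr) &
        is.finite(b) & b <= 0.45
      bS <- .boxMeanValid(b, valid, smoothRadius, inPlane)
      r2 <- smoothRadius
      while (any(mask & !is.finite(bS)) && r2 < max(d)) {
        r2 <- r2 + 1L
        fill <- .boxMeanValid(b, valid, r2, inPlane)
        need <- mask & !is.finite(bS)
        bS[need] <- fill[need]
      }
      stillNA <- mask & !is.finite(bS)
      if (any(stillNA))
        bS[stillNA] <- if (any(valid)) stats::median(b[valid]) else 0.1
      b[mask] <- bS[mask]
      for (v in idx) {
        s <- sig[v, ]
        ## fresh multistart rather than warm start: pass-1 solutions can
        ## sit in the degenerate short-T1 basin, which a warm start with
        ## the newly smoothed B cannot leave
        r <- .lmFitBest(s, dl, tr, bFixed = b[v], cParam = cParam)
        s0[v] <- r[1]; t1[v] <- r[2]
        res[v] <- r[4]; conv[v] <- conv[v] & as.logical(r[6])
      }
      passT1[[p]] <- t1
    }
  }

  r1 <- array(NA_real_, d)
  r1[mask] <- 1000 / t1[mask]
  out <- new("RelaxationMap", t1Map = t1, r1Map = r1, bMap = b, s0Map = s0,
             mask = mask, residual = res, converged = conv,
             voxelSize = series@voxelSize, fovOrigin = series@fovOrigin)
  if (keepPasses) attr(out, "passT1") <- passT1
  out
}

#' Convert a T1 map (ms) to an R1 map (s^-1)
#'
#' Elementwise `R1 = 1000 / T1`.  Nonpositive T1 inside the mask is
#' masked out with a message reporting the count.
#'
#' @param t1 array of T1 values in ms.
#' @param mask optional logical array; default: finite T1 voxels.
#' @return Array of R1 (s^-1), NA outside the (possibly reduced) mask.
#' @export
#' @examples
#' r1FromT1(array(c(1000, 500), c(2, 1, 1)))
r1FromT1 <- function(t1, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(t1)
  bad <- mask & (!is.finite(t1) | t1 <= 0)
  if (any(bad)) {
    message(sum(bad), " voxel(s) with nonpositive T1 masked out")
    mask <- mask & !bad
  }
  out <- array(NA_real_, dim = dim(t1))
  out[mask] <- 1000 / t1[mask]
  out
}

.sameGrid <- function(a, b, tol = 1e-6) {
  identical(gridDim(a), gridDim(b)) &&
    all(abs(voxelSize(a) - voxelSize(b)) < tol) &&
    all(abs(fovOrigin(a) - fovOrigin(b)) < tol)
}

#' Post-minus-pre R1 difference map
#'
#' Voxelwise `R1_post - R1_pre` on the intersection of the two fit
#' masks.  The contrast agent's local concentration is `deltaR1 / r1`.
#'
#' @param pre,post [RelaxationMap]s on the same grid.
#' @return A [DeltaR1Map].
#' @export
deltaR1 <- function(pre, post) {
  stopifnot(is(pre, "RelaxationMap"), is(post, "RelaxationMap"))
  if (!.sameGrid(pre, post))
    stop("pre and post maps are on different grids; resample before subtracting")
  m <- pre@mask & post@mask
  dr <- array(NA_real_, dim = dim(m))
  dr[m] <- post@r1Map[m] - pre@r1Map[m]
  new("DeltaR1Map", deltaR1 = dr, mask = m,
      voxelSize = pre@voxelSize, fovOrigin = pre@fovOrigin)
}

#' Mean delta-R1 over plaque ROIs
#'
#' The per-animal contrast-uptake summary: mean of the delta-R1 map over
#' all ROI voxels (intersected with the map's valid mask).
#'
#' @param map a [DeltaR1Map].
#' @param rois an [ROISet] on the same grid (use [transferROIs()] first
#'   if the ROIs were drawn on another grid).
#' @return Scalar mean delta-R1, s^-1.
#' @export
roiMeanDeltaR1 <- function(map, rois) {
  stopifnot(is(map, "DeltaR1Map"), is(rois, "ROISet"))
  if (!.sameGrid(map, rois))
    stop("ROIs are on a different grid; transfer them to the map grid first")
  sel <- rois@mask & map@mask
  if (!any(rois@mask)) stop("empty ROI set")
  if (!any(sel)) stop("no ROI voxel falls inside the fitted map mask")
  mean(map@deltaR1[sel])
}
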