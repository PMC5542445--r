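## Synthetic vessel phantom: a straight vessel along the slice axis with
## wall-attached ellipsoidal plaque blobs, per-compartment T1/S0/Gd, a
## smooth B1 field and Rician magnitude noise.  Ground truth is retained
## so that every downstream estimate can be benchmarked.

#' Construct a phantom specification
#'
#' Defaults describe one synthetic animal imaged at high field: blood,
#' wall and plaque T1 in the physiological range, the contrast agent
#' confined to plaque, voxels of 0.18 x 0.18 x 0.22 mm, and a slowly
#' varying B1 field.
#'
#' @param gridShape voxels per axis (slices along the third axis).
#' @param voxelSize mm per axis.
#' @param fovOrigin world position (mm) of the centre of voxel `[1,1,1]`.
#' @param lumenRadius,wallThickness vessel geometry, mm.
#' @param vesselCenter in-plane world coordinates (mm) of the vessel axis;
#'   defaults to the grid centre.
#' @param plaques data.frame with columns `cx, cy, cz, ax, ay, az` (mm):
#'   ellipsoid centres and semi-axes.  Zero rows gives a plaque-free animal.
#' @param t1Tissue named pre-contrast T1 (ms) for `background`, `blood`,
#'   `wall`, `plaque`.
#' @param s0Tissue named equilibrium signal (a.u.) per compartment;
#'   background is kept low (air-like) so intensity masks isolate tissue.
#' @param gdConcentration named agent concentration (mmol/L) per
#'   compartment; default accumulates only in plaque.
#' @param r1Agent longitudinal relaxivity, L mmol^-1 s^-1.
#' @param b1Mean,b1Amplitude,b1Scale B-field model: constant plus one
#'   Gaussian bump of the given amplitude and length scale (mm).
#' @param b1Center bump centre (mm); NA entries are drawn from `seed`.
#' @param noiseSigma magnitude-noise SD as a fraction of max(s0Tissue).
#' @param seed integer seed.
#' @return A validated [PhantomSpec].
#' @export
#' @examples
#' spec <- phantomSpec(plaques = data.frame(cx = 2.9, cy = 2.2, cz = 1.1,
#'                                          ax = 0.6, ay = 0.5, az = 0.5))
#' spec
phantomSpec <- function(gridShape = c(32L, 32L, 10L),
                        voxelSize = c(0.18, 0.18, 0.22),
                        fovOrigin = c(0, 0, 0),
                        lumenRadius = 0.55,
                        wallThickness = 0.2,
                        vesselCenter = NULL,
                        plaques = data.frame(cx = numeric(), cy = numeric(),
                                             cz = numeric(), ax = numeric(),
                                             ay = numeric(), az = numeric()),
                        t1Tissue = c(background = 900, blood = 2200,
                                     wall = 1300, plaque = 1100),
                        s0Tissue = c(background = 30, blood = 1000,
                                     wall = 1000, plaque = 1000),
                        gdConcentration = c(background = 0, blood = 0,
                                            wall = 0, plaque = 0.1),
                        r1Agent = 18,
                        b1Mean = 0.1,
                        b1Amplitude = 0.15,
                        b1Scale = 3,
                        b1Center = c(NA_real_, NA_real_, NA_real_),
                        noiseSigma = 0.02,
                        seed = 1L) {
  if (is.null(vesselCenter))
    vesselCenter <- fovOrigin[1:2] + (gridShape[1:2] - 1) / 2 * voxelSize[1:2]
  new("PhantomSpec",
      gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
      fovOrigin = as.numeric(fovOrigin), lumenRadius = lumenRadius,
      wallThickness = wallThickness, vesselCenter = as.numeric(vesselCenter),
      plaques = plaques,
      t1Tissue = t1Tissue[.compartments],
      s0Tissue = s0Tissue[.compartments],
      gdConcentration = gdConcentration[.compartments],
      r1Agent = r1Agent, b1Mean = b1Mean, b1Amplitude = b1Amplitude,
      b1Scale = b1Scale, b1Center = as.numeric(b1Center),
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

## world coordinate vectors per axis (voxel centres)
.axisCoords <- function(n, vs, o) o + (seq_len(n) - 1) * vs

#' Build the voxelized ground truth for a phantom
#'
#' Rasterizes the vessel and plaque geometry into a compartment-label
#' volume, evaluates the smooth B field, and derives the post-contrast T1
#' from `R1_post = R1_pre + r1 * C_Gd` per compartment (R1 in s^-1 from
#' `1000 / T1[ms]`).
#'
#' @param spec a [PhantomSpec].
#' @return A [GroundTruth].
#' @export
#' @examples
#' gt <- buildGroundTruth(phantomSpec())
#' plaqueVolume(gt)  # 0: no plaque blobs in the default spec
buildGroundTruth <- function(spec) {
  validObject(spec)
  d <- spec@gridShape
  xs <- .axisCoords(d[1], spec@voxelSize[1], spec@fovOrigin[1])
  ys <- .axisCoords(d[2], spec@voxelSize[2], spec@fovOrigin[2])
  zs <- .axisCoords(d[3], spec@voxelSize[3], spec@fovOrigin[3])

  ## in-plane radius from the vessel axis, replicated over slices
  r2 <- outer((xs - spec@vesselCenter[1])^2, (ys - spec@vesselCenter[2])^2, `+`)
  rr <- sqrt(r2)
  plane <- matrix(compartmentCodes()[["background"]], d[1], d[2])
  plane[rr <= spec@lumenRadius + spec@wallThickness] <- compartmentCodes()[["wall"]]
  plane[rr <= spec@lumenRadius] <- compartmentCodes()[["blood"]]
  labels <- array(plane, dim = d)
  lumen <- array(rr <= spec@lumenRadius, dim = d)

  if (nrow(spec@plaques)) {
    X <- array(rep(xs, times = d[2] * d[3]), dim = d)
    Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
    Z <- array(rep(zs, each = d[1] * d[2]), dim = d)
    wallAnn <- array(rr > spec@lumenRadius &
                     rr <= spec@lumenRadius + spec@wallThickness, dim = d)
    for (i in seq_len(nrow(spec@plaques))) {
      p <- spec@plaques[i, ]
      inside <- ((X - p$cx) / p$ax)^2 + ((Y - p$cy) / p$ay)^2 +
        ((Z - p$cz) / p$az)^2 <= 1
      if (!any(inside))
        stop(sprintf("plaque blob %d (centre %.2f, %.2f, %.2f mm) lies entirely outside the grid",
                     i, p$cx, p$cy, p$cz))
      if (!any(inside & wallAnn))
        warning(sprintf("plaque blob %d does not intersect the wall annulus", i))
      labels[inside & !lumen] <- compartmentCodes()[["plaque"]]
    }
  }

  ## smooth B field: constant + one long-wavelength Gaussian bump
  ctr <- spec@b1Center
  if (anyNA(ctr)) {
    set.seed(spec@seed + 101L)
    lo <- spec@fovOrigin + 0.25 * (d - 1) * spec@voxelSize
    hi <- spec@fovOrigin + 0.75 * (d - 1) * spec@voxelSize
    drawn <- lo + stats::runif(3) * (hi - lo)
    ctr[is.na(ctr)] <- drawn[is.na(ctr)]
  }
  d2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`), (zs - ctr[3])^2, `+`)
  bMap <- spec@b1Mean + spec@b1Amplitude * exp(-d2 / (2 * spec@b1Scale^2))
  bMap <- pmin(pmax(bMap, 0), 0.95)

  codeOf <- match(labels, compartmentCodes())   # 1..4 in .compartments order
  t1Pre <- array(spec@t1Tissue[codeOf], dim = d)
  cGd <- array(spec@gdConcentration[codeOf], dim = d)
  r1Post <- 1000 / t1Pre + spec@r1Agent * cGd
  t1Post <- 1000 / r1Post

  nPlq <- sum(labels == compartmentCodes()[["plaque"]])
  new("GroundTruth", t1Pre = t1Pre, t1Post = t1Post, bMap = bMap,
      labels = array(as.integer(labels), dim = d),
      plaqueVolume = nPlq * prod(spec@voxelSize),
      voxelSize = spec@voxelSize, fovOrigin = spec@fovOrigin, spec = spec)
}

## per-compartment S0 volume for a truth object
.s0Volume <- function(truth) {
  spec <- truth@spec
  array(spec@s0Tissue[match(truth@labels, compartmentCodes())],
        dim = dim(truth@labels))
}

## Rician magnitude noise: modulus of a complex Gaussian perturbation.
## At zero noise the magnitude of the (possibly slightly negative) model
## signal is returned.
.ricianNoise <- function(signal, sigmaAbs) {
  if (sigmaAbs == 0) return(abs(signal))
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, sd = sigmaAbs))^2 +
         stats::rnorm(n, sd = sigmaAbs)^2)
}

#' Simulate a saturation-recovery image series
#'
#' Forward-evaluates the saturation-recovery signal model voxelwise at
#' each delay (C = 1) and applies Rician magnitude noise.
#'
#' @param truth a [GroundTruth].
#' @param delays saturation delays, ms (default the canonical 5-point scheme).
#' @param tr repetition time, ms.
#' @param noiseSigma noise SD as a fraction of max compartment S0;
#'   defaults to the spec's value.
#' @param seed RNG seed; defaults to the spec's seed.
#' @param state `"pre"` or `"post"` contrast.
#' @return An [ImageSeries] with one volume per delay, in the given order.
#' @export
#' @examples
#' gt <- buildGroundTruth(phantomSpec(noiseSigma = 0))
#' ser <- simulateSRSeries(gt)
#' delays(ser)
simulateSRSeries <- function(truth, delays = c(77, 200, 350, 500, 1200),
                             tr = 1500, noiseSigma = NULL, seed = NULL,
                             state = c("pre", "post")) {
  state <- match.arg(state)
  stopifnot(is(truth, "GroundTruth"))
  if (!length(delays)) stop("delays must be nonempty")
  if (is.null(noiseSigma)) noiseSigma <- truth@spec@noiseSigma
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (is.null(seed)) seed <- truth@spec@seed
  t1 <- t1Map(truth, state)
  s0 <- .s0Volume(truth)
  d <- dim(t1)
  vols <- array(NA_real_, dim = c(d, length(delays)))
  sigmaAbs <- noiseSigma * max(truth@spec@s0Tissue)
  set.seed(seed)
  for (i in seq_along(delays)) {
    s <- modelSignal(s0, t1, truth@bMap, t = delays[i], tr = tr)
    vols[, , , i] <- .ricianNoise(s, sigmaAbs)
  }
  new("ImageSeries", volumes = vols, delays = as.numeric(delays), tr = tr,
      voxelSize = truth@voxelSize, fovOrigin = truth@fovOrigin)
}

## nearest-neighbour resampling of a 3D array onto a target grid
.resampleNN <- function(arr, srcVS, srcOrigin, tgtDim, tgtVS, tgtOrigin) {
  idx <- lapply(1:3, function(a) {
    w <- .axisCoords(tgtDim[a], tgtVS[a], tgtOrigin[a])
    i <- round((w - srcOrigin[a]) / srcVS[a]) + 1
    pmin(pmax(i, 1L), dim(arr)[a])
  })
  arr[as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))] |>
    array(dim = tgtDim)
}

#' Simulate the high-resolution anatomical volume
#'
#' Stands in for the 3D anatomical scan used for plaque volumetry: the
#' ground truth is resampled (nearest-neighbour labels) onto a grid
#' refined by `hiResFactor` per axis and optionally shifted in world
#' space, then a single volume is synthesized with the same recovery
#' signal model at the protocol's effective recovery time `ti`.
#'
#' @param truth a [GroundTruth].
#' @param ti effective recovery time of the anatomical protocol, ms.
#' @param tr repetition time, ms.
#' @param hiResFactor integer >= 1, grid refinement per axis.
#' @param noiseSigma noise fraction (anatomical scans average more
#'   acquisitions, so the default is lower than the SR default).
#' @param seed RNG seed; defaults to the spec's seed + 1.
#' @param state `"pre"` or `"post"` contrast.
#' @param fovShift world-space shift (mm) of the anatomy field of view
#'   relative to the SR grid, to exercise ROI transfer.
#' @return A single-volume [ImageSeries].
#' @export
simulateAnatomy <- function(truth, ti = 250, tr = 650, hiResFactor = 1L,
                            noiseSigma = 0.01, seed = NULL,
                            state = c("pre", "post"),
                            fovShift = c(0, 0, 0)) {
  state <- match.arg(state)
  stopifnot(is(truth, "GroundTruth"), hiResFactor >= 1)
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (is.null(seed)) seed <- truth@spec@seed + 1L
  f <- as.integer(hiResFactor)
  srcDim <- dim(truth@labels)
  tgtDim <- srcDim * f
  tgtVS <- truth@voxelSize / f
  ## refined grid spans the same FOV: first fine voxel centre sits at the
  ## coarse voxel's near corner + half a fine voxel
  tgtOrigin <- truth@fovOrigin - truth@voxelSize / 2 + tgtVS / 2 + fovShift

  t1 <- .resampleNN(t1Map(truth, state), truth@voxelSize, truth@fovOrigin,
                    tgtDim, tgtVS, tgtOrigin)
  b <- .resampleNN(truth@bMap, truth@voxelSize, truth@fovOrigin,
                   tgtDim, tgtVS, tgtOrigin)
  lab <- .resampleNN(truth@labels, truth@voxelSize, truth@fovOrigin,
                     tgtDim, tgtVS, tgtOrigin)
  s0 <- array(truth@spec@s0Tissue[match(lab, compartmentCodes())],
              dim = tgtDim)
  s <- modelSignal(s0, t1, b, t = ti, tr = tr)
  set.seed(seed)
  vol <- array(.ricianNoise(s, noiseSigma * max(truth@spec@s0Tissue)),
               dim = c(tgtDim, 1L))
  new("ImageSeries", volumes = vol, delays = ti, tr = tr,
      voxelSize = tgtVS, fovOrigin = tgtOrigin)
}

#' Generate a full paired pre/post contrast study
#'
#' Bundles ground truth, pre- and post-contrast saturation-recovery
#' series, and pre/post anatomical volumes for one synthetic animal.
#' Sub-seeds are derived from the spec seed so the four acquisitions use
#' independent noise.  With `outDir` given, all volumes are written as
#' NIfTI with a JSON manifest (see [writeStudy()]).
#'
#' @param spec a [PhantomSpec].
#' @param delays,tr saturation-recovery protocol (ms).
#' @param anatomyTI,anatomyTR anatomical protocol timing (ms).
#' @param hiResFactor anatomy grid refinement per axis.
#' @param anatomyShift world shift (mm) of the anatomy FOV.
#' @param anatomyNoiseSigma anatomy noise fraction.
#' @param outDir optional output directory.
#' @return A [PairedStudy].
#' @export
makePairedStudy <- function(spec, delays = c(77, 200, 350, 500, 1200),
                            tr = 1500, anatomyTI = 250, anatomyTR = 650,
                            hiResFactor = 1L,
                            anatomyShift = c(0.09, 0.09, 0),
                            anatomyNoiseSigma = 0.01, outDir = NULL) {
  truth <- buildGroundTruth(spec)
  study <- new("PairedStudy",
    spec = spec, truth = truth,
    pre = simulateSRSeries(truth, delays, tr, seed = spec@seed + 11L,
                           state = "pre"),
    post = simulateSRSeries(truth, delays, tr, seed = spec@seed + 13L,
                            state = "post"),
    anatomyPre = simulateAnatomy(truth, anatomyTI, anatomyTR, hiResFactor,
                                 anatomyNoiseSigma, seed = spec@seed + 17L,
                                 state = "pre", fovShift = anatomyShift),
    anatomyPost = simulateAnatomy(truth, anatomyTI, anatomyTR, hiResFactor,
                                  anatomyNoiseSigma, seed = spec@seed + 19L,
                                  state = "post", fovShift = anatomyShift))
  if (!is.null(outDir)) writeStudy(study, outDir)
  study
}
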