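#' Compartment codes used in label volumes
#'
#' The phantom partitions the grid into four tissue compartments:
#' background (perivascular, `0`), lumen blood (`1`), vessel wall (`2`)
#' and atherosclerotic plaque (`3`).
#'
#' @return Named integer vector mapping compartment name to label code.
#' @export
#' @examples
#' compartmentCodes()
compartmentCodes <- function() {
  c(background = 0L, blood = 1L, wall = 2L, plaque = 3L)
}

.compartments <- c("background", "blood", "wall", "plaque")

#' Virtual parent for objects living on a regular voxel grid
#'
#' Carries the voxel size (mm per axis) and the world-space position of
#' the centre of voxel `[1, 1, 1]` (`fovOrigin`, mm).  World position of
#' voxel `(i, j, k)` (1-based) is `fovOrigin + (c(i, j, k) - 1) * voxelSize`.
#'
#' @slot voxelSize numeric(3), mm per axis.
#' @slot fovOrigin numeric(3), mm.
#' @export
setClass("ImageGrid", representation("VIRTUAL",
  voxelSize = "numeric",
  fovOrigin = "numeric"
))

setValidity("ImageGrid", function(object) {
  msg <- character()
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive finite values (mm)")
  if (length(object@fovOrigin) != 3L || any(!is.finite(object@fovOrigin)))
    msg <- c(msg, "fovOrigin must be 3 finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' Synthetic vessel-phantom specification
#'
#' Declarative description of one synthetic animal: vessel geometry
#' (straight vessel along the slice axis), ellipsoidal plaque blobs
#' attached to the wall, per-compartment tissue T1 and equilibrium
#' signal, plaque-confined contrast-agent concentration, a smooth B1
#' inhomogeneity field, and the magnitude-noise level.
#'
#' @slot gridShape integer(3), voxels per axis; slices along the third axis.
#' @slot voxelSize numeric(3), mm.
#' @slot fovOrigin numeric(3), mm.
#' @slot lumenRadius lumen radius, mm.
#' @slot wallThickness vessel wall thickness, mm.
#' @slot vesselCenter in-plane world coordinates (mm) of the vessel axis.
#' @slot plaques data.frame with columns `cx, cy, cz, ax, ay, az` (mm):
#'   ellipsoid centres and semi-axes in world space.
#' @slot t1Tissue named numeric, pre-contrast T1 (ms) per compartment
#'   (`background`, `blood`, `wall`, `plaque`).
#' @slot s0Tissue named numeric, equilibrium signal (a.u.) per compartment.
#' @slot gdConcentration named numeric, contrast-agent concentration
#'   (mmol/L) per compartment; nonzero only where the agent accumulates.
#' @slot r1Agent longitudinal relaxivity of the agent, L mmol^-1 s^-1.
#' @slot b1Mean,b1Amplitude,b1Scale parameters of the smooth B field:
#'   constant level, Gaussian-bump amplitude, and bump length scale (mm).
#' @slot b1Center numeric(3) bump centre (mm); any NA entry is drawn
#'   reproducibly from `seed`.
#' @slot noiseSigma magnitude-noise standard deviation as a fraction of
#'   the largest compartment S0.
#' @slot seed integer RNG seed for everything stochastic in this animal.
#' @export
setClass("PhantomSpec", contains = "ImageGrid", representation(
  gridShape = "integer",
  lumenRadius = "numeric",
  wallThickness = "numeric",
  vesselCenter = "numeric",
  plaques = "data.frame",
  t1Tissue = "numeric",
  s0Tissue = "numeric",
  gdConcentration = "numeric",
  r1Agent = "numeric",
  b1Mean = "numeric",
  b1Amplitude = "numeric",
  b1Scale = "numeric",
  b1Center = "numeric",
  noiseSigma = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  for (nm in c("t1Tissue", "s0Tissue", "gdConcentration")) {
    v <- slot(object, nm)
    if (!all(.compartments %in% names(v)))
      msg <- c(msg, sprintf("%s must be named for all of: %s",
                            nm, paste(.compartments, collapse = ", ")))
  }
  if (any(object@t1Tissue <= 0)) msg <- c(msg, "all tissue T1 must be > 0")
  if (any(object@s0Tissue < 0)) msg <- c(msg, "s0Tissue must be >= 0")
  if (any(object@gdConcentration < 0))
    msg <- c(msg, "gdConcentration must be >= 0")
  if (object@r1Agent < 0) msg <- c(msg, "r1Agent must be >= 0")
  if (object@b1Mean < 0 || object@b1Mean + abs(object@b1Amplitude) >= 1)
    msg <- c(msg, "B field must satisfy 0 <= B < 1 everywhere")
  if (object@b1Scale <= 0) msg <- c(msg, "b1Scale must be > 0 (mm)")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@lumenRadius <= 0 || object@wallThickness <= 0)
    msg <- c(msg, "lumenRadius and wallThickness must be > 0")
  if (nrow(object@plaques) &&
      !all(c("cx", "cy", "cz", "ax", "ay", "az") %in% names(object@plaques)))
    msg <- c(msg, "plaques needs columns cx, cy, cz, ax, ay, az")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic animal
#'
#' Voxelwise truth against which estimates are benchmarked: pre- and
#' post-contrast T1, the B field, compartment labels, and the plaque
#' volume implied by the labels.
#'
#' @slot t1Pre,t1Post 3D arrays, T1 in ms.
#' @slot bMap 3D array, dimensionless B.
#' @slot labels integer 3D array, coded per [compartmentCodes()].
#' @slot plaqueVolume scalar mm^3 (plaque voxel count x voxel volume).
#' @slot spec the generating [PhantomSpec].
#' @export
setClass("GroundTruth", contains = "ImageGrid", representation(
  t1Pre = "array",
  t1Post = "array",
  bMap = "array",
  labels = "array",
  plaqueVolume = "numeric",
  spec = "PhantomSpec"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  d <- dim(object@t1Pre)
  if (!identical(d, dim(object@t1Post)) || !identical(d, dim(object@bMap)) ||
      !identical(d, dim(object@labels)))
    msg <- c(msg, "t1Pre, t1Post, bMap and labels must share one grid")
  if (any(object@t1Post > object@t1Pre + 1e-9))
    msg <- c(msg, "t1Post must not exceed t1Pre (the agent only shortens T1)")
  if (any(object@t1Pre <= 0)) msg <- c(msg, "t1Pre must be positive")
  if (any(object@bMap < 0 | object@bMap >= 1))
    msg <- c(msg, "bMap must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Saturation-recovery image series
#'
#' One 3D magnitude volume per saturation delay, on a common grid.  A
#' single-volume series is also used for the anatomical scan (its `delays`
#' then holds the effective recovery time of that protocol).
#'
#' @slot volumes 4D array `[x, y, z, delay]` of magnitude intensities (a.u.).
#' @slot delays numeric, saturation delay (ms) per volume.
#' @slot tr repetition time, ms.
#' @export
setClass("ImageSeries", contains = "ImageGrid", representation(
  volumes = "array",
  delays = "numeric",
  tr = "numeric"
))

setValidity("ImageSeries", function(object) {
  msg <- character()
  if (length(dim(object@volumes)) != 4L)
    msg <- c(msg, "volumes must be a 4D array [x, y, z, delay]")
  else if (dim(object@volumes)[4L] != length(object@delays))
    msg <- c(msg, "number of volumes must equal number of delays")
  if (any(object@delays <= 0)) msg <- c(msg, "delays must be strictly positive")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a positive scalar (ms)")
  if (length(msg)) msg else TRUE
})

#' Pixelwise relaxometry result
#'
#' Per-voxel (S0, T1, B) from the saturation-recovery fit, the derived R1,
#' and fit diagnostics.  Within the mask `r1Map * t1Map == 1000` holds to
#' machine precision; voxels outside the mask are NA.
#'
#' @slot t1Map,r1Map,bMap,s0Map 3D arrays (ms, s^-1, -, a.u.).
#' @slot mask logical 3D array of fitted voxels.
#' @slot residual 3D array of residual norms (a.u.).
#' @slot converged logical 3D array.
#' @export
setClass("RelaxationMap", contains = "ImageGrid", representation(
  t1Map = "array",
  r1Map = "array",
  bMap = "array",
  s0Map = "array",
  mask = "array",
  residual = "array",
  converged = "array"
))

setValidity("RelaxationMap", function(object) {
  d <- dim(object@t1Map)
  ok <- identical(d, dim(object@r1Map)) && identical(d, dim(object@bMap)) &&
    identical(d, dim(object@s0Map)) && identical(d, dim(object@mask))
  if (!ok) return("all map arrays must share one grid")
  m <- object@mask
  if (any(m)) {
    prod_ <- object@r1Map[m] * object@t1Map[m]
    if (any(abs(prod_ - 1000) > 1e-6))
      return("within the mask r1Map must equal 1000 / t1Map")
  }
  TRUE
})

#' Post-minus-pre R1 difference map
#'
#' @slot deltaR1 3D array of R1_post - R1_pre (s^-1); NA outside the mask.
#' @slot mask logical 3D array, intersection of the pre and post fit masks.
#' @export
setClass("DeltaR1Map", contains = "ImageGrid", representation(
  deltaR1 = "array",
  mask = "array"
))

setValidity("DeltaR1Map", function(object) {
  if (!identical(dim(object@deltaR1), dim(object@mask)))
    return("deltaR1 and mask must share one grid")
  TRUE
})

#' A set of plaque regions of interest on a named grid
#'
#' Binary per-slice masks stacked into a 3D array (slices along the last
#' axis), standing in for manually drawn plaque ROIs.
#'
#' @slot mask logical 3D array.
#' @slot readerId character label of the (synthetic) reader.
#' @export
setClass("ROISet", contains = "ImageGrid", representation(
  mask = "array",
  readerId = "character"
))

setValidity("ROISet", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' Plaque volumetry result
#'
#' @slot tpv total plaque volume, mm^3.
#' @slot perSliceArea per-slice ROI area, mm^2.
#' @slot nVoxels ROI voxel count.
#' @export
setClass("VolumeResult", representation(
  tpv = "numeric",
  perSliceArea = "numeric",
  nVoxels = "integer"
))

#' A paired pre/post contrast study for one synthetic animal
#'
#' @slot spec the [PhantomSpec].
#' @slot truth the [GroundTruth].
#' @slot pre,post saturation-recovery [ImageSeries] before / after contrast.
#' @slot anatomyPre,anatomyPost single-volume anatomical [ImageSeries].
#' @export
setClass("PairedStudy", representation(
  spec = "PhantomSpec",
  truth = "GroundTruth",
  pre = "ImageSeries",
  post = "ImageSeries",
  anatomyPre = "ImageSeries",
  anatomyPost = "ImageSeries"
))

## ---- accessors ------------------------------------------------------------

#' @describeIn voxelSize grid objects
#' @export
setMethod("voxelSize", "ImageGrid", function(x) x@voxelSize)

#' @describeIn fovOrigin grid objects
#' @export
setMethod("fovOrigin", "ImageGrid", function(x) x@fovOrigin)

#' @describeIn voxelVolume grid objects
#' @export
setMethod("voxelVolume", "ImageGrid", function(x) prod(x@voxelSize))

#' @describeIn gridDim phantom specification
#' @export
setMethod("gridDim", "PhantomSpec", function(x) x@gridShape)

#' @describeIn gridDim ground truth
#' @export
setMethod("gridDim", "GroundTruth", function(x) dim(x@labels))

#' @describeIn gridDim image series
#' @export
setMethod("gridDim", "ImageSeries", function(x) dim(x@volumes)[1:3])

#' @describeIn gridDim relaxation map
#' @export
setMethod("gridDim", "RelaxationMap", function(x) dim(x@t1Map))

#' @describeIn gridDim delta-R1 map
#' @export
setMethod("gridDim", "DeltaR1Map", function(x) dim(x@deltaR1))

#' @describeIn gridDim ROI set
#' @export
setMethod("gridDim", "ROISet", function(x) dim(x@mask))

#' @describeIn delays image series
#' @export
setMethod("delays", "ImageSeries", function(x) x@delays)

#' @describeIn repetitionTime image series
#' @export
setMethod("repetitionTime", "ImageSeries", function(x) x@tr)

#' @describeIn t1Map fitted map
#' @export
setMethod("t1Map", "RelaxationMap", function(x, ...) x@t1Map)

#' @describeIn t1Map ground truth; `state` selects `"pre"` or `"post"` contrast
#' @param state `"pre"` (default) or `"post"`.
#' @export
setMethod("t1Map", "GroundTruth", function(x, state = c("pre", "post")) {
  state <- match.arg(state)
  if (state == "pre") x@t1Pre else x@t1Post
})

#' @describeIn r1Map fitted map
#' @export
setMethod("r1Map", "RelaxationMap", function(x) x@r1Map)

#' @describeIn bMap fitted map
#' @export
setMethod("bMap", "RelaxationMap", function(x) x@bMap)

#' @describeIn bMap ground truth
#' @export
setMethod("bMap", "GroundTruth", function(x) x@bMap)

#' @describeIn s0Map fitted map
#' @export
setMethod("s0Map", "RelaxationMap", function(x) x@s0Map)

#' @describeIn imageMask fitted map
#' @export
setMethod("imageMask", "RelaxationMap", function(x) x@mask)

#' @describeIn imageMask delta-R1 map
#' @export
setMethod("imageMask", "DeltaR1Map", function(x) x@mask)

#' @describeIn imageMask ROI set
#' @export
setMethod("imageMask", "ROISet", function(x) x@mask)

#' @describeIn compartmentLabels ground truth
#' @export
setMethod("compartmentLabels", "GroundTruth", function(x) x@labels)

#' @describeIn plaqueVolume ground truth
#' @export
setMethod("plaqueVolume", "GroundTruth", function(x) x@plaqueVolume)

#' @describeIn readerId ROI set
#' @export
setMethod("readerId", "ROISet", function(x) x@readerId)

#' @describeIn deltaR1Values delta-R1 map
#' @export
setMethod("deltaR1Values", "DeltaR1Map", function(x) x@deltaR1)

## ---- show methods ---------------------------------------------------------

.fmtGrid <- function(x) {
  sprintf("%s voxels @ %s mm",
          paste(gridDim(x), collapse = " x "),
          paste(signif(voxelSize(x), 3), collapse = " x "))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", .fmtGrid(object), "\n")
  cat("  vessel: lumen", object@lumenRadius, "mm, wall",
      object@wallThickness, "mm;", nrow(object@plaques), "plaque blob(s)\n")
  cat("  T1 (ms):", paste(sprintf("%s=%g", names(object@t1Tissue),
                                  object@t1Tissue), collapse = ", "), "\n")
  cat("  Gd (mmol/L):",
      paste(sprintf("%s=%g", names(object@gdConcentration),
                    object@gdConcentration), collapse = ", "),
      "| r1 =", object@r1Agent, "L mmol^-1 s^-1\n")
  cat("  B1: mean", object@b1Mean, "amp", object@b1Amplitude,
      "scale", object@b1Scale, "mm | noise", object@noiseSigma,
      "| seed", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", .fmtGrid(object), "\n")
  tab <- table(factor(object@labels, levels = compartmentCodes(),
                      labels = names(compartmentCodes())))
  cat("  voxels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  cat(sprintf("  plaque volume: %.4g mm^3\n", object@plaqueVolume))
})

setMethod("show", "ImageSeries", function(object) {
  cat("ImageSeries:", .fmtGrid(object), "\n")
  cat("  delays (ms):", paste(object@delays, collapse = ", "),
      "| TR", object@tr, "ms\n")
})

setMethod("show", "RelaxationMap", function(object) {
  cat("RelaxationMap:", .fmtGrid(object), "\n")
  m <- object@mask
  cat(sprintf("  %d fitted voxels (%.1f%% converged)", sum(m),
              if (any(m)) 100 * mean(object@converged[m]) else NA_real_), "\n")
  if (any(m))
    cat(sprintf("  T1 median %.0f ms, B median %.3f\n",
                stats::median(object@t1Map[m]),
                stats::median(object@bMap[m])))
})

setMethod("show", "DeltaR1Map", function(object) {
  cat("DeltaR1Map:", .fmtGrid(object), "\n")
  m <- object@mask
  if (any(m))
    cat(sprintf("  %d voxels, median dR1 %.3f s^-1\n", sum(m),
                stats::median(object@deltaR1[m])))
})

setMethod("show", "ROISet", function(object) {
  cat("ROISet (reader ", object@readerId, "): ", .fmtGrid(object), "\n",
      sep = "")
  cat("  ", sum(object@mask), " ROI voxels on ",
      sum(apply(object@mask, 3, any)), " slice(s)\n", sep = "")
})

setMethod("show", "VolumeResult", function(object) {
  cat(sprintf("VolumeResult: TPV %.4g mm^3 (%d voxels, %d slices with ROI)\n",
              object@tpv, object@nVoxels, sum(object@perSliceArea > 0)))
})

setMethod("show", "PairedStudy", function(object) {
  cat("PairedStudy (seed ", object@spec@seed, ")\n", sep = "")
  cat("  SR series:", .fmtGrid(object@pre), "with",
      length(object@pre@delays), "delays\n")
  cat("  anatomy:  ", .fmtGrid(object@anatomyPre), "\n")
  cat(sprintf("  truth plaque volume: %.4g mm^3\n",
              object@truth@plaqueVolume))
})
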