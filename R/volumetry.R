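## Plaque ROI handling and volumetry: total plaque volume from per-slice
## ROIs, semiautomatic threshold segmentation with small-component
## removal, world-space ROI transfer between grids of different voxel
## size / field-of-view origin, and interobserver agreement.

#' Construct an ROI set
#'
#' @param mask logical 3D array (slices along the last axis).
#' @param voxelSize mm per axis.
#' @param fovOrigin world position (mm) of voxel `[1,1,1]`.
#' @param readerId label for the reader / generating method.
#' @return An [ROISet].
#' @export
roiSet <- function(mask, voxelSize, fovOrigin = c(0, 0, 0),
                   readerId = "reader") {
  new("ROISet", mask = array(as.logical(mask), dim(mask)),
      voxelSize = as.numeric(voxelSize), fovOrigin = as.numeric(fovOrigin),
      readerId = readerId)
}

#' Total plaque volume from an ROI set
#'
#' Per-slice ROI areas (mm^2) are summed across slices and multiplied by
#' the slice thickness, i.e. TPV equals ROI voxel count times voxel
#' volume.  An empty ROI set gives 0 mm^3.
#'
#' @param rois an [ROISet].
#' @return A [VolumeResult] with `tpv` (mm^3), `perSliceArea` (mm^2) and
#'   `nVoxels`.
#' @export
#' @examples
#' m <- array(FALSE, c(4, 4, 2)); m[2, 2, 1] <- TRUE
#' totalPlaqueVolume(roiSet(m, c(0.18, 0.18, 0.18)))  # 0.005832 mm^3
totalPlaqueVolume <- function(rois) {
  stopifnot(is(rois, "ROISet"))
  vs <- rois@voxelSize
  perSlice <- apply(rois@mask, 3, sum) * vs[1] * vs[2]
  n <- sum(rois@mask)
  new("VolumeResult", tpv = n * prod(vs), perSliceArea = as.numeric(perSlice),
      nVoxels = as.integer(n))
}

## connected-component labelling by iterative minimum-label propagation;
## 26-connectivity in 3D (8 in-plane when inPlane = TRUE)
.labelComponents <- function(mask, inPlane = FALSE) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- which(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = if (inPlane) 0L else -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  rng <- function(n, o) list(t = seq(max(1, 1 + o), min(n, n + o)),
                             s = seq(max(1, 1 - o), min(n, n - o)))
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      rx <- rng(d[1], offs$dx[k]); ry <- rng(d[2], offs$dy[k])
      rz <- rng(d[3], offs$dz[k])
      tt <- lab[rx$t, ry$t, rz$t, drop = FALSE]
      ss <- lab[rx$s, ry$s, rz$s, drop = FALSE]
      upd <- ss > 0L & tt > 0L & ss < tt
      if (any(upd)) {
        tt[upd] <- ss[upd]
        lab[rx$t, ry$t, rz$t] <- tt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Threshold segmentation of an intensity volume
#'
#' Semiautomatic plaque segmentation: voxels at or above the threshold
#' are selected and connected components (26-connectivity in 3D) smaller
#' than `minComponent` voxels are discarded.  Raising the threshold never
#' increases the segmented volume.
#'
#' @param volume a single-volume [ImageSeries], or a 3D array (then
#'   `voxelSize` / `fovOrigin` must be given).
#' @param threshold intensity cut; a warning is raised when it lies
#'   outside the volume's intensity range (the result is then empty or
#'   full as implied).
#' @param minComponent minimum connected-component size in voxels.
#' @param voxelSize,fovOrigin grid geometry when `volume` is an array.
#' @return An [ROISet] with `readerId = "segmentation"`.
#' @export
thresholdSegment <- function(volume, threshold, minComponent = 1L,
                             voxelSize = NULL, fovOrigin = c(0, 0, 0)) {
  if (is(volume, "ImageSeries")) {
    vs <- volume@voxelSize; fo <- volume@fovOrigin
    arr <- volume@volumes[, , , 1]
    if (dim(volume@volumes)[4] > 1)
      warning("multi-volume series: segmenting the first volume only")
  } else {
    if (is.null(voxelSize)) stop("voxelSize required for array input")
    arr <- volume; vs <- voxelSize; fo <- fovOrigin
  }
  if (threshold > max(arr) || threshold < min(arr))
    warning("threshold lies outside the volume's intensity range")
  sel <- arr >= threshold
  if (any(sel) && minComponent > 1L) {
    lab <- .labelComponents(sel)
    sizes <- table(lab[lab > 0L])
    keep <- as.integer(names(sizes)[sizes >= minComponent])
    sel <- array(lab %in% keep, dim(sel))
  }
  roiSet(sel, vs, fo, readerId = "segmentation")
}

.gridOf <- function(x) {
  if (is(x, "ImageGrid")) list(dim = gridDim(x), voxelSize = voxelSize(x),
                               fovOrigin = fovOrigin(x))
  else {
    stopifnot(all(c("dim", "voxelSize", "fovOrigin") %in% names(x)))
    x
  }
}

#' Transfer ROIs to another grid
#'
#' Maps an ROI set into the voxel grid of another acquisition (different
#' voxel size and/or field-of-view origin), using the shared world frame.
#' In `"coverage"` mode each target voxel is probed with a regular
#' `subdiv^3` sub-grid of points and included when at least half of its
#' volume is covered by the source mask; `"nearest"` mode probes only the
#' voxel centre.
#'
#' @param rois an [ROISet].
#' @param targetGrid an [ImageGrid] object (e.g. a [RelaxationMap] or
#'   [ImageSeries]) or a list with `dim`, `voxelSize`, `fovOrigin`.
#' @param mode `"coverage"` (default) or `"nearest"`.
#' @param subdiv sampling points per axis in coverage mode.
#' @return An [ROISet] on the target grid (same `readerId`).
#' @export
transferROIs <- function(rois, targetGrid, mode = c("coverage", "nearest"),
                         subdiv = 4L) {
  stopifnot(is(rois, "ROISet"))
  mode <- match.arg(mode)
  tg <- .gridOf(targetGrid)
  sd_ <- dim(rois@mask); svs <- rois@voxelSize; so <- rois@fovOrigin
  td <- as.integer(tg$dim); tvs <- tg$voxelSize; to <- tg$fovOrigin

  ## FOV overlap check on voxel-extent bounding boxes
  sLo <- so - svs / 2; sHi <- so + (sd_ - 1) * svs + svs / 2
  tLo <- to - tvs / 2; tHi <- to + (td - 1) * tvs + tvs / 2
  if (any(sHi <= tLo) || any(tHi <= sLo))
    stop("source and target fields of view do not overlap")

  q <- if (mode == "nearest") 1L else as.integer(subdiv)
  ## world coordinates of target voxel centres, one vector per axis
  w <- lapply(1:3, function(a) .axisCoords(td[a], tvs[a], to[a]))
  acc <- array(0, td)
  offs1d <- lapply(1:3, function(a) ((seq_len(q) - 0.5) / q - 0.5) * tvs[a])
  srcIdx <- function(a, wpt) {
    i <- floor((wpt - (so[a] - svs[a] / 2)) / svs[a]) + 1
    ifelse(i >= 1 & i <= sd_[a], i, NA_integer_)
  }
  for (ox in offs1d[[1]]) for (oy in offs1d[[2]]) for (oz in offs1d[[3]]) {
    ix <- srcIdx(1, w[[1]] + ox); iy <- srcIdx(2, w[[2]] + oy)
    iz <- srcIdx(3, w[[3]] + oz)
    G <- as.matrix(expand.grid(ix, iy, iz))
    inside <- !is.na(G[, 1]) & !is.na(G[, 2]) & !is.na(G[, 3])
    hit <- numeric(nrow(G))
    hit[inside] <- as.numeric(rois@mask[G[inside, , drop = FALSE]])
    acc <- acc + array(hit, td)
  }
  roiSet(acc / q^3 >= 0.5, tvs, to, readerId = rois@readerId)
}

## in-plane binary dilation / erosion with the 8-neighbourhood
.morph2d <- function(sl, grow) {
  d <- dim(sl)
  out <- sl
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- matrix(if (grow) FALSE else TRUE, d[1], d[2])
    xs <- seq(max(1, 1 + dx), min(d[1], d[1] + dx))
    ys <- seq(max(1, 1 + dy), min(d[2], d[2] + dy))
    sh[xs, ys] <- sl[xs - dx, ys - dy]
    out <- if (grow) out | sh else out & sh
  }
  out
}

#' Synthetic second reader: perturb ROI boundaries
#'
#' Emulates manual-delineation variability by randomly dilating, eroding
#' (one voxel, in-plane 8-neighbourhood) or keeping each slice's ROI,
#' with equal probability, reproducibly from `seed`.
#'
#' @param rois an [ROISet].
#' @param seed integer seed.
#' @param readerId label for the synthetic reader.
#' @return A perturbed [ROISet].
#' @export
perturbROIs <- function(rois, seed, readerId = "readerB") {
  stopifnot(is(rois, "ROISet"))
  set.seed(seed)
  m <- rois@mask
  for (k in seq_len(dim(m)[3])) {
    if (!any(m[, , k])) next
    act <- sample(c("keep", "dilate", "erode"), 1)
    if (act == "dilate") m[, , k] <- .morph2d(m[, , k], grow = TRUE)
    else if (act == "erode") m[, , k] <- .morph2d(m[, , k], grow = FALSE)
  }
  roiSet(m, rois@voxelSize, rois@fovOrigin, readerId = readerId)
}

#' Interobserver agreement between two readers' volumetry
#'
#' Pearson correlation between the two readers' total-plaque-volume
#' vectors over the same cases.
#'
#' @param a,b lists of [ROISet], one per case, paired by position.
#' @return A [CorrelationResult] (see [pearsonCorrelation()]).
#' @export
interobserverAgreement <- function(a, b) {
  if (length(a) != length(b)) stop("reader lists must be paired by case")
  if (length(a) < 3L) stop("need at least 3 cases for a correlation")
  tpvA <- vapply(a, function(r) totalPlaqueVolume(r)@tpv, numeric(1))
  tpvB <- vapply(b, function(r) totalPlaqueVolume(r)@tpv, numeric(1))
  pearsonCorrelation(tpvA, tpvB)
}
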