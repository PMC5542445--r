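## NIfTI-1 and sidecar I/O.  Voxel size travels in the NIfTI pixdim;
## the field-of-view origin, delays, TR and seeds travel in the JSON
## manifest / sidecar, which is the authoritative grid metadata.

.writeVol <- function(arr, voxelSize, file) {
  im <- RNifti::asNifti(arr)
  im <- RNifti::`pixdim<-`(im, c(voxelSize, rep(1, length(dim(arr)) - 3L)))
  RNifti::writeNifti(im, file)
  invisible(file)
}

#' Write an image series as NIfTI plus JSON sidecar
#'
#' The series is stored as one 4D NIfTI file (x, y, z, delay) and a JSON
#' sidecar `{delays_ms, tr_ms, voxel_size_mm, fov_origin_mm}`.
#'
#' @param series an [ImageSeries].
#' @param prefix output path prefix; writes `<prefix>.nii` and
#'   `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
writeImageSeries <- function(series, prefix) {
  stopifnot(is(series, "ImageSeries"))
  .writeVol(series@volumes, series@voxelSize, paste0(prefix, ".nii"))
  jsonlite::write_json(
    list(delays_ms = series@delays, tr_ms = series@tr,
         voxel_size_mm = series@voxelSize, fov_origin_mm = series@fovOrigin),
    paste0(prefix, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(prefix)
}

#' Read an image series written by [writeImageSeries()]
#'
#' @param prefix path prefix used at write time.
#' @return An [ImageSeries].
#' @export
readImageSeries <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  img <- RNifti::readNifti(paste0(prefix, ".nii"))
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  new("ImageSeries", volumes = arr, delays = as.numeric(meta$delays_ms),
      tr = as.numeric(meta$tr_ms), voxelSize = as.numeric(meta$voxel_size_mm),
      fovOrigin = as.numeric(meta$fov_origin_mm))
}

#' Write an ROI set as a NIfTI label volume with JSON sidecar
#'
#' @param rois an [ROISet].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
writeROISet <- function(rois, prefix) {
  stopifnot(is(rois, "ROISet"))
  .writeVol(array(as.integer(rois@mask), dim(rois@mask)), rois@voxelSize,
            paste0(prefix, ".nii"))
  jsonlite::write_json(
    list(voxel_size_mm = rois@voxelSize, fov_origin_mm = rois@fovOrigin,
         reader_id = rois@readerId),
    paste0(prefix, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(prefix)
}

#' Read an ROI set written by [writeROISet()]
#' @param prefix path prefix used at write time.
#' @return An [ROISet].
#' @export
readROISet <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  img <- RNifti::readNifti(paste0(prefix, ".nii"))
  arr <- array(as.vector(img), dim(img))
  roiSet(arr != 0, as.numeric(meta$voxel_size_mm),
         as.numeric(meta$fov_origin_mm),
         readerId = as.character(meta$reader_id))
}

#' Write a fitted relaxation map as NIfTI volumes plus diagnostics CSV
#'
#' Writes `<prefix>_t1.nii`, `_r1.nii`, `_b.nii`, `_s0.nii`, `_mask.nii`
#' and a per-voxel diagnostics CSV (index, parameters, residual,
#' convergence flag) for the masked voxels.
#'
#' @param map a [RelaxationMap].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
writeRelaxationMap <- function(map, prefix) {
  stopifnot(is(map, "RelaxationMap"))
  .writeVol(map@t1Map, map@voxelSize, paste0(prefix, "_t1.nii"))
  .writeVol(map@r1Map, map@voxelSize, paste0(prefix, "_r1.nii"))
  .writeVol(map@bMap, map@voxelSize, paste0(prefix, "_b.nii"))
  .writeVol(map@s0Map, map@voxelSize, paste0(prefix, "_s0.nii"))
  .writeVol(array(as.integer(map@mask), dim(map@mask)), map@voxelSize,
            paste0(prefix, "_mask.nii"))
  idx <- which(map@mask, arr.ind = TRUE)
  utils::write.csv(
    data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
               s0 = map@s0Map[map@mask], t1_ms = map@t1Map[map@mask],
               b = map@bMap[map@mask], residual = map@residual[map@mask],
               converged = map@converged[map@mask]),
    paste0(prefix, "_fit.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Write a full paired study to a directory
#'
#' Emits pre/post SR series, pre/post anatomy, ground-truth label and T1
#' volumes, and a JSON manifest with protocol timing, grid metadata and
#' the seed.
#'
#' @param study a [PairedStudy].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "PairedStudy"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir)
  writeImageSeries(study@pre, file.path(dir, "sr_pre"))
  writeImageSeries(study@post, file.path(dir, "sr_post"))
  writeImageSeries(study@anatomyPre, file.path(dir, "anatomy_pre"))
  writeImageSeries(study@anatomyPost, file.path(dir, "anatomy_post"))
  tr <- study@truth
  .writeVol(array(as.integer(tr@labels), dim(tr@labels)), tr@voxelSize,
            file.path(dir, "truth_labels.nii"))
  .writeVol(tr@t1Pre, tr@voxelSize, file.path(dir, "truth_t1_pre.nii"))
  .writeVol(tr@t1Post, tr@voxelSize, file.path(dir, "truth_t1_post.nii"))
  .writeVol(tr@bMap, tr@voxelSize, file.path(dir, "truth_b.nii"))
  jsonlite::write_json(
    list(delays_ms = study@pre@delays, tr_ms = study@pre@tr,
         anatomy_ti_ms = study@anatomyPre@delays,
         anatomy_tr_ms = study@anatomyPre@tr,
         voxel_size_mm = study@pre@voxelSize,
         fov_origin_mm = study@pre@fovOrigin,
         anatomy_voxel_size_mm = study@anatomyPre@voxelSize,
         anatomy_fov_origin_mm = study@anatomyPre@fovOrigin,
         plaque_volume_mm3 = tr@plaqueVolume,
         seed = study@spec@seed),
    file.path(dir, "manifest.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
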