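#' @import methods
NULL

#' Voxel size of an image-grid object
#'
#' @param x an object carrying grid geometry.
#' @return Numeric vector of length 3, millimetres per axis.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Field-of-view origin
#'
#' World-space position (mm) of the centre of voxel `[1, 1, 1]`.
#'
#' @param x an object carrying grid geometry.
#' @return Numeric vector of length 3 (mm).
#' @export
setGeneric("fovOrigin", function(x) standardGeneric("fovOrigin"))

#' Grid dimensions
#'
#' @param x an object carrying grid geometry.
#' @return Integer vector of voxels per axis.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Voxel volume in cubic millimetres
#'
#' @param x an object carrying grid geometry.
#' @return Scalar, prod(voxelSize(x)).
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' Saturation delays of an image series
#'
#' @param x an [ImageSeries].
#' @return Numeric vector of delays (ms), one per volume.
#' @export
setGeneric("delays", function(x) standardGeneric("delays"))

#' Repetition time
#'
#' @param x an [ImageSeries].
#' @return TR in ms.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' T1 map accessor
#' @param x a [RelaxationMap] or [GroundTruth].
#' @param ... further arguments for methods.
#' @return 3D array of T1 (ms).
#' @export
setGeneric("t1Map", function(x, ...) standardGeneric("t1Map"))

#' R1 map accessor
#' @param x a [RelaxationMap].
#' @return 3D array of R1 (s^-1).
#' @export
setGeneric("r1Map", function(x) standardGeneric("r1Map"))

#' B (saturation-efficiency) map accessor
#' @param x a [RelaxationMap] or [GroundTruth].
#' @return 3D array of the dimensionless B parameter.
#' @export
setGeneric("bMap", function(x) standardGeneric("bMap"))

#' S0 map accessor
#' @param x a [RelaxationMap].
#' @return 3D array of fitted equilibrium signal (a.u.).
#' @export
setGeneric("s0Map", function(x) standardGeneric("s0Map"))

#' Fitted / valid voxel mask
#' @param x a map or ROI object.
#' @return Logical 3D array.
#' @export
setGeneric("imageMask", function(x) standardGeneric("imageMask"))

#' Compartment label volume
#' @param x a [GroundTruth].
#' @return Integer 3D array coded by [compartmentCodes()].
#' @export
setGeneric("compartmentLabels", function(x) standardGeneric("compartmentLabels"))

#' Ground-truth plaque volume
#' @param x a [GroundTruth].
#' @return Plaque volume in mm^3 (plaque-voxel count times voxel volume).
#' @export
setGeneric("plaqueVolume", function(x) standardGeneric("plaqueVolume"))

#' Reader label of an ROI set
#' @param x an [ROISet].
#' @return Character reader identifier.
#' @export
setGeneric("readerId", function(x) standardGeneric("readerId"))

#' Delta-R1 values
#' @param x a [DeltaR1Map].
#' @return 3D array of R1_post - R1_pre (s^-1), NA outside the mask.
#' @export
setGeneric("deltaR1Values", function(x) standardGeneric("deltaR1Values"))
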