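#' Radiomic feature schema
#'
#' Declares the exact named feature set extracted from every region, grouped
#' by class, and the settings that parameterize extraction. The full default
#' schema follows the common CT radiomics composition: 13 shape, 19
#' first-order and 75 texture features (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14,
#' NGTDM 5) on the original image, plus 8 wavelet sub-bands (single-level
#' undecimated 3-D Haar: LLL..HHH) each contributing 18 first-order
#' (TotalEnergy, a voxel-volume-scaled duplicate of Energy, is dropped in the
#' filtered bands) and the 75 texture features — 93 per band, 744 in total,
#' for a grand total of 851 features per region.
#'
#' @param n_bins fixed bin count for gray-level discretization of texture
#'   features (default 25), applied over each region's min-max range.
#' @param classes feature classes to include.
#' @param wavelet logical, include the 8 wavelet sub-band blocks.
#' @param min_voxels regions smaller than this trigger the degenerate-feature
#'   policy flagging (default 10).
#' @return list of class `feature_schema` with `feature_names`, per-class name
#'   lists, settings, and a `version` string.
#' @export
feature_schema <- function(n_bins = 25L,
                           classes = c("shape", "firstorder", "glcm", "glrlm",
                                       "glszm", "gldm", "ngtdm"),
                           wavelet = TRUE, min_voxels = 10L) {
  classes <- match.arg(classes, several.ok = TRUE)
  cls_names <- list(
    shape = shape_feature_names(),
    firstorder = firstorder_feature_names(),
    glcm = glcm_feature_names(),
    glrlm = glrlm_feature_names(),
    glszm = glszm_feature_names(),
    gldm = gldm_feature_names(),
    ngtdm = ngtdm_feature_names())
  stopifnot(lengths(cls_names)[c("shape", "firstorder", "glcm", "glrlm",
                                 "glszm", "gldm", "ngtdm")] ==
              c(13L, 19L, 24L, 16L, 16L, 14L, 5L))
  texture_classes <- intersect(classes, c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
  orig <- unlist(lapply(intersect(c("shape", "firstorder"), classes), function(cl)
    paste0("original_", cl, "_", cls_names[[cl]])), use.names = FALSE)
  orig <- c(orig, unlist(lapply(texture_classes, function(cl)
    paste0("original_", cl, "_", cls_names[[cl]])), use.names = FALSE))
  wav <- character(0)
  if (wavelet) {
    bands <- wavelet_band_names()
    per_band_fo <- if ("firstorder" %in% classes)
      setdiff(cls_names$firstorder, "TotalEnergy") else character(0)
    wav <- unlist(lapply(bands, function(b) {
      c(paste0("wavelet-", b, "_firstorder_", per_band_fo),
        unlist(lapply(texture_classes, function(cl)
          paste0("wavelet-", b, "_", cl, "_", cls_names[[cl]])), use.names = FALSE))
    }), use.names = FALSE)
  }
  feature_names <- c(orig, wav)
  stopifnot(!anyDuplicated(feature_names))
  full <- setequal(classes, c("shape", "firstorder", "glcm", "glrlm",
                              "glszm", "gldm", "ngtdm")) && wavelet
  if (full) stopifnot(length(feature_names) == 851L)
  structure(list(feature_names = feature_names, class_names = cls_names,
                 classes = classes, wavelet = wavelet,
                 n_bins = as.integer(n_bins), min_voxels = as.integer(min_voxels),
                 version = "habicat-schema-1"),
            class = "feature_schema")
}

wavelet_band_names <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

shape_feature_names <- function() c(
  "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity",
  "Maximum3DDiameter", "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
  "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
  "LeastAxisLength", "Elongation", "Flatness")

firstorder_feature_names <- function() c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10", "Percentile90",
  "Maximum", "Mean", "Median", "InterquartileRange", "Range",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "StandardDeviation", "Skewness", "Kurtosis", "Variance", "Uniformity")

glcm_feature_names <- function() c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "MCC", "SumAverage", "SumEntropy", "SumSquares")

glrlm_feature_names <- function() c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

glszm_feature_names <- function() c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

ngtdm_feature_names <- function() c(
  "Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

gldm_feature_names <- function() c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis", "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")
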