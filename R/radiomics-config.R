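# Extraction configuration and the pinned 105-feature roster.

RADSTAB_CATEGORIES <- c("shape", "firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")

SHAPE_NAMES <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity",
  "Maximum3DDiameter", "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
  "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
  "Elongation", "Flatness"
)

FIRSTORDER_NAMES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile", "90Percentile",
  "Maximum", "Mean", "Median", "InterquartileRange", "Range",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Skewness", "Kurtosis", "Variance", "Uniformity"
)

GLCM_NAMES <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumEntropy", "SumSquares"
)

GLRLM_NAMES <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"
)

GLSZM_NAMES <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)

GLDM_NAMES <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis", "GrayLevelNonUniformity",
  "DependenceNonUniformity", "DependenceNonUniformityNormalized",
  "GrayLevelVariance", "DependenceVariance", "DependenceEntropy",
  "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LargeDependenceHighGrayLevelEmphasis"
)

NGTDM_NAMES <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

#' Radiomic extraction configuration
#'
#' @param target_spacing resampling target voxel spacing (mm).
#' @param interpolator spline order for image resampling: 0 = nearest
#'   neighbour, 1 = trilinear (default). Masks always use nearest neighbour.
#' @param normalization z-score standardize intensities before extraction.
#' @param normalization_scope `"volume"` (statistics over the whole resampled
#'   volume, default) or `"roi"`.
#' @param n_bins fixed bin count for intensity discretization (default 64).
#' @param categories enabled feature families.
#' @param slicewise compute intensity/texture features per slice and average
#'   over contributing slices (default); shape features are always 3-D.
#' @return a `radiomics_config` list.
#' @export
radiomics_config <- function(target_spacing = c(1.458, 1.458, 5.5),
                             interpolator = 1, normalization = TRUE,
                             normalization_scope = c("volume", "roi"),
                             n_bins = 64, categories = RADSTAB_CATEGORIES,
                             slicewise = TRUE) {
  if (n_bins < 2) abort("n_bins must be >= 2", class = "radstab_parameter_error")
  stopifnot(all(target_spacing > 0), all(categories %in% RADSTAB_CATEGORIES))
  structure(list(target_spacing = as.numeric(target_spacing),
                 interpolator = interpolator, normalization = normalization,
                 normalization_scope = match.arg(normalization_scope),
                 n_bins = as.integer(n_bins), categories = categories,
                 slicewise = slicewise),
            class = "radiomics_config")
}

#' The pinned feature-name roster
#'
#' Returns the ordered names of the features produced by [extract_features()]
#' for the given configuration; the default seven-category roster has exactly
#' 105 entries.
#'
#' @param cfg a [radiomics_config()].
#' @return character vector of `category_FeatureName` strings.
#' @export
feature_manifest <- function(cfg = radiomics_config()) {
  sets <- list(shape = SHAPE_NAMES, firstorder = FIRSTORDER_NAMES,
               glcm = GLCM_NAMES, glrlm = GLRLM_NAMES, glszm = GLSZM_NAMES,
               gldm = GLDM_NAMES, ngtdm = NGTDM_NAMES)
  unlist(lapply(intersect(RADSTAB_CATEGORIES, cfg$categories),
                function(cat) paste0(cat, "_", sets[[cat]])), use.names = FALSE)
}
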