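# The fixed 549-entry pathomic feature registry. Family sizes are part of
# the extraction contract: morphology 16, intensity 20, texture 93,
# graph 49, wavelet 371 (4 x 93 Haar sub-band blocks minus one documented
# degenerate entry). Every extractor emits its family's block in registry
# order, so tile vectors, patient vectors and model inputs align by name.

morphology_feature_names <- function() {
  c(paste0("Morphology_",
           c("Area_Mean", "Perimeter_Mean", "MajorAxis_Mean",
             "MinorAxis_Mean", "Eccentricity_Mean", "Solidity_Mean",
             "Extent_Mean", "Circularity_Mean", "EquivalentDiameter_Mean",
             "AspectRatio_Mean")),
    paste0("Morphology_FSD_Band", 1:6))
}

intensity_feature_names <- function() {
  c(paste0("Intensity_",
           c("Minimum", "Maximum", "Mean", "Median", "Stddev", "MAD",
             "IQR", "Percentile10", "Percentile90", "Skewness",
             "Kurtosis", "HistogramEntropy")),
    paste0("Gradient_",
           c("Mean", "Stddev", "Skewness", "Kurtosis", "HistogramEntropy",
             "Energy", "EdgeCount", "EdgeFraction")))
}

firstorder_feature_names <- function() {
  paste0("FirstOrder_",
         c("Energy", "Entropy", "Minimum", "Percentile10", "Percentile90",
           "Maximum", "Mean", "Median", "InterquartileRange", "Range",
           "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
           "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
           "Uniformity", "StandardDeviation"))
}

glcm_feature_names <- function() {
  paste0("GLCM_",
         c("Autocorrelation", "JointAverage", "ClusterProminence",
           "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
           "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
           "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
           "Id", "Idn", "InverseVariance", "MaximumProbability",
           "SumAverage", "SumEntropy", "SumSquares", "MCC"))
}

glrlm_feature_names <- function() {
  paste0("GLRLM_",
         c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
           "RunLengthNonUniformityNormalized", "RunPercentage",
           "GrayLevelVariance", "RunVariance", "RunEntropy",
           "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
           "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
           "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
}

glszm_feature_names <- function() {
  paste0("GLSZM_",
         c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
           "SizeZoneNonUniformityNormalized", "ZonePercentage",
           "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
           "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
           "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
           "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
}

gldm_feature_names <- function() {
  paste0("GLDM_",
         c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
           "GrayLevelNonUniformity", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "GrayLevelVariance",
           "DependenceVariance", "DependenceEntropy",
           "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis",
           "SmallDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis",
           "LargeDependenceHighGrayLevelEmphasis"))
}

ngtdm_feature_names <- function() {
  paste0("NGTDM_", c("Coarseness", "Contrast", "Busyness", "Complexity",
                     "Strength"))
}

texture_feature_names <- function() {
  c(firstorder_feature_names(), glcm_feature_names(), glrlm_feature_names(),
    glszm_feature_names(), gldm_feature_names(), ngtdm_feature_names())
}

graph_measurement_names <- function() {
  c("Voronoi_Area", "Voronoi_Perimeter", "Voronoi_Max_Distance",
    "Delaunay_Sides", "Delaunay_Area", "Delaunay_Perimeter",
    "MST_Edge_Length", "NN_Distance_K1", "NN_Distance_K3",
    "NN_Distance_K5", "NN_Distance_K7", "NN_Distance_K9")
}

graph_feature_names <- function() {
  c(as.vector(t(outer(graph_measurement_names(),
                      c("Mean", "Stddev", "MinMaxRatio", "Disorder"),
                      paste, sep = "_"))),
    "Graph_Nuclei_Count")
}

# the one designated degenerate wavelet entry dropped so 4 x 93 -> 371
wavelet_excluded_feature <- function() "Wavelet_LL_FirstOrder_Minimum"

wavelet_feature_names <- function() {
  nm <- as.vector(vapply(c("LL", "LH", "HL", "HH"), function(b)
    paste0("Wavelet_", b, "_", texture_feature_names()),
    character(length(texture_feature_names()))))
  setdiff(nm, wavelet_excluded_feature())
}

#' The pathomic feature registry
#'
#' Returns the fixed, ordered registry of all 549 pathomic features:
#' 16 nuclear morphology / Fourier shape descriptor features, 20 nuclear
#' intensity and gradient features, 93 first- and second-order texture
#' features (18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
#' 5 NGTDM), 49 nuclear-architecture graph features, and 371 wavelet
#' features (the 93-feature texture block on each of the four Haar
#' sub-bands, minus the designated degenerate entry
#' `Wavelet_LL_FirstOrder_Minimum`). The order is stable across runs and
#' defines the column order of every feature table the package writes.
#'
#' @return a data.frame with columns `index`, `family` (one of
#'   `morphology`, `intensity`, `texture`, `graph`, `wavelet`) and `name`.
#' @examples
#' reg <- feature_registry()
#' table(reg$family)
#' nrow(reg)  # 549
#' @export
feature_registry <- function() {
  fam <- list(morphology = morphology_feature_names(),
              intensity = intensity_feature_names(),
              texture = texture_feature_names(),
              graph = graph_feature_names(),
              wavelet = wavelet_feature_names())
  df <- data.frame(
    family = rep(names(fam), lengths(fam)),
    name = unlist(fam, use.names = FALSE),
    stringsAsFactors = FALSE)
  df$index <- seq_len(nrow(df))
  df[, c("index", "family", "name")]
}

#' Write the feature registry as JSON
#'
#' Dumps the registry (`family`, `name`, `index`) to a JSON file so the
#' exact feature composition shipped with a given package version is
#' auditable outside R.
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(feature_registry(), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
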