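#' The standardized radiomic feature catalog
#'
#' Builds the full catalog of 487 standardized radiomic feature descriptors
#' across the 11 families used for image-biomarker work: morphology, local
#' intensity, intensity statistics, intensity histogram, intensity-volume
#' histogram, and the six texture families (GLCM, GLRLM, GLSZM, GLDZM, NGTDM,
#' NGLDM). GLCM/GLRLM carry six aggregation variants (2D/2.5D/3D x
#' averaged/merged); the zone/neighbourhood families carry three (2D, 2.5D,
#' 3D); first-order families carry none.
#'
#' Only the 3D / aggregation-free descriptors that do not depend on exact
#' geometry or absolute intensity calibration are ever computed
#' (\code{computed == TRUE}, 184 descriptors); 2D/2.5D, morphology and local
#' intensity entries exist so the selection cascade can account for them.
#'
#' @return A \code{data.frame} with columns \code{feature_id} (unique),
#'   \code{family}, \code{name}, \code{aggregation} and \code{computed},
#'   in canonical catalog order.
#' @examples
#' cat <- buildCatalog()
#' nrow(cat)            # 487
#' sum(cat$computed)    # 184
#' @export
buildCatalog <- function() {
  morph <- c(
    "volume_mesh", "volume_voxel", "surface_area", "surface_volume_ratio",
    "compactness_1", "compactness_2", "spherical_disproportion", "sphericity",
    "asphericity", "centre_of_mass_shift", "max_3d_diameter",
    "major_axis_length", "minor_axis_length", "least_axis_length",
    "elongation", "flatness", "volume_density_aabb", "area_density_aabb",
    "volume_density_ombb", "area_density_ombb", "volume_density_aee",
    "area_density_aee", "volume_density_mvee", "area_density_mvee",
    "volume_density_convex_hull", "area_density_convex_hull",
    "integrated_intensity", "morans_i", "gearys_c")
  locint <- c("local_intensity_peak", "global_intensity_peak")
  stat <- c(
    "mean", "variance", "skewness", "kurtosis", "median", "minimum", "p10",
    "p90", "maximum", "interquartile_range", "range",
    "mean_absolute_deviation", "robust_mean_absolute_deviation",
    "median_absolute_deviation", "coefficient_of_variation",
    "quartile_coefficient_of_dispersion", "energy", "root_mean_square")
  ih <- c(
    "mean", "variance", "skewness", "kurtosis", "median", "minimum", "p10",
    "p90", "maximum", "mode", "interquartile_range", "range",
    "mean_absolute_deviation", "robust_mean_absolute_deviation",
    "median_absolute_deviation", "coefficient_of_variation",
    "quartile_coefficient_of_dispersion", "entropy", "uniformity",
    "max_gradient", "max_gradient_level", "min_gradient",
    "min_gradient_level")
  ivh <- c("v10", "v90", "v10_minus_v90", "i10", "i90", "i10_minus_i90",
           "auc")
  glcm <- c(
    "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
    "difference_average", "difference_variance", "difference_entropy",
    "sum_average", "sum_variance", "sum_entropy", "angular_second_moment",
    "contrast", "dissimilarity", "inverse_difference",
    "inverse_difference_normalised", "inverse_difference_moment",
    "inverse_difference_moment_normalised", "inverse_variance",
    "correlation", "autocorrelation", "cluster_tendency", "cluster_shade",
    "cluster_prominence", "information_correlation_1",
    "information_correlation_2")
  glrlm <- c(
    "short_runs_emphasis", "long_runs_emphasis", "low_gl_run_emphasis",
    "high_gl_run_emphasis", "short_run_low_gl_emphasis",
    "short_run_high_gl_emphasis", "long_run_low_gl_emphasis",
    "long_run_high_gl_emphasis", "gl_non_uniformity",
    "gl_non_uniformity_normalised", "run_length_non_uniformity",
    "run_length_non_uniformity_normalised", "run_percentage",
    "gl_variance", "run_length_variance", "run_entropy")
  glszm <- c(
    "small_zone_emphasis", "large_zone_emphasis", "low_gl_zone_emphasis",
    "high_gl_zone_emphasis", "small_zone_low_gl_emphasis",
    "small_zone_high_gl_emphasis", "large_zone_low_gl_emphasis",
    "large_zone_high_gl_emphasis", "gl_non_uniformity",
    "gl_non_uniformity_normalised", "zone_size_non_uniformity",
    "zone_size_non_uniformity_normalised", "zone_percentage",
    "gl_variance", "zone_size_variance", "zone_size_entropy")
  gldzm <- c(
    "small_distance_emphasis", "large_distance_emphasis",
    "low_gl_zone_emphasis", "high_gl_zone_emphasis",
    "small_distance_low_gl_emphasis", "small_distance_high_gl_emphasis",
    "large_distance_low_gl_emphasis", "large_distance_high_gl_emphasis",
    "gl_non_uniformity", "gl_non_uniformity_normalised",
    "zone_distance_non_uniformity", "zone_distance_non_uniformity_normalised",
    "zone_percentage", "gl_variance", "zone_distance_variance",
    "zone_distance_entropy")
  ngtdm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  ngldm <- c(
    "low_dependence_emphasis", "high_dependence_emphasis",
    "low_gl_count_emphasis", "high_gl_count_emphasis",
    "low_dependence_low_gl_emphasis", "low_dependence_high_gl_emphasis",
    "high_dependence_low_gl_emphasis", "high_dependence_high_gl_emphasis",
    "gl_non_uniformity", "gl_non_uniformity_normalised",
    "dependence_count_non_uniformity",
    "dependence_count_non_uniformity_normalised",
    "dependence_count_percentage", "gl_variance",
    "dependence_count_variance", "dependence_count_entropy",
    "dependence_count_energy")

  agg6 <- c("2D_avg", "2D_merged", "2p5D_avg", "2p5D_merged",
            "3D_avg", "3D_merged")
  agg3 <- c("2D", "2p5D", "3D")

  block <- function(family, names, aggs) {
    do.call(rbind, lapply(aggs, function(a) {
      data.frame(family = family, name = names, aggregation = a,
                 stringsAsFactors = FALSE)
    }))
  }
  cat <- rbind(
    block("morphology", morph, "none"),
    block("local_intensity", locint, "none"),
    block("statistics", stat, "none"),
    block("intensity_histogram", ih, "none"),
    block("intensity_volume_histogram", ivh, "none"),
    block("GLCM", glcm, agg6),
    block("GLRLM", glrlm, agg6),
    block("GLSZM", glszm, agg3),
    block("GLDZM", gldzm, agg3),
    block("NGTDM", ngtdm, agg3),
    block("NGLDM", ngldm, agg3))

  prefix <- c(morphology = "morph", local_intensity = "locint",
              statistics = "stat", intensity_histogram = "ih",
              intensity_volume_histogram = "ivh", GLCM = "glcm",
              GLRLM = "glrlm", GLSZM = "glszm", GLDZM = "gldzm",
              NGTDM = "ngtdm", NGLDM = "ngldm")
  aggtag <- ifelse(cat$aggregation == "none", "",
                   paste0(tolower(gsub("p5", "5", cat$aggregation)), "_"))
  cat$feature_id <- paste0(prefix[cat$family], "_", aggtag, cat$name)
  cat$computed <- cat$aggregation %in% c("none", "3D", "3D_avg", "3D_merged") &
    !(cat$family %in% c("morphology", "local_intensity"))
  rownames(cat) <- NULL
  cat[, c("feature_id", "family", "name", "aggregation", "computed")]
}

#' Serialize the feature catalog to JSON
#'
#' @param path output file path.
#' @param catalog a catalog from [buildCatalog()].
#' @return `path`, invisibly.
#' @export
writeCatalogJSON <- function(path, catalog = buildCatalog()) {
  jsonlite::write_json(catalog, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
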