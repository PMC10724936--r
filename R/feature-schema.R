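#' Canonical feature schema
#'
#' The pipeline works on 26 lesion-level features: 12 geometric quantities
#' computed from the OCT lumen radius profile, the physician-annotated
#' minimal lumen diameter (MLD), and 13 clinical covariates. The canonical
#' column order below is also the reference ranking order used when pruning
#' collinear features on real data.
#'
#' @return Character vector of feature names.
#' @export
geometric_feature_names <- function() {
  c("mean_lumen_radius",
    "minimum_lumen_radius",
    "maximum_lumen_radius",
    "mean_lumen_radius_stenosis",
    "mean_radius_per_length",
    "maximum_radius_rapport",
    "stenosis_lesion_length",
    "percentage_diameter_reduction",
    "proximal_radius_rapport",
    "radius_rapport",
    "proximal_area",
    "distal_area")
}

#' @rdname geometric_feature_names
#' @export
clinical_feature_names <- function() {
  c("sex", "age", "height", "weight", "smoking", "aht", "dyslipidemia",
    "diabetes", "echo_ef", "diastolic_pattern", "ivs", "hb", "ht")
}

#' @rdname geometric_feature_names
#' @export
feature_names <- function() {
  c(geometric_feature_names(), "minimal_lumen_diameter",
    clinical_feature_names())
}

#' Published univariate model accuracies
#'
#' Per-feature accuracies of the 26 univariate models reported by the
#' original single-center study (80 patients / 102 lesions), as printed:
#' for each feature, the best of 12 base learners under tenfold
#' cross-validation over 10 seeds (mean, standard deviation, max, min, in
#' percent). These numbers are inputs to the feature-selection rule (mean
#' accuracy >= 60% keeps the top 14 rows); the private cohort behind them
#' is not available.
#'
#' @return Data frame with columns `rank`, `feature`, `algorithm`,
#'   `mean_acc`, `sd_acc`, `max_acc`, `min_acc`.
#' @export
published_univariate_accuracies <- function() {
  path <- system.file("extdata", "published_univariate_accuracies.csv",
                      package = "octffr", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
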