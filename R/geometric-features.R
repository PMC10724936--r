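#' Geometric stenosis features from a lumen radii profile
#'
#' Computes the 12 geometric quantities used as lesion features:
#' mean/min/max lumen radius over the analyzed segment, mean radius over the
#' stenosis region, mean radius per segment length, maximum radius rapport
#' `(r_max - r_min) / r_max`, stenosis length `lengthS`, percentage diameter
#' reduction `100 * (1 - 2 r_mean / (r_prox + r_dist))`, proximal radius
#' rapport `(r_prox - r_dist) / r_prox`, radius rapport
#' `((r_prox + r_dist)/2 - r_min) / ((r_prox + r_dist)/2)`, and the
#' proximal/distal lumen areas `pi r^2`.
#'
#' `r_prox` and `r_dist` are the radii at the annotated lesion boundary
#' frames (`lesion_start`, `lesion_end`); in clinical data these boundaries
#' are set by the medical expert. Lengths use `(end - start) * frame_spacing`
#' with inclusive frame means.
#'
#' @param profile A [radii_profile()].
#' @return Named list of the 12 features (units: mm, mm^2, %, unitless).
#' @export
compute_geometric_features <- function(profile) {
  stopifnot(inherits(profile, "radii_profile"))
  seg <- segment_radii(profile)
  les <- lesion_radii(profile)
  sp <- profile$frame_spacing

  r_mean <- mean(seg)
  r_min <- min(seg)
  r_max <- max(seg)
  r_prox <- profile$radii[profile$lesion_start + 1L]
  r_dist <- profile$radii[profile$lesion_end + 1L]
  seg_len <- (profile$segment_end - profile$segment_start) * sp
  length_s <- (profile$lesion_end - profile$lesion_start) * sp
  half_sum <- (r_prox + r_dist) / 2

  list(
    mean_lumen_radius = r_mean,
    minimum_lumen_radius = r_min,
    maximum_lumen_radius = r_max,
    mean_lumen_radius_stenosis = mean(les),
    mean_radius_per_length = r_mean / seg_len,
    maximum_radius_rapport = (r_max - r_min) / r_max,
    stenosis_lesion_length = length_s,
    percentage_diameter_reduction = 100 * (1 - 2 * r_mean / (r_prox + r_dist)),
    proximal_radius_rapport = (r_prox - r_dist) / r_prox,
    radius_rapport = (half_sum - r_min) / half_sum,
    proximal_area = pi * r_prox^2,
    distal_area = pi * r_dist^2
  )
}

#' Assemble the lesion-by-feature matrix
#'
#' Builds the 26-column feature matrix: 12 geometric features from each
#' lesion's radii profile, the physician-annotated minimal lumen diameter
#' (MLD, distinct from twice the computed minimum lumen radius), and the 13
#' clinical covariates of the lesion's patient. Any missing covariate is an
#' error naming the lesion and column; nothing is imputed.
#'
#' @param cohort An `oct_cohort` (see [generate_cohort()]) or a list with
#'   elements `lesions` (data frame with `lesion_id`, `patient_id`, `mld`),
#'   `patients` (data frame of clinical covariates) and `profiles` (named
#'   list of [radii_profile()]s).
#' @return Object of class `feature_matrix`: numeric matrix (lesions x 26,
#'   rownames = lesion ids) with attribute `normalized = FALSE`.
#' @export
assemble_feature_matrix <- function(cohort) {
  lesions <- cohort$lesions
  patients <- cohort$patients
  profiles <- cohort$profiles
  n <- nrow(lesions)
  cols <- feature_names()
  out <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(lesions$lesion_id, cols))
  clin <- clinical_feature_names()
  pidx <- match(lesions$patient_id, patients$patient_id)
  if (anyNA(pidx)) {
    stop("lesion ", lesions$lesion_id[which(is.na(pidx))[1]],
         " references an unknown patient")
  }
  for (i in seq_len(n)) {
    id <- lesions$lesion_id[i]
    prof <- profiles[[id]]
    if (is.null(prof)) stop("lesion ", id, " has no radii profile")
    geo <- compute_geometric_features(prof)
    out[i, names(geo)] <- unlist(geo)
    out[i, "minimal_lumen_diameter"] <- lesions$mld[i]
    prow <- patients[pidx[i], clin]
    # sex stored as F/M; encode numerically (F = 0, M = 1)
    prow$sex <- if (is.character(prow$sex) || is.factor(prow$sex)) {
      as.numeric(as.character(prow$sex) == "M")
    } else as.numeric(prow$sex)
    vals <- as.numeric(prow)
    if (anyNA(vals)) {
      bad <- clin[which(is.na(vals))[1]]
      stop("lesion ", id, ": missing clinical covariate '", bad, "'")
    }
    out[i, clin] <- vals
  }
  if (anyNA(out)) {
    bad <- which(is.na(out), arr.ind = TRUE)[1, ]
    stop("missing value for lesion ", rownames(out)[bad[1]],
         ", column '", cols[bad[2]], "'")
  }
  structure(out, normalized = FALSE, class = c("feature_matrix", "matrix", "array"))
}

#' L1-normalize a feature matrix
#'
#' Divides each feature column by the sum of absolute values of that column
#' (Manhattan norm), so every column's magnitudes sum to 1. Normalization is
#' per column, not per row: per-row normalization would mix units (mm,
#' years, percent) and break the meaning of univariate models.
#'
#' @param matrix A `feature_matrix` not yet normalized.
#' @return The normalized `feature_matrix` (attribute `normalized = TRUE`).
#' @export
l1_normalize <- function(matrix) {
  if (isTRUE(attr(matrix, "normalized"))) stop("matrix is already normalized")
  sums <- colSums(abs(matrix))
  if (any(sums == 0)) {
    stop("cannot L1-normalize all-zero column(s): ",
         paste(colnames(matrix)[sums == 0], collapse = ", "))
  }
  out <- sweep(matrix, 2, sums, "/")
  attr(out, "normalized") <- TRUE
  class(out) <- class(matrix)
  out
}

#' Pearson correlation matrix of features
#'
#' @param matrix A `feature_matrix` (or plain numeric matrix).
#' @param feature_subset Optional character vector of columns.
#' @return Symmetric matrix of Pearson coefficients; a constant column
#'   yields correlation 0 (with a warning) rather than NA.
#' @export
pearson_correlation_matrix <- function(matrix, feature_subset = colnames(matrix)) {
  if (length(feature_subset) < 1L) stop("feature subset is empty")
  if (nrow(matrix) < 3L) stop("need at least 3 rows for a correlation matrix")
  m <- matrix[, feature_subset, drop = FALSE]
  const <- apply(m, 2, function(x) isTRUE(all.equal(var(x), 0)) || var(x) == 0)
  cc <- suppressWarnings(cor(m))
  if (any(const)) {
    warning("constant column(s) ", paste(feature_subset[const], collapse = ", "),
            "; their correlations are set to 0")
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Drop perfectly correlated features
#'
#' Walks the features in rank order and removes any feature whose absolute
#' Pearson correlation with an already-kept feature reaches `threshold`
#' (default 0.999; "perfect" correlation is assessed with a floating-point
#' margin). The earlier-ranked member of each collinear pair is kept.
#'
#' @param matrix A `feature_matrix`.
#' @param threshold Absolute correlation cutoff in (0, 1].
#' @param rank_order Character vector giving the feature priority (first =
#'   highest rank). Defaults to column order.
#' @return List with `matrix` (pruned `feature_matrix`) and `removed`
#'   (character vector of dropped features, possibly empty).
#' @export
prune_perfectly_correlated <- function(matrix, threshold = 0.999,
                                       rank_order = colnames(matrix)) {
  stopifnot(all(rank_order %in% colnames(matrix)))
  cc <- pearson_correlation_matrix(matrix, rank_order)
  kept <- character(0)
  removed <- character(0)
  for (f in rank_order) {
    if (length(kept) > 0 && any(abs(cc[f, kept]) >= threshold)) {
      removed <- c(removed, f)
    } else {
      kept <- c(kept, f)
    }
  }
  keep_cols <- setdiff(colnames(matrix), removed)
  out <- matrix[, keep_cols, drop = FALSE]
  attr(out, "normalized") <- attr(matrix, "normalized")
  class(out) <- class(matrix)
  list(matrix = out, removed = removed)
}
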