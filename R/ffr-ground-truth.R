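#' Drift-corrected distal pressure
#'
#' The pressure drift `D` is the arithmetic difference between the aortic
#' and distal wire pressures recorded at the end of the pullback; the
#' corrected distal pressure is `Pd + D`.
#'
#' @param pd Measured distal pressure at the start of the FFR investigation
#'   (mmHg).
#' @param d Pressure drift (mmHg, integer).
#' @return `pd + d`.
#' @export
correct_distal_pressure <- function(pd, d) {
  stopifnot(all(pd > 0), all(d == round(d)), all(abs(d) <= 10))
  pd + d
}

#' Drift-corrected FFR
#'
#' Computes `corrected_Pd / Pa`, applying the drift correction only when the
#' drift magnitude is in the relevant set (default {2, 3} mmHg: drifts of
#' 0-1 mmHg are accepted as insignificant, while a drift beyond 3 mmHg
#' means the pressures should have been re-equalized and the measurement
#' repeated, so it triggers a warning rather than a silent correction).
#' Negative drifts in the relevant set are corrected with the signed
#' addition and flagged with a warning.
#'
#' @param pd,pa Distal and aortic pressures (mmHg), both > 0.
#' @param d Pressure drift (mmHg, integer).
#' @param drift_relevance Drift magnitudes (mmHg) that trigger correction.
#' @return Corrected FFR fraction; values > 1 are clamped to 1 with a
#'   warning.
#' @export
corrected_ffr <- function(pd, pa, d = 0, drift_relevance = c(2, 3)) {
  stopifnot(all(pa > 0), all(pd > 0), all(d == round(d)), all(abs(d) <= 10))
  if (any(abs(d) > max(drift_relevance))) {
    warning("drift beyond ", max(drift_relevance),
            " mmHg: pressures should be re-equalized and re-measured")
  }
  if (any(d < 0 & abs(d) %in% drift_relevance)) {
    warning("negative relevant drift corrected with signed addition")
  }
  relevant <- abs(d) %in% drift_relevance & abs(d) <= max(drift_relevance)
  ffr <- ifelse(relevant, (pd + d) / pa, pd / pa)
  if (any(ffr > 1)) {
    warning("corrected FFR > 1 clamped to 1")
    ffr <- pmin(ffr, 1)
  }
  ffr
}

#' Binary significance label
#'
#' A lesion is hemodynamically significant (class 1) when the corrected FFR
#' is less than or equal to the clinical cutoff 0.8; the boundary value 0.8
#' itself is class 1.
#'
#' @param ffr Corrected FFR value(s) in (0, 1.2).
#' @return Integer label(s) in {0, 1}.
#' @export
label_lesion <- function(ffr) {
  stopifnot(all(ffr > 0), all(ffr < 1.2))
  as.integer(ffr <= 0.8)
}

#' FFR uncertainty zone
#'
#' Classifies an FFR value against the clinical gray zone (default
#' `[0.75, 0.85]`, both bounds inclusive; a narrower `[0.75, 0.83]` zone is
#' used for one subgroup analysis).
#'
#' @param ffr FFR value(s).
#' @param lo,hi Zone bounds, `lo < hi`.
#' @return Character vector in {"below", "gray", "above"}.
#' @export
zone_of <- function(ffr, lo = 0.75, hi = 0.85) {
  stopifnot(lo < hi)
  ifelse(ffr > hi, "above", ifelse(ffr < lo, "below", "gray"))
}

#' Label a cohort from its pressure records
#'
#' Applies drift correction, FFR computation, significance labeling and
#' zone assignment to every lesion of a cohort table.
#'
#' @param lesions Data frame with columns `lesion_id`, `pd`, `pa`, `drift`.
#' @param drift_relevance Drift magnitudes (mmHg) that trigger correction.
#' @param zone_bounds Gray-zone bounds `c(lo, hi)`.
#' @return Data frame `lesion_id, corrected_ffr, label, zone, adjusted`
#'   where `adjusted` flags lesions whose corrected FFR differs from the
#'   raw `pd / pa`.
#' @export
label_cohort <- function(lesions, drift_relevance = c(2, 3),
                         zone_bounds = c(0.75, 0.85)) {
  ffr <- corrected_ffr(lesions$pd, lesions$pa, lesions$drift, drift_relevance)
  data.frame(
    lesion_id = lesions$lesion_id,
    corrected_ffr = ffr,
    label = label_lesion(ffr),
    zone = zone_of(ffr, zone_bounds[1], zone_bounds[2]),
    adjusted = abs(lesions$drift) %in% drift_relevance,
    stringsAsFactors = FALSE
  )
}
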