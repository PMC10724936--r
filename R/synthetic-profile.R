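#' Sample a synthetic lumen radii profile
#'
#' Emulates the 1-D radius-vs-length signal extracted from an OCT pullback:
#' a healthy lumen tapering linearly proximal-to-distal by fraction `taper`,
#' with a smooth raised-cosine narrowing of relative depth `severity` over
#' `lesion_length`, plus i.i.d. Gaussian radius noise (radii floored at
#' 0.1 mm). The raised-cosine shape makes the stenosis-region mean radius
#' distinct from the minimum radius, so the geometric features are not
#' degenerate. Markers are set to the segment ends and the lesion ends.
#'
#' @param severity Relative narrowing depth at lesion center, in [0, 1);
#'   `severity >= 1` (lumen closure) is rejected.
#' @param lesion_length Stenosis length (mm), shorter than the segment.
#' @param baseline_radius Healthy proximal radius (mm).
#' @param taper Fractional radius loss over the full segment.
#' @param noise_sd Radius measurement noise sd (mm).
#' @param segment_length Analyzed segment length (mm), at most 75 mm (one
#'   pullback).
#' @param lesion_center Lesion center position (mm); default mid-segment.
#' @param frame_spacing Frame spacing (mm); default 0.2 (5 frames/mm).
#' @param lesion_id Optional identifier.
#' @return A [radii_profile()].
#' @export
sample_radii_profile <- function(severity, lesion_length, baseline_radius,
                                 taper = 0, noise_sd = 0,
                                 segment_length = 40,
                                 lesion_center = segment_length / 2,
                                 frame_spacing = 0.2,
                                 lesion_id = NA_character_) {
  if (severity >= 1) stop("severity >= 1 would close the lumen")
  if (severity < 0) stop("severity must be >= 0")
  if (baseline_radius <= 0) stop("baseline_radius must be > 0")
  if (segment_length > 75) {
    stop("segment length > 75 mm exceeds one OCT pullback")
  }
  if (lesion_length <= 0 || lesion_length >= segment_length) {
    stop("lesion_length must be positive and shorter than the segment")
  }
  half <- lesion_length / 2
  if (lesion_center - half < 0 || lesion_center + half > segment_length) {
    stop("lesion extends beyond the segment")
  }
  n_frames <- round(segment_length / frame_spacing) + 1L
  x <- (seq_len(n_frames) - 1L) * frame_spacing
  healthy <- baseline_radius * (1 - taper * x / segment_length)
  inside <- abs(x - lesion_center) <= half
  depth <- numeric(n_frames)
  depth[inside] <- severity * healthy[inside] *
    0.5 * (1 + cos(2 * pi * (x[inside] - lesion_center) / lesion_length))
  r <- healthy - depth
  if (noise_sd > 0) r <- r + rnorm(n_frames, 0, noise_sd)
  r <- pmax(r, 0.1)
  radii_profile(
    r,
    lesion_start = round((lesion_center - half) / frame_spacing),
    lesion_end = round((lesion_center + half) / frame_spacing),
    segment_start = 0L,
    segment_end = n_frames - 1L,
    frame_spacing = frame_spacing,
    lesion_id = lesion_id
  )
}

#' FFR surrogate from lumen geometry
#'
#' A monotone stenosis pressure-drop surrogate linking lumen geometry to
#' FFR; the original study measures FFR invasively and never models
#' hemodynamics, so this surrogate exists only to give the synthetic cohort
#' a geometry-to-FFR coupling. Pressure drop is a viscous (Poiseuille-like)
#' term plus a turbulent expansion-loss term:
#' `dP = c_v * lengthS / r_min^4 * Q + c_t * (A_prox/A_min - 1)^2 * Q^2`,
#' and `FFR = clamp((Pa - dP)/Pa, 0.01, 1)`. The surrogate is monotone
#' decreasing in severity and in lesion length; a severity-0 profile gives
#' FFR within a fraction of a percent of 1 (the viscous term never vanishes
#' for an open lumen).
#'
#' @param profile A [radii_profile()].
#' @param pa Aortic pressure (mmHg), > 0.
#' @param flow Hyperemic flow (mL/s), > 0.
#' @param viscous_coeff Viscous coefficient (mmHg mm^3 s/mL).
#' @param turbulent_coeff Turbulent coefficient (mmHg s^2/mL^2).
#' @return FFR fraction in [0.01, 1].
#' @export
ffr_from_geometry <- function(profile, pa = 95, flow = 2,
                              viscous_coeff = 0.0664,
                              turbulent_coeff = 0.22) {
  stopifnot(pa > 0, flow > 0)
  seg <- segment_radii(profile)
  r_min <- min(seg)
  if (r_min <= 0) stop("r_min must be > 0")
  length_s <- (profile$lesion_end - profile$lesion_start) * profile$frame_spacing
  r_prox <- profile$radii[profile$lesion_start + 1L]
  area_ratio <- (r_prox / r_min)^2
  surrogate_ffr(r_min, length_s, area_ratio, pa, flow,
                viscous_coeff, turbulent_coeff)
}

# analytic core shared by ffr_from_geometry and severity inversion
surrogate_ffr <- function(r_min, length_s, area_ratio, pa, flow,
                          viscous_coeff, turbulent_coeff) {
  dp <- viscous_coeff * length_s / r_min^4 * flow +
    turbulent_coeff * (area_ratio - 1)^2 * flow^2
  pmin(pmax((pa - dp) / pa, 0.01), 1.0)
}

# zero-noise surrogate FFR as a function of severity for a lesion with the
# given healthy geometry (taper evaluated at the lesion center)
severity_to_ffr <- function(severity, lesion_length, baseline_radius, taper,
                            segment_length, lesion_center, pa, flow,
                            viscous_coeff, turbulent_coeff) {
  r_center <- baseline_radius * (1 - taper * lesion_center / segment_length)
  r_prox <- baseline_radius *
    (1 - taper * (lesion_center - lesion_length / 2) / segment_length)
  r_min <- r_center * (1 - severity)
  # the segment-wide minimum is the narrower of the lesion throat and the
  # tapered distal end
  r_distal_end <- baseline_radius * (1 - taper)
  r_min <- pmin(r_min, r_distal_end)
  surrogate_ffr(r_min, lesion_length, (r_prox / r_min)^2, pa, flow,
                viscous_coeff, turbulent_coeff)
}

# invert the surrogate: find the severity whose zero-noise FFR equals
# `target`; targets above the severity-0 FFR map to severity 0
invert_severity <- function(target, lesion_length, baseline_radius, taper,
                            segment_length, lesion_center, pa, flow,
                            viscous_coeff, turbulent_coeff) {
  f <- function(s) severity_to_ffr(s, lesion_length, baseline_radius, taper,
                                   segment_length, lesion_center, pa, flow,
                                   viscous_coeff, turbulent_coeff) - target
  if (f(0) <= 0) return(0)
  if (f(0.98) >= 0) return(0.98)
  uniroot(f, c(0, 0.98), tol = 1e-9)$root
}
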