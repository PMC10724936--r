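#' Synthetic cohort configuration
#'
#' Holds every knob of the synthetic cohort generator, defaulted to the
#' conditions of the single-center study the pipeline models: 80 patients
#' with 102 intermediate lesions, FFR concentrated in the 0.75-0.85 gray
#' zone (zone masses 25/47/30 out of 102 below / inside / above), vessel mix
#' 57/20/25 (LAD/LCX/RCA), and drift of 2 mmHg in 12 lesions and 3 mmHg in
#' 3 lesions. The FFR distribution is a mixture of zone-truncated normals:
#' the base mean and sd are calibrated once here (deterministic
#' root-finding) so the mixture mean and sd equal 0.80 and 0.08 exactly.
#'
#' @param n_patients Number of patients.
#' @param n_lesions Total lesion budget.
#' @param lesions_per_patient Probability vector over 1, 2, 3 lesions.
#' @param vessel_mix Named probability vector over LAD/LCX/RCA.
#' @param ffr_zone_masses Probability masses of the below/gray/above FFR
#'   zones.
#' @param ffr_zone_bounds Numeric `c(min, lo, hi, max)` FFR supports of the
#'   three zones.
#' @param ffr_mean,ffr_sd Target mean and sd of the FFR mixture.
#' @param drift_counts Named counts of lesions with drift 2 and 3 mmHg; the
#'   default scales the study's 12/3 out of 102 to `n_lesions`.
#' @param radius_noise_sd Radius measurement noise sd (mm).
#' @param pressure_noise_sd Aortic pressure variability sd (mmHg).
#' @param pa_mean Mean aortic pressure (mmHg).
#' @param pressure_resolution Pressure rounding granularity (mmHg; 0 =
#'   exact, used by inversion tests).
#' @param mld_noise_sd Physician MLD annotation noise sd (mm).
#' @param hemo_noise_sd Sd of the physiologic residual between measured FFR
#'   and what lumen geometry alone predicts (FFR units); 0 makes geometry
#'   fully determine FFR.
#' @param gray_zone_extra_noise_sd Extra geometry-vs-FFR residual sd applied
#'   only to gray-zone lesions (FFR units, default 0).
#' @param clinical_coupling Named coefficients (`weight` kg, `ht` percent)
#'   linking clinical covariates to the patient's mean FFR deficit; 0
#'   decouples them.
#' @param flow Hyperemic flow used by the pressure-drop surrogate (mL/s).
#' @param viscous_coeff,turbulent_coeff Surrogate coefficients
#'   (mmHg mm^3 s/mL and mmHg s^2/mL^2).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config including the seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 80L,
                          n_lesions = 102L,
                          lesions_per_patient = c(`1` = 0.775, `2` = 0.175, `3` = 0.05),
                          vessel_mix = c(LAD = 57, LCX = 20, RCA = 25) / 102,
                          ffr_zone_masses = c(below = 25, gray = 47, above = 30) / 102,
                          ffr_zone_bounds = c(0.40, 0.75, 0.85, 1.00),
                          ffr_mean = 0.80,
                          ffr_sd = 0.08,
                          drift_counts = NULL,
                          radius_noise_sd = 0.02,
                          pressure_noise_sd = 8,
                          pa_mean = 95,
                          pressure_resolution = 1,
                          mld_noise_sd = 0.1,
                          hemo_noise_sd = 0.05,
                          gray_zone_extra_noise_sd = 0,
                          clinical_coupling = c(weight = 40, ht = 25),
                          flow = 2,
                          viscous_coeff = 0.0664,
                          turbulent_coeff = 0.22,
                          seed = 1L) {
  if (is.null(drift_counts)) {
    drift_counts <- c(`2` = round(12 / 102 * n_lesions),
                      `3` = round(3 / 102 * n_lesions))
  }
  stopifnot(
    n_patients >= 1, n_lesions >= n_patients,
    abs(sum(lesions_per_patient) - 1) < 1e-9,
    abs(sum(vessel_mix) - 1) < 1e-9,
    abs(sum(ffr_zone_masses) - 1) < 1e-9,
    length(ffr_zone_bounds) == 4, !is.unsorted(ffr_zone_bounds),
    all(c(radius_noise_sd, pressure_noise_sd, mld_noise_sd,
          hemo_noise_sd, gray_zone_extra_noise_sd) >= 0),
    sum(drift_counts) <= n_lesions
  )
  base <- calibrate_ffr_mixture(ffr_zone_masses, ffr_zone_bounds,
                                ffr_mean, ffr_sd)
  structure(list(
    n_patients = as.integer(n_patients),
    n_lesions = as.integer(n_lesions),
    lesions_per_patient = lesions_per_patient,
    vessel_mix = vessel_mix,
    ffr_zone_masses = ffr_zone_masses,
    ffr_zone_bounds = ffr_zone_bounds,
    ffr_mean = ffr_mean, ffr_sd = ffr_sd,
    ffr_base_mean = base[["mean"]], ffr_base_sd = base[["sd"]],
    drift_counts = drift_counts,
    radius_noise_sd = radius_noise_sd,
    pressure_noise_sd = pressure_noise_sd,
    pa_mean = pa_mean,
    pressure_resolution = pressure_resolution,
    mld_noise_sd = mld_noise_sd,
    hemo_noise_sd = hemo_noise_sd,
    gray_zone_extra_noise_sd = gray_zone_extra_noise_sd,
    clinical_coupling = clinical_coupling,
    flow = flow,
    viscous_coeff = viscous_coeff,
    turbulent_coeff = turbulent_coeff,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# moments of N(mu, s) truncated to (a, b)
truncnorm_moments <- function(mu, s, a, b) {
  al <- (a - mu) / s
  be <- (b - mu) / s
  z <- pnorm(be) - pnorm(al)
  m <- mu + s * (dnorm(al) - dnorm(be)) / z
  v <- s^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z -
                ((dnorm(al) - dnorm(be)) / z)^2)
  c(mean = m, var = v)
}

# solve for the base normal whose zone-truncated mixture hits the target
# mean/sd; deterministic, run once per config
calibrate_ffr_mixture <- function(masses, bounds, target_mean, target_sd) {
  zones <- cbind(bounds[1:3], bounds[2:4])
  obj <- function(p) {
    mu <- p[1]; s <- exp(p[2])
    mom <- vapply(1:3, function(i)
      truncnorm_moments(mu, s, zones[i, 1], zones[i, 2]), numeric(2))
    mm <- sum(masses * mom[1, ])
    vv <- sum(masses * (mom[2, ] + mom[1, ]^2)) - mm^2
    (mm - target_mean)^2 + (sqrt(vv) - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-8) {
    stop("FFR mixture calibration failed: infeasible zone masses/bounds")
  }
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config: %d patients / %d lesions, FFR ~ %.2f +/- %.2f (base %.4f/%.4f), drift %s, seed %d>\n",
    x$n_patients, x$n_lesions, x$ffr_mean, x$ffr_sd,
    x$ffr_base_mean, x$ffr_base_sd,
    paste(names(x$drift_counts), x$drift_counts, sep = "mmHg x", collapse = ", "),
    x$seed))
  invisible(x)
}

#' Draw true FFR values from the calibrated zone mixture
#'
#' @param n Number of draws.
#' @param config A [cohort_config()].
#' @return Numeric vector of FFR fractions.
#' @export
sample_true_ffr <- function(n, config) {
  b <- config$ffr_zone_bounds
  zone <- sample.int(3, n, replace = TRUE, prob = config$ffr_zone_masses)
  lo <- b[zone]
  hi <- b[zone + 1]
  mu <- config$ffr_base_mean
  s <- config$ffr_base_sd
  p <- pnorm((lo - mu) / s) + runif(n) * (pnorm((hi - mu) / s) - pnorm((lo - mu) / s))
  qnorm(p) * s + mu
}
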