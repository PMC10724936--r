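#' Sample a pressure record encoding a known FFR
#'
#' Inverse of the drift-correction pipeline: draws an aortic pressure, sets
#' the drift-corrected distal pressure to `true_ffr * Pa` (rounded to the
#' instrument resolution), and records `Pd = corrected_Pd - drift`, so that
#' applying the drift correction and the FFR ratio recovers `true_ffr` up
#' to rounding (exactly, when `resolution = 0`).
#'
#' @param true_ffr FFR fraction in (0, 1].
#' @param drift Integer drift (mmHg, >= 0).
#' @param pa_mean Mean aortic pressure (mmHg).
#' @param noise_sd Aortic pressure sd (mmHg).
#' @param resolution Pressure rounding granularity (mmHg); 0 disables
#'   rounding.
#' @return Named numeric vector `c(pd, pa, drift)`.
#' @export
sample_pressures <- function(true_ffr, drift = 0, pa_mean = 95,
                             noise_sd = 0, resolution = 1) {
  stopifnot(true_ffr > 0, true_ffr <= 1, drift >= 0, drift == round(drift))
  pa <- pa_mean + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
  quantize <- function(x) if (resolution > 0) round(x / resolution) * resolution else x
  pa <- quantize(pa)
  corrected_pd <- quantize(true_ffr * pa)
  c(pd = corrected_pd - drift, pa = pa, drift = drift)
}

#' Sample a clinical record
#'
#' Draws the 13 clinical covariates from marginals matching the study
#' population: 82% male, age 60.5 +/- 11.2 years, BMI 27.7 +/- 2.5 kg/m^2
#' (height drawn by sex, weight from BMI), hypertension 75%, dyslipidemia
#' 77.5%, smoking history 52.5% (split past/present), diabetes 33.75%,
#' ejection fraction 48.28 +/- 6.31%. Weight and hematocrit optionally
#' carry a weak signal of the patient's mean FFR deficit through the
#' `coupling` coefficients; with all couplings 0 the clinical features are
#' independent of FFR.
#'
#' @param patient_id Identifier.
#' @param mean_ffr The patient's mean true FFR (drives the optional
#'   coupling; ignored when `coupling` is zero).
#' @param coupling Named coefficients `c(weight = , ht = )`.
#' @return One-row data frame with `patient_id` and the 13 covariates.
#' @export
sample_clinical <- function(patient_id, mean_ffr = 0.8,
                            coupling = c(weight = 0, ht = 0)) {
  sex <- if (runif(1) < 0.82) "M" else "F"
  age <- rnorm(1, 60.5, 11.2)
  height <- if (sex == "M") rnorm(1, 175, 7) else rnorm(1, 162, 6)
  bmi <- rnorm(1, 27.7, 2.5)
  deficit <- 0.80 - mean_ffr
  weight <- bmi * (height / 100)^2 + coupling[["weight"]] * deficit
  smoking <- sample(0:2, 1, prob = c(0.475, 0.275, 0.25))
  data.frame(
    patient_id = patient_id,
    sex = sex,
    age = max(age, 25),
    height = height,
    weight = max(weight, 40),
    smoking = smoking,
    aht = rbinom(1, 1, 0.75),
    dyslipidemia = rbinom(1, 1, 0.775),
    diabetes = rbinom(1, 1, 0.3375),
    echo_ef = min(max(rnorm(1, 48.28, 6.31), 15), 75),
    diastolic_pattern = sample(0:3, 1, prob = c(0.30, 0.45, 0.20, 0.05)),
    ivs = rnorm(1, 11.5, 1.6),
    hb = rnorm(1, 14.3, 1.5),
    ht = min(max(rnorm(1, 42.8, 4) + coupling[["ht"]] * deficit, 20), 60),
    stringsAsFactors = FALSE
  )
}

# draw per-patient lesion counts in {1,2,3} summing exactly to n_lesions
draw_lesion_counts <- function(n_patients, n_lesions, probs) {
  counts <- sample(1:3, n_patients, replace = TRUE, prob = probs)
  delta <- n_lesions - sum(counts)
  while (delta != 0) {
    if (delta > 0) {
      i <- sample(which(counts < 3), 1)
      counts[i] <- counts[i] + 1L
      delta <- delta - 1L
    } else {
      i <- sample(which(counts > 1), 1)
      counts[i] <- counts[i] - 1L
      delta <- delta + 1L
    }
  }
  counts
}

#' Generate a synthetic cohort
#'
#' Draws patients, lesions, lumen radii profiles, pressures and drift with
#' the statistical structure the downstream analysis assumes. True FFR is
#' drawn per lesion from the calibrated zone mixture; the stenosis severity
#' of each profile is then solved (root-finding on the pressure-drop
#' surrogate) so that geometry predicts `true_ffr` up to a physiologic
#' residual of sd `hemo_noise_sd`. Pressures encode `true_ffr` at 1-mmHg
#' resolution; drift of 2 and 3 mmHg is assigned to exactly the configured
#' numbers of lesions. Lesions of one patient share the patient's clinical
#' record. The cohort is a deterministic function of the config (including
#' its seed).
#'
#' @param config A [cohort_config()].
#' @return Object of class `oct_cohort`: list with `patients` (clinical
#'   records), `lesions` (one row per lesion: identifiers, vessel,
#'   proximal-LAD flag, pressures, drift, MLD, true FFR), `profiles`
#'   (named list of [radii_profile()]s) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (sum(config$drift_counts) > config$n_lesions) {
    stop("more drifted lesions than lesions")
  }
  set.seed(config$seed)
  np <- config$n_patients
  nl <- config$n_lesions

  counts <- draw_lesion_counts(np, nl, config$lesions_per_patient)
  patient_ids <- sprintf("P%03d", seq_len(np))
  lesion_patient <- rep(patient_ids, counts)
  lesion_ids <- sprintf("L%05d", seq_len(nl))

  true_ffr <- sample_true_ffr(nl, config)

  # drift: exactly the configured counts, assigned to random lesions
  drift <- integer(nl)
  pool <- sample.int(nl, sum(config$drift_counts))
  n2 <- config$drift_counts[["2"]]
  if (n2 > 0) drift[pool[seq_len(n2)]] <- 2L
  if (length(pool) > n2) drift[pool[(n2 + 1):length(pool)]] <- 3L

  vessels <- sample(names(config$vessel_mix), nl, replace = TRUE,
                    prob = config$vessel_mix)
  proximal_lad <- ifelse(vessels == "LAD", rbinom(nl, 1, 0.4), 0L)

  # clinical records, weakly coupled to the patient's mean true FFR
  patient_mean_ffr <- tapply(true_ffr, lesion_patient, mean)[patient_ids]
  patients <- do.call(rbind, lapply(seq_len(np), function(i) {
    sample_clinical(patient_ids[i], patient_mean_ffr[[i]],
                    config$clinical_coupling)
  }))

  sp <- 0.2
  zone <- zone_of(true_ffr, config$ffr_zone_bounds[2], config$ffr_zone_bounds[3])
  profiles <- vector("list", nl)
  names(profiles) <- lesion_ids
  pd <- pa <- mld <- numeric(nl)
  baseline_mean <- c(LAD = 1.75, LCX = 1.55, RCA = 1.85)
  baseline_sd <- c(LAD = 0.15, LCX = 0.15, RCA = 0.20)

  for (i in seq_len(nl)) {
    v <- vessels[i]
    baseline <- max(rnorm(1, baseline_mean[[v]], baseline_sd[[v]]), 1.2)
    seg_len <- round(runif(1, 25, 70) / sp) * sp
    les_len <- round(runif(1, 5, min(20, seg_len / 3)) / (2 * sp)) * 2 * sp
    taper <- runif(1, 0.05, 0.25)
    margin <- les_len / 2 + 2
    center <- round(runif(1, margin, seg_len - margin) / sp) * sp

    res_sd <- config$hemo_noise_sd +
      if (zone[i] == "gray") config$gray_zone_extra_noise_sd else 0
    geo_target <- true_ffr[i] + if (res_sd > 0) rnorm(1, 0, res_sd) else 0
    geo_target <- min(max(geo_target, 0.05), 1)
    sev <- invert_severity(geo_target, les_len, baseline, taper, seg_len,
                           center, config$pa_mean, config$flow,
                           config$viscous_coeff, config$turbulent_coeff)
    prof <- sample_radii_profile(sev, les_len, baseline, taper,
                                 config$radius_noise_sd, seg_len, center,
                                 frame_spacing = sp, lesion_id = lesion_ids[i])
    profiles[[i]] <- prof
    pres <- sample_pressures(true_ffr[i], drift[i], config$pa_mean,
                             config$pressure_noise_sd,
                             config$pressure_resolution)
    pd[i] <- pres[["pd"]]
    pa[i] <- pres[["pa"]]
    r_min <- min(segment_radii(prof))
    mld[i] <- max(2 * r_min + if (config$mld_noise_sd > 0)
      rnorm(1, 0, config$mld_noise_sd) else 0, 0.2)
  }

  lesions <- data.frame(
    lesion_id = lesion_ids,
    patient_id = lesion_patient,
    vessel = vessels,
    proximal_lad = as.integer(proximal_lad),
    pd = pd,
    pa = pa,
    drift = drift,
    mld = mld,
    true_ffr = true_ffr,
    stringsAsFactors = FALSE
  )
  structure(list(patients = patients, lesions = lesions,
                 profiles = profiles, config = config),
            class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf("<oct_cohort: %d patients, %d lesions, seed %d>\n",
              nrow(x$patients), nrow(x$lesions), x$config$seed))
  invisible(x)
}
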