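#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes `cohort.csv` (one lesion per row: identifiers,
#' vessel, proximal-LAD flag, pressures `pd`/`pa`/`drift`, physician `mld`,
#' and the patient's 13 clinical covariates) plus one
#' `profiles/<lesion_id>.csv` per lesion with header `frame,radius_mm` and a
#' sidecar `profiles/<lesion_id>.markers.json` holding `segment_start`,
#' `segment_end`, `lesion_start`, `lesion_end` (0-based inclusive frame
#' indices) and `frame_spacing`. `read_cohort()` is its inverse.
#'
#' @param cohort An `oct_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns an `oct_cohort`-shaped list (without a generator config).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  tab <- merge(cohort$lesions, cohort$patients, by = "patient_id", sort = FALSE)
  tab <- tab[order(match(tab$lesion_id, cohort$lesions$lesion_id)), ]
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE, quote = FALSE)
  for (id in names(cohort$profiles)) {
    p <- cohort$profiles[[id]]
    write.csv(data.frame(frame = seq_along(p$radii) - 1L,
                         radius_mm = p$radii),
              file.path(dir, "profiles", paste0(id, ".csv")),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(segment_start = p$segment_start, segment_end = p$segment_end,
           lesion_start = p$lesion_start, lesion_end = p$lesion_end,
           frame_spacing = p$frame_spacing),
      file.path(dir, "profiles", paste0(id, ".markers.json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tab <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  lesion_cols <- c("lesion_id", "patient_id", "vessel", "proximal_lad",
                   "pd", "pa", "drift", "mld",
                   intersect("true_ffr", names(tab)))
  lesions <- tab[, lesion_cols]
  patients <- unique(tab[, c("patient_id", clinical_feature_names())])
  rownames(patients) <- NULL
  profiles <- lapply(lesions$lesion_id, function(id) {
    sig <- read.csv(file.path(dir, "profiles", paste0(id, ".csv")))
    mk <- jsonlite::read_json(
      file.path(dir, "profiles", paste0(id, ".markers.json")),
      simplifyVector = TRUE)
    radii_profile(sig$radius_mm,
                  lesion_start = mk$lesion_start, lesion_end = mk$lesion_end,
                  segment_start = mk$segment_start, segment_end = mk$segment_end,
                  frame_spacing = mk$frame_spacing, lesion_id = id)
  })
  names(profiles) <- lesions$lesion_id
  structure(list(patients = patients, lesions = lesions,
                 profiles = profiles, config = NULL),
            class = "oct_cohort")
}
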