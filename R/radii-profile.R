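#' Lumen radii profile
#'
#' A 1-D lumen radius signal along a coronary vessel segment, one radius per
#' OCT frame, with frame-index markers delimiting the analyzed segment and
#' the stenosis (lesion) region. Frame indices are 0-based and inclusive;
#' physical positions are `index * frame_spacing` millimetres. The default
#' spacing of 0.2 mm corresponds to the 5 frames/mm pullback of the imaging
#' protocol; it is stored per profile so other pullback speeds remain
#' representable.
#'
#' @param radii Numeric vector of lumen radii in mm, one per frame; all > 0.
#' @param lesion_start,lesion_end 0-based frame indices of the annotated
#'   stenosis boundaries (inclusive).
#' @param segment_start,segment_end 0-based frame indices of the analyzed
#'   vessel segment (inclusive); default the whole signal.
#' @param frame_spacing Frame spacing in mm (default 0.2 mm = 5 frames/mm).
#' @param lesion_id Optional identifier.
#' @return Object of class `radii_profile`.
#' @export
radii_profile <- function(radii, lesion_start, lesion_end,
                          segment_start = 0L,
                          segment_end = length(radii) - 1L,
                          frame_spacing = 0.2,
                          lesion_id = NA_character_) {
  radii <- as.numeric(radii)
  if (length(radii) < 2L) stop("profile needs at least two frames")
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("all radii must be finite and > 0")
  }
  if (frame_spacing <= 0) stop("frame_spacing must be > 0")
  idx <- c(segment_start, lesion_start, lesion_end, segment_end)
  if (any(idx != round(idx))) stop("marker indices must be integers")
  if (!(segment_start <= lesion_start && lesion_start <= lesion_end &&
        lesion_end <= segment_end)) {
    stop("markers must satisfy segment_start <= lesion_start <= lesion_end <= segment_end")
  }
  if (segment_start < 0 || segment_end > length(radii) - 1L) {
    stop("segment markers out of bounds")
  }
  if (segment_end == segment_start) stop("zero-length segment")
  structure(list(
    lesion_id = lesion_id,
    frame_spacing = frame_spacing,
    radii = radii,
    segment_start = as.integer(segment_start),
    segment_end = as.integer(segment_end),
    lesion_start = as.integer(lesion_start),
    lesion_end = as.integer(lesion_end)
  ), class = "radii_profile")
}

#' @export
print.radii_profile <- function(x, ...) {
  cat(sprintf(
    "<radii_profile %s: %d frames @ %.2f mm, segment [%d,%d], lesion [%d,%d], r_min %.3f mm>\n",
    x$lesion_id, length(x$radii), x$frame_spacing,
    x$segment_start, x$segment_end, x$lesion_start, x$lesion_end,
    min(x$radii[(x$segment_start + 1L):(x$segment_end + 1L)])))
  invisible(x)
}

# radii over the analyzed segment (inclusive), 1-based view of 0-based markers
segment_radii <- function(profile) {
  profile$radii[(profile$segment_start + 1L):(profile$segment_end + 1L)]
}

lesion_radii <- function(profile) {
  profile$radii[(profile$lesion_start + 1L):(profile$lesion_end + 1L)]
}
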