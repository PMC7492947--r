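#' Corrected TIMI frame count (cTFC)
#'
#' Converts a raw TIMI frame count (cine-frames for contrast to reach
#' the standardized distal landmark) to the corrected count: LAD counts
#' are divided by 1.7 to compensate for the vessel's greater length,
#' LCX/RCA counts are unchanged, and an occluded vessel is scored 100
#' frames regardless of the recorded count.
#'
#' @param raw_tfc raw frame count(s), non-negative (ignored, may be `NA`,
#'   where `occluded` is `TRUE`).
#' @param vessel `"LAD"`, `"LCX"` or `"RCA"` (recycled).
#' @param occluded logical: vessel occluded (TIMI grade 0) at this
#'   timepoint (recycled).
#' @return Numeric vector of corrected frame counts, full precision
#'   (round only at report time).
#' @examples
#' ctfc(51, "LAD")            # 30
#' ctfc(36, "RCA")            # 36
#' ctfc(NA, "LCX", occluded = TRUE)  # 100
#' @export
ctfc <- function(raw_tfc, vessel, occluded = FALSE) {
  n <- max(length(raw_tfc), length(vessel), length(occluded))
  raw_tfc <- rep_len(raw_tfc, n)
  vessel <- rep_len(vessel, n)
  occluded <- rep_len(occluded, n)
  check_that(all(vessel %in% c("LAD", "LCX", "RCA")), "vessel",
             "must be LAD, LCX or RCA")
  bad <- !occluded & (is.na(raw_tfc) | raw_tfc < 0)
  if (any(bad)) {
    stop("invalid `raw_tfc`: must be non-negative for a non-occluded ",
         "vessel (offending index ", which(bad)[1], ")", call. = FALSE)
  }
  out <- ifelse(vessel == "LAD", raw_tfc / 1.7, raw_tfc)
  out[occluded] <- 100
  out
}
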