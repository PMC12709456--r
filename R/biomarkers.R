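# Amyloid-PET Centiloid conversion and positivity classification.

.centiloid_calib <- list(
  FBB = c(slope = 94.082, intercept = -94.772),   # Florbetaben
  FBP = c(slope = 110.982, intercept = -116.172)  # Florbetapir
)

#' Convert amyloid-PET SUVR to Centiloid units
#'
#' Tracer-specific affine calibrations:
#' Florbetaben \code{CL = 94.082 x SUVR - 94.772};
#' Florbetapir \code{CL = 110.982 x SUVR - 116.172}.
#'
#' @param suvr positive standardized uptake value ratio(s).
#' @param tracer \code{"FBB"} (Florbetaben) or \code{"FBP"} (Florbetapir);
#'   recycled against \code{suvr}.
#' @return Centiloid values.
#' @export
suvr_to_centiloid <- function(suvr, tracer) {
  if (any(suvr <= 0)) stop("SUVR must be positive")
  tracer <- rep_len(toupper(as.character(tracer)), length(suvr))
  bad <- setdiff(unique(tracer), names(.centiloid_calib))
  if (length(bad)) stop("unknown tracer(s): ", paste(bad, collapse = ", "))
  cal <- do.call(rbind, .centiloid_calib[tracer])
  unname(cal[, "slope"] * suvr + cal[, "intercept"])
}

#' Invert the Centiloid calibration back to SUVR
#'
#' @param centiloid Centiloid values.
#' @inheritParams suvr_to_centiloid
#' @return SUVR values.
#' @export
centiloid_to_suvr <- function(centiloid, tracer) {
  tracer <- rep_len(toupper(as.character(tracer)), length(centiloid))
  cal <- do.call(rbind, .centiloid_calib[tracer])
  unname((centiloid - cal[, "intercept"]) / cal[, "slope"])
}

#' Amyloid positivity from a global cortical Centiloid value
#'
#' Positive strictly above 24 CL.
#'
#' @param centiloid finite Centiloid value(s).
#' @return factor with levels \code{negative}, \code{positive}.
#' @export
amyloid_status <- function(centiloid) {
  if (any(!is.finite(centiloid))) stop("non-finite Centiloid value")
  factor(ifelse(centiloid > 24, "positive", "negative"),
         levels = c("negative", "positive"))
}
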