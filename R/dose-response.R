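#' Normalize plate signals to percent of vehicle control
#'
#' Divides each well's signal by the mean vehicle-control signal of its own
#' plate and multiplies by 100, so vehicle wells average exactly 100 per
#' plate and treated responses are comparable across plates.
#'
#' @param wells data.frame with columns `plate`, `well`, `concentration`
#'   (µM; vehicle wells at 0), `signal`, and logical `is_vehicle`.
#' @return The input data.frame with an added `response` column (% control).
#' @export
percent_control <- function(wells) {
  req <- c("plate", "concentration", "signal", "is_vehicle")
  miss <- setdiff(req, names(wells))
  if (length(miss)) {
    stop("wells is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wells$response <- NA_real_
  for (p in unique(wells$plate)) {
    on_plate <- wells$plate == p
    veh <- wells$is_vehicle & on_plate
    if (!any(veh)) stop("plate ", p, " has no vehicle wells", call. = FALSE)
    vmean <- mean(wells$signal[veh])
    if (!is.finite(vmean) || vmean <= 0) {
      stop("plate ", p, " has non-positive vehicle mean", call. = FALSE)
    }
    wells$response[on_plate] <- 100 * wells$signal[on_plate] / vmean
  }
  wells
}

#' Background-corrected LDH absorbance
#'
#' Cytotoxicity signal for the lactate dehydrogenase release assay:
#' absorbance at 490 nm minus the 680 nm background read. Negative
#' corrected values are passed through with a warning rather than clipped,
#' because clipping would bias control-relative normalization.
#'
#' @param a490 absorbance at 490 nm.
#' @param a680 background absorbance at 680 nm.
#' @return `a490 - a680`, vectorized.
#' @export
ldh_signal <- function(a490, a680) {
  out <- a490 - a680
  if (any(out < 0, na.rm = TRUE)) {
    warning(sum(out < 0, na.rm = TRUE),
            " negative background-corrected LDH value(s) passed through")
  }
  out
}

#' Mitochondrial membrane potential ratio
#'
#' JC-10 assay readout: the 525 nm emission divided by the 590 nm
#' emission; loss of membrane potential shifts the dye toward the 525 nm
#' monomer, raising the ratio.
#'
#' @param em525 fluorescence emission at 525 nm.
#' @param em590 fluorescence emission at 590 nm; must be nonzero.
#' @return `em525 / em590`, vectorized.
#' @export
mmp_ratio <- function(em525, em590) {
  if (any(em590 == 0, na.rm = TRUE)) {
    stop("zero 590 nm emission: ratio undefined", call. = FALSE)
  }
  em525 / em590
}
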