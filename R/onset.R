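#' Detect the onset time of an insole sensor channel
#'
#' Force-sensing-resistor channels are uncalibrated, so onset is defined
#' relative to the channel's own range: the time of the first sample at or
#' above `threshold_fraction` times the channel maximum within the supplied
#' window. A channel that never rises above zero has no onset and returns
#' `NA` (the footfall is unusable for onset-timing analysis).
#'
#' @param fsr Numeric vector, the sensor samples (arbitrary units, >= 0).
#' @param sampling_rate Sampling rate in Hz.
#' @param threshold_fraction Fraction of the channel maximum defining onset
#'   (default 0.1), in (0, 1).
#' @param t0 Time of the first sample in seconds (default 0), so windows cut
#'   from a longer trace keep absolute time.
#' @return Onset time in seconds, or `NA_real_` if the channel never crosses.
#' @examples
#' x <- c(rep(0, 119), seq(0, 1, length.out = 50))
#' detect_onset(x, 1000)
#' @export
detect_onset <- function(fsr, sampling_rate, threshold_fraction = 0.1, t0 = 0) {
  stopifnot(is.numeric(fsr), sampling_rate > 0,
            threshold_fraction > 0, threshold_fraction < 1)
  peak <- suppressWarnings(max(fsr, na.rm = TRUE))
  if (!is.finite(peak) || peak <= 0) {
    inform("Sensor channel never rises above zero; no onset.")
    return(NA_real_)
  }
  i <- which(fsr >= threshold_fraction * peak)[1]
  t0 + (i - 1) / sampling_rate
}

#' Onset-time difference between heel and toe sensors
#'
#' The onset-time difference (OTD) is the heel-sensor onset minus the
#' toe-sensor onset, in milliseconds. A negative OTD means the heel sensor
#' fired first (rearfoot landing); a positive OTD means the toe sensor fired
#' first (forefoot landing). Missing onsets propagate to a missing OTD.
#'
#' @param t_heel,t_toe Onset times in seconds (vectors recycle as usual).
#' @return OTD in ms: `(t_heel - t_toe) * 1000`.
#' @examples
#' compute_otd(0.100, 0.150)  # heel first: -50 ms
#' @export
compute_otd <- function(t_heel, t_toe) {
  stopifnot(is.numeric(t_heel), is.numeric(t_toe))
  (t_heel - t_toe) * 1000
}

#' Normalise an onset-time difference for foot length
#'
#' A longer foot takes longer to roll between heel and toe, scaling the OTD;
#' to compare subjects, the measured OTD is linearly corrected with the
#' ratio between the subject's foot length and a 23 cm standard. Two
#' scalings are offered: `"to_standard"` (default) multiplies by
#' `standard_length / foot_length`, mapping every subject onto the standard
#' foot; `"literal_ratio"` multiplies by `foot_length / standard_length`
#' (the inverse scaling); `"none"` leaves the value unchanged. The two
#' non-trivial modes are mutually inverse, and both preserve the sign of the
#' raw OTD.
#'
#' @param otd_raw OTD in ms.
#' @param foot_length Foot length(s) in cm; must be positive.
#' @param standard_length Standard foot length in cm (default 23).
#' @param mode Normalisation mode; see Details.
#' @return Normalised OTD in ms.
#' @examples
#' normalize_otd(-46, foot_length = 27.6)                 # -38.33 ms
#' normalize_otd(-46, foot_length = 27.6, mode = "literal_ratio")  # -55.2 ms
#' @export
normalize_otd <- function(otd_raw, foot_length, standard_length = 23,
                          mode = c("to_standard", "literal_ratio", "none")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(otd_raw), is.numeric(foot_length))
  if (any(!is.na(foot_length) & foot_length <= 0) || standard_length <= 0) {
    abort("foot_length and standard_length must be positive.")
  }
  switch(mode,
    to_standard = otd_raw * standard_length / foot_length,
    literal_ratio = otd_raw * foot_length / standard_length,
    none = otd_raw
  )
}
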