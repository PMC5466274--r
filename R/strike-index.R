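#' Strike index from the initial-contact centre of pressure
#'
#' The strike index (SI) is the position of the centre of pressure at
#' initial contact along the foot's long axis, expressed as a percentage of
#' foot length: 0% at the heel tip, 100% at the toe. SI in 0-33% indicates a
#' rearfoot strike, 34-66% a midfoot strike and 67-100% a forefoot strike.
#'
#' COP estimates can fall marginally outside the foot outline through plate
#' noise; such values are clamped to \[0, `foot_length`\] with a warning
#' rather than rejected.
#'
#' @param cop_ic_long Numeric vector, COP at initial contact along the foot
#'   axis (cm from the heel tip).
#' @param foot_length Foot length(s) in cm; scalar or vector matching
#'   `cop_ic_long`.
#' @return Numeric vector of SI values in percent, in \[0, 100\].
#' @examples
#' compute_si(c(0, 11.5, 7.59), foot_length = 23)
#' @export
compute_si <- function(cop_ic_long, foot_length) {
  stopifnot(is.numeric(cop_ic_long), is.numeric(foot_length))
  if (any(!is.na(foot_length) & foot_length <= 0)) {
    abort("foot_length must be positive.")
  }
  out_of_range <- !is.na(cop_ic_long) & !is.na(foot_length) &
    (cop_ic_long < 0 | cop_ic_long > foot_length)
  if (any(out_of_range)) {
    warn(sprintf("%d COP value(s) outside [0, foot_length]; clamped.",
                 sum(out_of_range)))
    cop_ic_long <- pmin(pmax(cop_ic_long, 0), foot_length)
  }
  100 * cop_ic_long / foot_length
}
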