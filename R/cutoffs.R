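#' Invert an agreement line into OTD classification cutoffs
#'
#' Solves `SI_target = B * OTD + intercept` for OTD at each strike-index
#' class boundary (by default 33% and 66%), turning a fitted or published
#' agreement line into the pair of onset-time-difference thresholds that
#' separates rearfoot, midfoot and forefoot strikes.
#'
#' Confidence bounds are obtained by substituting the 95% CI bounds of the
#' slope with the intercept held fixed: `ci_lower = (SI - intercept) /
#' B_lower` and `ci_upper = (SI - intercept) / B_upper`. The bounds are
#' reported in that slope-bound order (the convention of the reference
#' calibration tables), so `ci_lower`/`ci_upper` name the slope bound used,
#' not the numeric order.
#'
#' @param fit An `"si_otd_fit"` (fitted or [si_otd_line()]).
#' @param si_targets Strike-index boundaries in percent (default
#'   `c(33, 66)`).
#' @return A `"cutoff_window"` tibble with columns `scope`, `si_target`,
#'   `otd` (ms), `ci_lower`, `ci_upper`.
#' @examples
#' derive_cutoffs(si_otd_line(0.444, 45.84, ci95_B = c(0.441, 0.448)))
#' @export
derive_cutoffs <- function(fit, si_targets = c(33, 66)) {
  stopifnot(inherits(fit, "si_otd_fit"), is.numeric(si_targets),
            length(si_targets) >= 1)
  if (fit$B == 0) abort("Cannot invert a zero-slope line.")
  out <- tibble::tibble(
    scope = fit$scope,
    si_target = si_targets,
    otd = (si_targets - fit$intercept) / fit$B,
    ci_lower = (si_targets - fit$intercept) / fit$ci95_B[["lower"]],
    ci_upper = (si_targets - fit$intercept) / fit$ci95_B[["upper"]]
  )
  class(out) <- c("cutoff_window", class(out))
  out
}

#' Reference insole calibration
#'
#' The agreement lines estimated on the reference dataset: 109 adult
#' runners on an instrumented split-belt treadmill, 25,655 analysed
#' footfalls across level (0 deg), inclined (+10 deg) and declined
#' (-10 deg) running, all three instructed footstrike patterns. One row per
#' scope with the slope `B` (SI percent per ms), its 95% CI, the intercept
#' and the reported coefficient of determination.
#'
#' These coefficients let the package classify OTDs without access to a
#' force platform; [derive_cutoffs()] turns each row into the
#' classification time window for that surface.
#'
#' @return A tibble with columns `scope`, `B`, `ci_lower_B`, `ci_upper_B`,
#'   `intercept`, `r_squared`.
#' @examples
#' ref <- reference_lines()
#' derive_cutoffs(reference_line("flat"))
#' @export
reference_lines <- function() {
  tibble::tibble(
    scope = c("all", "flat", "inclined", "declined"),
    B = c(0.444, 0.440, 0.425, 0.507),
    ci_lower_B = c(0.441, 0.436, 0.420, 0.502),
    ci_upper_B = c(0.448, 0.444, 0.430, 0.512),
    intercept = c(45.84, 42.27, 57.02, 39.00),
    r_squared = c(0.836, 0.836, 0.799, 0.833)
  )
}

#' @describeIn reference_lines One scope of the reference calibration as an
#'   [si_otd_line()] object ready for [derive_cutoffs()] or [classify_otd()].
#' @param scope One of `"all"`, `"flat"`, `"inclined"`, `"declined"`.
#' @export
reference_line <- function(scope = c("all", "flat", "inclined", "declined")) {
  scope <- match.arg(scope)
  row <- dplyr::filter(reference_lines(), .data$scope == !!scope)
  si_otd_line(row$B, row$intercept, ci95_B = c(row$ci_lower_B, row$ci_upper_B),
              scope = scope, r_squared = row$r_squared)
}

#' Cutoff windows for every scope of a multi-scope fit
#'
#' @param fits Either the result of [fit_all_scopes()] (uses its attached
#'   fit objects) or a named list of `"si_otd_fit"` objects.
#' @param si_targets Strike-index boundaries in percent.
#' @return A `"cutoff_window"` tibble, one row per scope x boundary.
#' @export
derive_all_cutoffs <- function(fits, si_targets = c(33, 66)) {
  if (is.data.frame(fits)) fits <- attr(fits, "fits")
  stopifnot(is.list(fits), length(fits) >= 1)
  out <- purrr::map_dfr(fits, derive_cutoffs, si_targets = si_targets)
  class(out) <- c("cutoff_window", setdiff(class(out), "cutoff_window"))
  out
}
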