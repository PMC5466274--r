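#' Processing configuration
#'
#' Bundles every tunable of the signal-processing and analysis chain with its
#' documented default, so that a run can be reproduced from the configuration
#' echoed into its output metadata.
#'
#' @param contact_threshold Vertical ground-reaction-force level (N) whose
#'   rising crossing marks initial contact and whose falling crossing marks
#'   toe-off. Default 10 N, a conventional force-plate contact criterion.
#' @param filter_cutoff Low-pass cutoff (Hz) applied to force signals before
#'   event detection. Default 50 Hz.
#' @param filter_order Butterworth filter order (per pass). Default 4.
#' @param zero_phase Apply the filter forward and backward (no phase lag,
#'   squared magnitude response)? Default `TRUE`; event timing in gait
#'   analysis is conventionally extracted from zero-phase-filtered signals.
#' @param min_stance_ms Contact episodes shorter than this (ms) are discarded
#'   as noise during segmentation. Default 50 ms.
#' @param n_last_footfalls Number of trailing footfalls retained per trial
#'   (steady-state extraction). Default 30.
#' @param split_zone_halfwidth Half-width (cm) of the zone around the
#'   treadmill belt split; landings whose initial-contact centre of pressure
#'   falls inside it are unusable. Default 1 cm.
#' @param onset_threshold_fraction Insole-channel onset is the first sample
#'   at or above this fraction of the channel maximum. Default 0.1.
#' @param normalization_mode How the raw onset-time difference is corrected
#'   for foot length; see [normalize_otd()]. Default `"to_standard"`.
#' @param standard_length Standard foot length (cm) that normalisation maps
#'   onto. Default 23 cm.
#' @param si_bands Strike-index class boundaries (percent) separating
#'   rearfoot/midfoot/forefoot. Default `c(33, 66)`.
#' @param seed Optional integer seed recorded in output metadata and used for
#'   any randomised step.
#'
#' @return A named list with class `"solestrike_config"`.
#' @examples
#' cfg <- run_config(contact_threshold = 20)
#' cfg$contact_threshold
#' @export
run_config <- function(contact_threshold = 10,
                       filter_cutoff = 50,
                       filter_order = 4,
                       zero_phase = TRUE,
                       min_stance_ms = 50,
                       n_last_footfalls = 30,
                       split_zone_halfwidth = 1,
                       onset_threshold_fraction = 0.1,
                       normalization_mode = c("to_standard", "literal_ratio", "none"),
                       standard_length = 23,
                       si_bands = c(33, 66),
                       seed = NULL) {
  normalization_mode <- match.arg(normalization_mode)
  stopifnot(
    contact_threshold > 0,
    filter_cutoff > 0,
    filter_order >= 2, filter_order %% 2 == 0,
    min_stance_ms >= 0,
    n_last_footfalls >= 0,
    split_zone_halfwidth >= 0,
    onset_threshold_fraction > 0, onset_threshold_fraction < 1,
    standard_length > 0,
    length(si_bands) == 2, si_bands[1] < si_bands[2]
  )
  structure(
    list(
      contact_threshold = contact_threshold,
      filter_cutoff = filter_cutoff,
      filter_order = filter_order,
      zero_phase = zero_phase,
      min_stance_ms = min_stance_ms,
      n_last_footfalls = n_last_footfalls,
      split_zone_halfwidth = split_zone_halfwidth,
      onset_threshold_fraction = onset_threshold_fraction,
      normalization_mode = normalization_mode,
      standard_length = standard_length,
      si_bands = si_bands,
      seed = seed
    ),
    class = "solestrike_config"
  )
}

#' @export
print.solestrike_config <- function(x, ...) {
  cat("<solestrike_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(val)) "NULL" else paste(format(val), collapse = ", ")))
  }
  invisible(x)
}
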