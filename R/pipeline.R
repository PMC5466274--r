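#' Process raw sensor traces into footfall records
#'
#' Runs the full measurement chain on one trace set: low-pass filter the
#' vertical GRF, segment it into stances, keep the trailing
#' `n_last_footfalls`, read the strike index off the initial-contact centre
#' of pressure, flag split-belt landings from the lateral COP, detect the
#' heel and toe insole onsets within each stance window, and compute the raw
#' and foot-length-normalised onset-time differences.
#'
#' Split-belt landings are flagged, not dropped: the analysis stage
#' ([fit_si_on_otd()]) excludes them, which keeps the collected/analysed
#' footfall accounting visible.
#'
#' @param traces A `"sensor_traces"` object ([simulate_traces()],
#'   [simulate_trial()] or [read_traces()]).
#' @param config A [run_config()].
#' @return A tibble with one row per retained stance: identifier columns
#'   when present in the trace metadata, `t_ic`, `foot_length`, `si`,
#'   `otd_raw`, `otd_norm`, `split_belt`.
#' @examples
#' rec <- list(si = 15, otd_raw = -55, foot_length = 25, split_belt = FALSE)
#' process_traces(simulate_traces(rec))
#' @export
process_traces <- function(traces, config = run_config()) {
  stopifnot(inherits(traces, "sensor_traces"),
            inherits(config, "solestrike_config"))
  fs <- attr(traces, "sampling_rate")
  foot_length <- attr(traces, "foot_length")
  truth <- attr(traces, "truth")

  vgrf_f <- lowpass_filter(traces$vgrf, fs,
                           cutoff = config$filter_cutoff,
                           order = config$filter_order,
                           zero_phase = config$zero_phase)
  seg <- segment_stances(vgrf_f, fs,
                         contact_threshold = config$contact_threshold,
                         min_stance_ms = config$min_stance_ms,
                         cop_long = traces$cop_long, cop_lat = traces$cop_lat)
  seg <- keep_last_n(seg, config$n_last_footfalls)
  if (nrow(seg) == 0) {
    return(tibble::tibble(
      t_ic = numeric(), foot_length = numeric(), si = numeric(),
      otd_raw = numeric(), otd_norm = numeric(), split_belt = logical()
    ))
  }

  # onset window: open slightly before detected contact (the FSR can fire at
  # true contact, a fraction of a ms before the force threshold crossing) and
  # close at toe-off
  lead <- max(1L, round(0.020 * fs))
  onsets <- purrr::map(seq_len(nrow(seg)), function(k) {
    i0 <- max(1L, seg$i_ic[k] - lead)
    i1 <- seg$i_off[k]
    win <- seq.int(i0, i1)
    t0 <- (i0 - 1) / fs
    list(
      heel = detect_onset(traces$fsr_heel[win], fs,
                          threshold_fraction = config$onset_threshold_fraction,
                          t0 = t0),
      toe = detect_onset(traces$fsr_toe[win], fs,
                         threshold_fraction = config$onset_threshold_fraction,
                         t0 = t0)
    )
  })
  t_heel <- purrr::map_dbl(onsets, "heel")
  t_toe <- purrr::map_dbl(onsets, "toe")

  otd_raw <- compute_otd(t_heel, t_toe)
  out <- tibble::tibble(
    t_ic = seg$t_ic,
    foot_length = foot_length,
    si = compute_si(seg$cop_ic_long, foot_length),
    otd_raw = otd_raw,
    otd_norm = normalize_otd(otd_raw, foot_length,
                             standard_length = config$standard_length,
                             mode = config$normalization_mode),
    split_belt = !is.na(seg$cop_ic_lat) &
      abs(seg$cop_ic_lat) <= config$split_zone_halfwidth
  )
  for (extra in c("subject_id", "surface", "instructed_pattern")) {
    if (!is.null(truth[[extra]])) out[[extra]] <- truth[[extra]][1]
  }
  dplyr::relocate(out, dplyr::any_of(c("subject_id", "surface", "instructed_pattern")))
}
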