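#' Synthesise raw sensor traces for one footfall
#'
#' Builds the synchronized sampled channels one stance would produce on an
#' instrumented split-belt treadmill with a two-sensor insole: a half-sine
#' vertical GRF, a centre of pressure that starts at the strike-index
#' position and rolls monotonically toeward, a lateral COP inside or outside
#' the belt-split zone according to the record's flag, and two
#' force-sensing-resistor channels whose onsets are separated by exactly the
#' record's raw OTD (before sampling quantisation). The heel sensor onset is
#' at `t_ic + max(0, otd_raw)` and the toe sensor at `t_ic + max(0, -otd_raw)`,
#' so `t_heel - t_toe = otd_raw`.
#'
#' This generator emulates the signal features the processing chain depends
#' on (event timing, COP at contact, thresholds), not impact dynamics: there
#' is no impact transient, no noise floor, and no belt-speed variation.
#'
#' @param record One footfall: a one-row data frame or named list with at
#'   least `si` (percent), `otd_raw` (ms), `foot_length` (cm) and
#'   `split_belt` (logical). Extra identifier columns are carried into the
#'   trace metadata.
#' @param stance_duration Stance time in s (default 0.25).
#' @param sampling_rate Hz (default 1000); one clock for all channels.
#' @param t_pad Zero-force padding before initial contact and after toe-off,
#'   in s (default 0.1).
#' @param peak_force Half-sine peak in N (default 1500).
#' @param fsr_rise_ms Sensor rise time from onset to saturation, ms
#'   (default 20).
#' @param sensor_lag_range Two non-negative numbers (s): every FSR onset is
#'   delayed by one uniform draw from this range, emulating sensor response
#'   latency (< 3 ms for the reference hardware). Default `c(0, 0)` (ideal
#'   sensors; both channels keep their exact separation).
#' @param split_zone_halfwidth Half-width (cm) of the belt-split zone used to
#'   place the lateral COP (default 1).
#' @param contact_threshold Force level (N) below which the COP channels are
#'   undefined (off-plate), default 10.
#' @return A `"sensor_traces"` object: a tibble with columns `time`, `vgrf`,
#'   `cop_long`, `cop_lat`, `fsr_heel`, `fsr_toe` and attributes
#'   `sampling_rate`, `foot_length` and `truth` (the ground-truth stance
#'   table used by round-trip tests).
#' @examples
#' rec <- list(si = 20, otd_raw = -40, foot_length = 24, split_belt = FALSE)
#' tr <- simulate_traces(rec)
#' @export
simulate_traces <- function(record, stance_duration = 0.25, sampling_rate = 1000,
                            t_pad = 0.1, peak_force = 1500, fsr_rise_ms = 20,
                            sensor_lag_range = c(0, 0),
                            split_zone_halfwidth = 1, contact_threshold = 10) {
  record <- as.list(record)
  stopifnot(stance_duration > 0, sampling_rate > 0, t_pad >= 0,
            peak_force > 0, fsr_rise_ms > 0,
            length(sensor_lag_range) == 2, all(sensor_lag_range >= 0))
  otd_s <- record$otd_raw / 1000
  if (abs(otd_s) >= stance_duration) {
    abort(sprintf(
      "|otd_raw| = %.1f ms is not shorter than the stance (%g ms); onsets would fall outside it.",
      abs(record$otd_raw), stance_duration * 1000))
  }

  n <- round((stance_duration + 2 * t_pad) * sampling_rate) + 1L
  time <- (seq_len(n) - 1L) / sampling_rate
  t_ic <- t_pad
  t_off <- t_ic + stance_duration

  in_stance <- time >= t_ic & time <= t_off
  vgrf <- numeric(n)
  vgrf[in_stance] <- peak_force * sin(pi * (time[in_stance] - t_ic) / stance_duration)
  vgrf <- pmax(vgrf, 0)

  cop_ic <- record$si / 100 * record$foot_length
  cop_long <- rep(NA_real_, n)
  cop_long[in_stance] <- cop_ic +
    (record$foot_length - cop_ic) * (time[in_stance] - t_ic) / stance_duration
  lat <- if (isTRUE(record$split_belt)) 0.5 * split_zone_halfwidth
         else 5 * max(split_zone_halfwidth, 1)
  cop_lat <- rep(NA_real_, n)
  cop_lat[in_stance] <- lat

  lag <- runif(2, sensor_lag_range[1], sensor_lag_range[2])
  t_heel <- t_ic + max(0, otd_s) + lag[1]
  t_toe <- t_ic + max(0, -otd_s) + lag[2]
  fsr_channel <- function(t_on) {
    rise <- fsr_rise_ms / 1000
    y <- numeric(n)
    on <- time >= t_on & time <= t_off + rise
    # jump to 0.2 at onset so the first on-sample already exceeds a 10%
    # threshold, then ramp to saturation
    y[on] <- pmin(1, 0.2 + 0.8 * (time[on] - t_on) / rise)
    y
  }
  truth <- tibble::tibble(
    t_ic = t_ic, t_off = t_off,
    si = record$si, otd_raw = record$otd_raw,
    foot_length = record$foot_length,
    split_belt = isTRUE(record$split_belt),
    t_heel = t_heel, t_toe = t_toe
  )
  for (extra in c("subject_id", "surface", "instructed_pattern")) {
    if (!is.null(record[[extra]])) truth[[extra]] <- as.character(record[[extra]])
  }

  new_sensor_traces(
    tibble::tibble(
      time = time, vgrf = vgrf, cop_long = cop_long, cop_lat = cop_lat,
      fsr_heel = fsr_channel(t_heel), fsr_toe = fsr_channel(t_toe)
    ),
    sampling_rate = sampling_rate,
    foot_length = record$foot_length,
    truth = truth
  )
}

new_sensor_traces <- function(data, sampling_rate, foot_length, truth) {
  structure(data,
            sampling_rate = sampling_rate,
            foot_length = foot_length,
            truth = truth,
            class = c("sensor_traces", class(data)))
}

#' Synthesise a trial trace: a train of stances
#'
#' Concatenates single-stance traces for a set of footfall records from one
#' subject and condition into one continuous recording, separated by flight
#' gaps, as a treadmill trial would produce.
#'
#' @param records Footfall records (tibble, e.g. from
#'   [simulate_footfalls()]), one row per stance, in order.
#' @param gap Flight time between consecutive stances in s (default 0.15).
#' @inheritParams simulate_traces
#' @param ... Passed to [simulate_traces()].
#' @return A `"sensor_traces"` object whose `truth` attribute has one row
#'   per stance (with absolute `t_ic`).
#' @examples
#' ff <- simulate_footfalls(population_spec(n_subjects = 1,
#'   footfalls_per_condition = 3, seed = 2))
#' tr <- simulate_trial(dplyr::filter(ff, surface == "flat",
#'   instructed_pattern == "RFS"))
#' @export
simulate_trial <- function(records, gap = 0.15, stance_duration = 0.25,
                           sampling_rate = 1000, ...) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (length(unique(records$foot_length)) > 1) {
    abort("All records in one trial must share a foot_length (one subject).")
  }
  pieces <- purrr::map(seq_len(nrow(records)), function(i) {
    simulate_traces(records[i, ], stance_duration = stance_duration,
                    sampling_rate = sampling_rate, t_pad = gap / 2, ...)
  })
  offsets <- c(0, cumsum(purrr::map_dbl(pieces, ~ nrow(.x) / sampling_rate))[-length(pieces)])
  data <- purrr::map2_dfr(pieces, offsets, function(p, off) {
    p$time <- p$time + off
    tibble::as_tibble(p)
  })
  truth <- purrr::map2_dfr(pieces, offsets, function(p, off) {
    tr <- attr(p, "truth")
    tr$t_ic <- tr$t_ic + off
    tr$t_off <- tr$t_off + off
    tr$t_heel <- tr$t_heel + off
    tr$t_toe <- tr$t_toe + off
    tr
  })
  new_sensor_traces(data, sampling_rate = sampling_rate,
                    foot_length = records$foot_length[1], truth = truth)
}

#' @export
print.sensor_traces <- function(x, ...) {
  fs <- attr(x, "sampling_rate")
  tr <- attr(x, "truth")
  cat(sprintf("<sensor_traces> %d samples @ %g Hz (%.2f s), %d stance(s), foot %g cm\n",
              nrow(x), fs, nrow(x) / fs, nrow(tr), attr(x, "foot_length")))
  NextMethod()
}
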