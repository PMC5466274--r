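#' Segment a vertical GRF signal into stance phases
#'
#' A stance opens at the first sample where the (filtered) vertical ground
#' reaction force rises through `contact_threshold` and closes where it falls
#' back through it. Episodes shorter than `min_stance_ms` are discarded as
#' noise, and a trailing episode still above threshold at the end of the
#' signal is dropped as incomplete. When centre-of-pressure channels are
#' supplied, each stance also records the COP at initial contact: the first
#' non-missing COP sample at or after the contact sample (COP is undefined
#' off the plate).
#'
#' @param vgrf Numeric vector, vertical GRF in N (already low-pass filtered).
#' @param sampling_rate Sampling rate in Hz.
#' @param contact_threshold Contact criterion in N (default 10).
#' @param min_stance_ms Minimum stance duration retained, in ms (default 50).
#' @param cop_long,cop_lat Optional numeric vectors, same length as `vgrf`:
#'   COP along the foot axis (cm, 0 = heel tip) and lateral COP (cm, 0 =
#'   belt-split midline). May contain `NA` where the foot is off the plate.
#' @return A tibble with one row per stance: `stance`, sample indices
#'   `i_ic`/`i_off`, times `t_ic`/`t_off` (s, first sample = 0), and when COP
#'   was given, `cop_ic_long` and `cop_ic_lat`.
#' @examples
#' fs <- 1000
#' vgrf <- rep(0, 600)
#' vgrf[101:350] <- 800 * sinpi(seq_len(250) / 250)
#' segment_stances(vgrf, fs)
#' @export
segment_stances <- function(vgrf, sampling_rate, contact_threshold = 10,
                            min_stance_ms = 50, cop_long = NULL, cop_lat = NULL) {
  stopifnot(is.numeric(vgrf), sampling_rate > 0, contact_threshold > 0)
  empty <- tibble::tibble(
    stance = integer(), i_ic = integer(), i_off = integer(),
    t_ic = numeric(), t_off = numeric()
  )
  if (!is.null(cop_long)) empty$cop_ic_long <- numeric()
  if (!is.null(cop_lat)) empty$cop_ic_lat <- numeric()
  if (length(vgrf) == 0) return(empty)

  above <- vgrf > contact_threshold
  d <- diff(c(FALSE, above))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  # drop an unterminated trailing stance
  if (length(starts) > length(ends)) starts <- starts[seq_along(ends)]
  if (length(starts) == 0) return(empty)

  dur_ms <- (ends - starts + 1L) / sampling_rate * 1000
  keep <- dur_ms >= min_stance_ms
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) == 0) return(empty)

  out <- tibble::tibble(
    stance = seq_along(starts),
    i_ic = as.integer(starts),
    i_off = as.integer(ends),
    t_ic = (starts - 1) / sampling_rate,
    t_off = (ends - 1) / sampling_rate
  )
  first_defined <- function(channel, i0, i1) {
    idx <- seq.int(i0, i1)
    v <- channel[idx]
    v <- v[!is.na(v)]
    if (length(v)) v[1] else NA_real_
  }
  if (!is.null(cop_long)) {
    stopifnot(length(cop_long) == length(vgrf))
    out$cop_ic_long <- purrr::map2_dbl(out$i_ic, out$i_off,
                                       ~ first_defined(cop_long, .x, .y))
  }
  if (!is.null(cop_lat)) {
    stopifnot(length(cop_lat) == length(vgrf))
    out$cop_ic_lat <- purrr::map2_dbl(out$i_ic, out$i_off,
                                      ~ first_defined(cop_lat, .x, .y))
  }
  out
}

#' Keep the last n stances of a trial
#'
#' Running trials are analysed on their trailing, steady-state footfalls;
#' this returns the final `n` rows of a stance (or footfall) table, in
#' order. If fewer than `n` are available, all rows are returned with a
#' warning.
#'
#' @param segments A tibble of stances or footfall records, in time order.
#' @param n Number of trailing rows to keep (default 30).
#' @return A tibble with `min(n, nrow(segments))` rows.
#' @export
keep_last_n <- function(segments, n = 30) {
  stopifnot(is.data.frame(segments), n >= 0)
  if (nrow(segments) < n) {
    warn(sprintf("Only %d footfalls available; %d requested. Keeping all.",
                 nrow(segments), n))
    return(segments)
  }
  dplyr::slice_tail(segments, n = n)
}

#' Exclude landings on the treadmill belt split
#'
#' A landing whose initial-contact centre of pressure lies within
#' `split_zone_halfwidth` of the belt-split midline straddles both force
#' plates and yields an unusable COP. This removes such rows (those with
#' `|cop_ic_lat| <= split_zone_halfwidth`), preserving the order of the
#' survivors.
#'
#' @param segments A tibble containing a `cop_ic_lat` column (cm, 0 = split
#'   midline).
#' @param split_zone_halfwidth Half-width of the unusable zone in cm
#'   (default 1).
#' @return A list with elements `kept` (the surviving rows, in order) and
#'   `n_excluded` (count removed).
#' @export
exclude_split_belt <- function(segments, split_zone_halfwidth = 1) {
  stopifnot(is.data.frame(segments), split_zone_halfwidth >= 0)
  if (!"cop_ic_lat" %in% names(segments)) {
    abort("`segments` must contain a `cop_ic_lat` column.")
  }
  inside <- !is.na(segments$cop_ic_lat) &
    abs(segments$cop_ic_lat) <= split_zone_halfwidth
  list(
    kept = segments[!inside, , drop = FALSE],
    n_excluded = sum(inside)
  )
}
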