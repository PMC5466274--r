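#' Study-population specification for the synthetic-gait generator
#'
#' Describes a split-belt treadmill study in which every subject runs on each
#' surface inclination with each instructed footstrike pattern, contributing a
#' fixed number of footfalls per condition. Defaults reproduce the reference
#' design: 109 subjects x 3 surfaces (level, +10 deg, -10 deg) x 3 instructed
#' patterns x 30 footfalls = 29,430 footfalls, of which a fraction
#' 3775/29430 straddles the belt split and is flagged unusable.
#'
#' The statistical core is the per-surface agreement line between strike
#' index (SI, percent of foot length) and foot-length-normalised onset-time
#' difference (OTD, ms): `SI = intercept + slope * OTD` plus Gaussian
#' measurement scatter of the strike index about the line. `noise_sd_by_surface`
#' expresses that scatter in OTD-equivalent milliseconds (the SI residual SD
#' is `slope * noise_sd`); the defaults are calibrated so the per-surface
#' coefficient of determination lands at 0.836 / 0.799 / 0.833 for
#' flat / inclined / declined.
#'
#' @param n_subjects Number of subjects.
#' @param surfaces Surface inclinations included (subset of
#'   `c("flat", "inclined", "declined")`; flat = 0 deg, inclined = +10 deg,
#'   declined = -10 deg).
#' @param patterns Instructed footstrike patterns (subset of
#'   `c("RFS", "MFS", "FFS")`).
#' @param footfalls_per_condition Footfalls retained per subject x surface x
#'   pattern cell.
#' @param slope_by_surface Named numeric, SI percent per ms; the agreement
#'   slope of each surface. All entries must be positive.
#' @param intercept_by_surface Named numeric, SI percent at OTD = 0.
#' @param noise_sd_by_surface Named numeric, ms; SD of the strike-index
#'   scatter about the line, in OTD-equivalent units.
#' @param si_pattern_mean Named numeric, percent; centre of the achieved
#'   strike-index distribution for each instructed pattern.
#' @param si_pattern_sd Percent; within-condition SD of the achieved strike
#'   index target.
#' @param exclusion_rate Probability that a footfall lands on the belt split
#'   and is flagged unusable. Default 3775/29430.
#' @param foot_length_mean,foot_length_sd,foot_length_range Per-subject foot
#'   length distribution (cm): truncated normal.
#' @param standard_length Standard foot length (cm) used by the OTD
#'   normalisation the generator inverts to produce raw OTDs.
#' @param seed Optional integer; makes generation fully reproducible.
#'
#' @return A `"population_spec"` object (named list).
#' @seealso [simulate_footfalls()], [simulate_traces()]
#' @examples
#' spec <- population_spec(n_subjects = 4, footfalls_per_condition = 5, seed = 1)
#' nrow(simulate_footfalls(spec))  # 4 * 3 * 3 * 5
#' @export
population_spec <- function(n_subjects = 109,
                            surfaces = SURFACE_LEVELS,
                            patterns = PATTERN_LEVELS,
                            footfalls_per_condition = 30,
                            slope_by_surface = c(flat = 0.440, inclined = 0.425, declined = 0.507),
                            intercept_by_surface = c(flat = 42.27, inclined = 57.02, declined = 39.00),
                            noise_sd_by_surface = c(flat = 21.155, inclined = 24.801, declined = 18.560),
                            si_pattern_mean = c(RFS = 25, MFS = 50, FFS = 75),
                            si_pattern_sd = 5,
                            exclusion_rate = 3775 / 29430,
                            foot_length_mean = 24,
                            foot_length_sd = 1.5,
                            foot_length_range = c(20, 30),
                            standard_length = 23,
                            seed = NULL) {
  surfaces <- as.character(surfaces)
  patterns <- as.character(patterns)
  bad_surf <- setdiff(surfaces, SURFACE_LEVELS)
  if (length(bad_surf)) {
    abort(paste0("Unknown surface value(s): ", paste(bad_surf, collapse = ", "),
                 " (surfaces must be among ", paste(SURFACE_LEVELS, collapse = ", "), ")"))
  }
  bad_pat <- setdiff(patterns, PATTERN_LEVELS)
  if (length(bad_pat)) {
    abort(paste0("Unknown pattern value(s): ", paste(bad_pat, collapse = ", "),
                 " (patterns must be among ", paste(PATTERN_LEVELS, collapse = ", "), ")"))
  }
  if (n_subjects < 1 || footfalls_per_condition < 1 ||
      length(surfaces) < 1 || length(patterns) < 1) {
    abort("All design counts (subjects, surfaces, patterns, footfalls) must be >= 1.")
  }
  if (exclusion_rate < 0 || exclusion_rate > 1) {
    abort("exclusion_rate must lie in [0, 1].")
  }
  for (s in surfaces) {
    if (is.na(slope_by_surface[s]) || slope_by_surface[s] <= 0) {
      abort(paste0("slope_by_surface must supply a positive slope for surface '", s, "'."))
    }
    if (is.na(intercept_by_surface[s])) {
      abort(paste0("intercept_by_surface is missing surface '", s, "'."))
    }
    if (is.na(noise_sd_by_surface[s]) || noise_sd_by_surface[s] < 0) {
      abort(paste0("noise_sd_by_surface must supply a non-negative SD for surface '", s, "'."))
    }
  }
  for (p in patterns) {
    if (is.na(si_pattern_mean[p])) {
      abort(paste0("si_pattern_mean is missing pattern '", p, "'."))
    }
  }
  stopifnot(si_pattern_sd >= 0, foot_length_mean > 0, foot_length_sd >= 0,
            length(foot_length_range) == 2, foot_length_range[1] > 0,
            foot_length_range[1] < foot_length_range[2], standard_length > 0)

  structure(
    list(
      n_subjects = as.integer(n_subjects),
      surfaces = surfaces,
      patterns = patterns,
      footfalls_per_condition = as.integer(footfalls_per_condition),
      slope_by_surface = slope_by_surface,
      intercept_by_surface = intercept_by_surface,
      noise_sd_by_surface = noise_sd_by_surface,
      si_pattern_mean = si_pattern_mean,
      si_pattern_sd = si_pattern_sd,
      exclusion_rate = exclusion_rate,
      foot_length_mean = foot_length_mean,
      foot_length_sd = foot_length_sd,
      foot_length_range = foot_length_range,
      standard_length = standard_length,
      seed = seed
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  n <- x$n_subjects * length(x$surfaces) * length(x$patterns) * x$footfalls_per_condition
  cat("<population_spec>\n")
  cat(sprintf("  %d subjects x %d surfaces x %d patterns x %d footfalls = %d records\n",
              x$n_subjects, length(x$surfaces), length(x$patterns),
              x$footfalls_per_condition, n))
  cat(sprintf("  split-belt exclusion rate %.4f; seed %s\n",
              x$exclusion_rate, if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

# inverse-CDF draw from a truncated normal (no rejection, fully vectorised)
rtruncated_normal <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Simulate a table of per-footfall analysis records
#'
#' Draws one row per footfall of the design in `spec`. Per subject, a foot
#' length is drawn once. Per footfall, a latent achieved strike-index target
#' is drawn around the instructed pattern's centre; the normalised OTD is the
#' point on the surface's agreement line at that target, the recorded strike
#' index adds measurement scatter about the line (clamped to \[0, 100\]), the
#' raw OTD inverts the foot-length normalisation, and a split-belt flag is
#' drawn Bernoulli(`exclusion_rate`).
#'
#' @param spec A [population_spec()].
#' @return A tibble with one row per footfall and columns `subject_id`,
#'   `surface`, `instructed_pattern`, `foot_length` (cm), `si` (percent),
#'   `otd_raw` (ms), `otd_norm` (ms), `split_belt` (logical).
#' @examples
#' ff <- simulate_footfalls(population_spec(n_subjects = 3, seed = 42))
#' dplyr::count(ff, surface, instructed_pattern)
#' @export
simulate_footfalls <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  subjects <- sprintf("S%03d", seq_len(spec$n_subjects))
  foot_len <- rtruncated_normal(spec$n_subjects, spec$foot_length_mean,
                                spec$foot_length_sd,
                                spec$foot_length_range[1], spec$foot_length_range[2])
  names(foot_len) <- subjects

  grid <- tidyr::expand_grid(
    subject_id = subjects,
    surface = spec$surfaces,
    instructed_pattern = spec$patterns,
    footfall = seq_len(spec$footfalls_per_condition)
  )
  n <- nrow(grid)

  slope <- unname(spec$slope_by_surface[grid$surface])
  intercept <- unname(spec$intercept_by_surface[grid$surface])
  noise_sd <- unname(spec$noise_sd_by_surface[grid$surface])
  mu <- unname(spec$si_pattern_mean[grid$instructed_pattern])

  # latent achieved target stays within the physical SI range
  si_target <- mu + rtruncated_normal_dev(n, spec$si_pattern_sd, mu)
  otd_norm <- (si_target - intercept) / slope
  si <- pmin(pmax(si_target + slope * rnorm(n, 0, noise_sd), 0), 100)
  fl <- unname(foot_len[grid$subject_id])
  otd_raw <- otd_norm * fl / spec$standard_length
  split_belt <- runif(n) < spec$exclusion_rate

  tibble::tibble(
    subject_id = grid$subject_id,
    surface = factor(grid$surface, levels = SURFACE_LEVELS),
    instructed_pattern = factor(grid$instructed_pattern, levels = PATTERN_LEVELS),
    foot_length = fl,
    si = si,
    otd_raw = otd_raw,
    otd_norm = otd_norm,
    split_belt = split_belt
  )
}

# per-record deviation of the latent SI target, truncated so target stays in [0,100]
rtruncated_normal_dev <- function(n, sd, mu) {
  if (sd == 0) return(numeric(n))
  p_lo <- pnorm(0, mu, sd)
  p_hi <- pnorm(100, mu, sd)
  qnorm(runif(n, p_lo, p_hi), mu, sd) - mu
}
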