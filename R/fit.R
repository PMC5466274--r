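#' Fit the strike-index-on-OTD agreement line
#'
#' Ordinary least squares of strike index (percent) on normalised
#' onset-time difference (ms), the univariate agreement model that lets a
#' two-sensor insole stand in for a force platform. Fits either the pooled
#' data (`scope = "all"`) or one surface inclination; split-belt-flagged and
#' missing-OTD footfalls are dropped first.
#'
#' Reported alongside the slope `B` and intercept: the slope's standard
#' error, t statistic (`B / se_B`), two-sided p value on `n - 2` degrees of
#' freedom, 95% confidence interval, the coefficient of determination, the
#' standardized slope `beta = B * sd(OTD) / sd(SI)` (in a univariate model
#' `beta^2 = R^2` identically), and the variance inflation factor, which is
#' exactly 1 with a single predictor.
#'
#' @param data Footfall records: a data frame with columns `si`,
#'   `otd_norm`, and optionally `surface` and `split_belt`.
#' @param scope `"all"` (default) or one of `"flat"`, `"inclined"`,
#'   `"declined"`; non-`"all"` scopes filter on the `surface` column.
#' @param exclude_split Drop rows with `split_belt == TRUE` (default `TRUE`;
#'   ignored if the column is absent).
#' @return An `"si_otd_fit"` object. Use [tidy()], [glance()], [autoplot()],
#'   [derive_cutoffs()] and [predict_si()] on it.
#' @examples
#' ff <- simulate_footfalls(population_spec(n_subjects = 20, seed = 3))
#' fit <- fit_si_on_otd(ff, scope = "flat")
#' glance(fit)
#' @export
fit_si_on_otd <- function(data, scope = c("all", "flat", "inclined", "declined"),
                          exclude_split = TRUE) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("si", "otd_norm"), names(data))
  if (length(missing_cols)) {
    abort(paste0("Records are missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- data
  if (scope != "all") {
    if (!"surface" %in% names(d)) {
      abort("A surface-specific scope needs a `surface` column.")
    }
    d <- dplyr::filter(d, as.character(.data$surface) == scope)
  }
  if (exclude_split && "split_belt" %in% names(d)) {
    d <- dplyr::filter(d, !.data$split_belt)
  }
  d <- dplyr::filter(d, !is.na(.data$si), !is.na(.data$otd_norm))
  n <- nrow(d)
  if (n < 3) {
    abort(sprintf("Need at least 3 usable footfalls in scope '%s'; have %d.",
                  scope, n))
  }
  if (var(d$otd_norm) == 0) {
    abort("OTD has zero variance in this scope; the agreement line is undefined.")
  }

  model <- lm(si ~ otd_norm, data = d)
  sm <- summary(model)
  B <- unname(coef(model)[2])
  se_B <- sm$coefficients["otd_norm", "Std. Error"]
  ci <- unname(confint(model, "otd_norm", level = 0.95))

  structure(
    list(
      scope = scope,
      B = B,
      intercept = unname(coef(model)[1]),
      se_B = se_B,
      t_stat = B / se_B,
      p_value = sm$coefficients["otd_norm", "Pr(>|t|)"],
      r_squared = sm$r.squared,
      beta = B * sd(d$otd_norm) / sd(d$si),
      vif = 1,
      ci95_B = c(lower = ci[1], upper = ci[2]),
      n = n,
      data = tibble::tibble(otd_norm = d$otd_norm, si = d$si)
    ),
    class = "si_otd_fit"
  )
}

#' Wrap published agreement-line coefficients
#'
#' Builds an `"si_otd_fit"`-compatible object from known coefficients —
#' e.g. the reference calibration in [reference_lines()] — so cutoff
#' windows can be derived and OTDs classified without refitting.
#'
#' @param B Slope, SI percent per ms (non-zero).
#' @param intercept SI percent at OTD = 0.
#' @param ci95_B Optional length-2 numeric, the 95% CI of `B`
#'   (lower, upper).
#' @param scope Label: `"all"` or a surface name.
#' @param r_squared,n Optional, carried through for reporting.
#' @return An object of class `c("si_otd_line", "si_otd_fit")`.
#' @examples
#' line <- si_otd_line(0.444, 45.84, ci95_B = c(0.441, 0.448))
#' derive_cutoffs(line)
#' @export
si_otd_line <- function(B, intercept, ci95_B = NULL, scope = "all",
                        r_squared = NA_real_, n = NA_integer_) {
  stopifnot(is.numeric(B), length(B) == 1, is.numeric(intercept),
            length(intercept) == 1)
  if (B == 0) abort("B must be non-zero.")
  if (!is.null(ci95_B)) {
    stopifnot(length(ci95_B) == 2, ci95_B[1] <= B, B <= ci95_B[2])
    ci95_B <- c(lower = unname(ci95_B[1]), upper = unname(ci95_B[2]))
  } else {
    ci95_B <- c(lower = NA_real_, upper = NA_real_)
  }
  structure(
    list(
      scope = scope, B = B, intercept = intercept,
      se_B = NA_real_, t_stat = NA_real_, p_value = NA_real_,
      r_squared = r_squared, beta = NA_real_, vif = 1,
      ci95_B = ci95_B, n = n, data = NULL
    ),
    class = c("si_otd_line", "si_otd_fit")
  )
}

#' Predict strike index from an OTD
#'
#' Evaluates a fitted (or published) agreement line at the given normalised
#' OTDs. Predictions are clamped to the physical strike-index range
#' \[0, 100\]; a logical attribute `"out_of_range"` marks which inputs fell
#' outside it before clamping.
#'
#' @param fit An `"si_otd_fit"` object.
#' @param otd Numeric vector of normalised OTDs (ms).
#' @return Numeric vector of predicted SI (percent), clamped to \[0, 100\].
#' @examples
#' predict_si(si_otd_line(0.444, 45.84), c(-28.92, 0, 45.41))
#' @export
predict_si <- function(fit, otd) {
  stopifnot(inherits(fit, "si_otd_fit"), is.numeric(otd))
  raw <- fit$B * otd + fit$intercept
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "out_of_range") <- raw < 0 | raw > 100
  out
}

format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}

#' @export
print.si_otd_fit <- function(x, ...) {
  cat(sprintf("<si_otd_fit> scope: %s\n", x$scope))
  cat(sprintf("  SI = %.3f * OTD + %.2f", x$B, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("   (R^2 = %.3f)", x$r_squared))
  cat("\n")
  if (!is.na(x$se_B)) {
    cat(sprintf("  B = %.3f (95%% CI %.3f-%.3f), t = %.2f, beta = %.3f, VIF = %g, p %s, n = %d\n",
                x$B, x$ci95_B["lower"], x$ci95_B["upper"], x$t_stat, x$beta,
                x$vif, format_p(x$p_value), x$n))
  }
  invisible(x)
}

#' @describeIn fit_si_on_otd Broom-style one-row-per-term coefficient table.
#' @param x An `"si_otd_fit"` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.si_otd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "otd_norm"),
    estimate = c(x$intercept, x$B),
    std.error = c(NA_real_, x$se_B),
    statistic = c(NA_real_, x$t_stat),
    p.value = c(NA_real_, x$p_value),
    conf.low = c(NA_real_, unname(x$ci95_B["lower"])),
    conf.high = c(NA_real_, unname(x$ci95_B["upper"]))
  )
}

#' @describeIn fit_si_on_otd Broom-style one-row model summary (scope, B,
#'   t, beta, VIF, p, CI of B, R^2, n).
#' @exportS3Method generics::glance
glance.si_otd_fit <- function(x, ...) {
  tibble::tibble(
    scope = x$scope,
    B = x$B,
    intercept = x$intercept,
    t = x$t_stat,
    beta = x$beta,
    vif = x$vif,
    p.value = x$p_value,
    ci_lower_B = unname(x$ci95_B["lower"]),
    ci_upper_B = unname(x$ci95_B["upper"]),
    r.squared = x$r_squared,
    n = x$n
  )
}

#' Fit the agreement line for every scope
#'
#' Fits the pooled model plus one model per surface present in the data and
#' returns the stacked [glance()] rows — the shape of the conventional
#' regression summary table (one row per scope with B, t, beta, VIF, p and
#' the 95% CI of B).
#'
#' @inheritParams fit_si_on_otd
#' @return A tibble with one row per scope. The fitted objects themselves
#'   are attached as the `"fits"` attribute (a named list).
#' @examples
#' ff <- simulate_footfalls(population_spec(n_subjects = 15, seed = 4))
#' fit_all_scopes(ff)
#' @export
fit_all_scopes <- function(data, exclude_split = TRUE) {
  scopes <- "all"
  if ("surface" %in% names(data)) {
    present <- intersect(SURFACE_LEVELS, unique(as.character(data$surface)))
    scopes <- c("all", present)
  }
  fits <- purrr::map(scopes, ~ fit_si_on_otd(data, scope = .x,
                                             exclude_split = exclude_split))
  names(fits) <- scopes
  out <- purrr::map_dfr(fits, glance)
  attr(out, "fits") <- fits
  out
}

#' Scatter and fitted line for an agreement fit
#'
#' @param object An `"si_otd_fit"` with retained data.
#' @param max_points At most this many footfalls are drawn (random thinning
#'   keeps plots light); the line uses the full fit. Default 5000.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.si_otd_fit <- function(object, max_points = 5000, ...) {
  if (is.null(object$data)) {
    abort("This fit carries no data to plot (published line?).")
  }
  d <- object$data
  if (nrow(d) > max_points) {
    d <- dplyr::slice_sample(d, n = max_points)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$otd_norm, y = .data$si)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_abline(slope = object$B, intercept = object$intercept,
                         colour = "#D55E00", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(33, 66), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "Normalised onset-time difference (ms)",
      y = "Strike index (%)",
      title = sprintf("SI = %.3f OTD + %.2f  (scope: %s, R² = %.3f)",
                      object$B, object$intercept, object$scope,
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
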