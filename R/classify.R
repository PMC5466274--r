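#' Classify footstrike pattern from the strike index
#'
#' Applies the conventional strike-index bands: rearfoot strike (RFS) for
#' SI in 0-33%, midfoot strike (MFS) for 34-66% and forefoot strike (FFS)
#' for 67-100%. For continuous SI the bands are realised as half-open
#' intervals with ties assigned downward: `si <= 33` is RFS,
#' `33 < si <= 66` is MFS, `si > 66` is FFS.
#'
#' @param si Numeric vector of strike indices (percent); must lie in
#'   \[0, 100\].
#' @param bands Two class boundaries in percent (default `c(33, 66)`).
#' @return A factor with levels `RFS`, `MFS`, `FFS`.
#' @examples
#' classify_si(c(20, 33, 33.01, 80))
#' @export
classify_si <- function(si, bands = c(33, 66)) {
  stopifnot(is.numeric(si), length(bands) == 2, bands[1] < bands[2])
  bad <- !is.na(si) & (si < 0 | si > 100)
  if (any(bad)) {
    abort(sprintf("%d strike index value(s) outside [0, 100].", sum(bad)))
  }
  cut(si, breaks = c(-Inf, bands, Inf), labels = PATTERN_LEVELS, right = TRUE)
}

#' Classify footstrike pattern from an onset-time difference
#'
#' Uses a classification time window — the OTD cutoffs at the 33% and 66%
#' strike-index boundaries from [derive_cutoffs()] — to assign a pattern to
#' each normalised OTD: RFS at or below the 33% cutoff, MFS up to the 66%
#' cutoff, FFS above it. Tie handling matches [classify_si()], so
#' classifying an OTD and classifying its predicted SI through the same
#' line can never disagree.
#'
#' @param otd_norm Numeric vector of normalised OTDs (ms).
#' @param window Either a `"cutoff_window"` tibble for one scope (two rows,
#'   boundaries 33 and 66) or a numeric length-2 vector
#'   `c(otd_at_33, otd_at_66)`.
#' @return A factor with levels `RFS`, `MFS`, `FFS`.
#' @examples
#' win <- derive_cutoffs(reference_line("all"))
#' classify_otd(c(-40, 0, 60), win)
#' @export
classify_otd <- function(otd_norm, window) {
  stopifnot(is.numeric(otd_norm))
  if (inherits(window, "data.frame")) {
    if (length(unique(window$scope)) != 1 || nrow(window) != 2) {
      abort("`window` must hold exactly the two cutoffs of one scope.")
    }
    window <- window$otd[order(window$si_target)]
  }
  stopifnot(is.numeric(window), length(window) == 2)
  if (window[1] >= window[2]) {
    abort("Inverted window: the 33% cutoff must fall below the 66% cutoff.")
  }
  cut(otd_norm, breaks = c(-Inf, window, Inf), labels = PATTERN_LEVELS,
      right = TRUE)
}

#' Agreement between strike-index and OTD classifications
#'
#' Cross-tabulates the laboratory classification (from the force-platform
#' strike index, taken as truth) against the insole classification (from
#' the OTD window) and summarises their agreement: a 3x3 confusion matrix
#' with truth in rows, overall percent agreement (trace over total) and
#' per-class recall (diagonal over row sums).
#'
#' @param labels_si Factor/character vector of truth labels (RFS/MFS/FFS).
#' @param labels_otd Factor/character vector of surrogate labels, same
#'   length.
#' @return An `"agreement_report"` list: `confusion` (matrix, rows = SI),
#'   `overall` (fraction in \[0, 1\]), `recall` (named numeric), `n`.
#' @examples
#' truth <- classify_si(c(10, 50, 90, 20))
#' pred <- classify_si(c(12, 40, 88, 70))
#' agreement_report(truth, pred)
#' @export
agreement_report <- function(labels_si, labels_otd) {
  if (length(labels_si) != length(labels_otd)) {
    abort("Label vectors must have equal length.")
  }
  truth <- factor(as.character(labels_si), levels = PATTERN_LEVELS)
  pred <- factor(as.character(labels_otd), levels = PATTERN_LEVELS)
  keep <- !is.na(truth) & !is.na(pred)
  confusion <- table(si = truth[keep], otd = pred[keep])
  confusion <- unclass(as.matrix(confusion))
  n <- sum(confusion)
  row_tot <- rowSums(confusion)
  structure(
    list(
      confusion = confusion,
      overall = if (n > 0) sum(diag(confusion)) / n else NA_real_,
      recall = ifelse(row_tot > 0, diag(confusion) / row_tot, NA_real_),
      n = n
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d, overall agreement = %.1f%%\n",
              x$n, 100 * x$overall))
  print(x$confusion)
  cat("per-class recall:",
      paste(sprintf("%s %.1f%%", names(x$recall), 100 * x$recall),
            collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn agreement_report Confusion matrix as a tidy tibble (one row
#'   per truth x surrogate cell).
#' @param x An `"agreement_report"`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$confusion,
                                        responseName = "count",
                                        stringsAsFactors = FALSE))
}

#' @describeIn agreement_report One-row summary: n, overall agreement and
#'   per-class recall.
#' @exportS3Method generics::glance
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    overall = x$overall,
    recall_RFS = unname(x$recall["RFS"]),
    recall_MFS = unname(x$recall["MFS"]),
    recall_FFS = unname(x$recall["FFS"])
  )
}
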