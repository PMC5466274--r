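#' Run the simulation stage and write its outputs
#'
#' Generates a footfall table (and optionally per-trial raw traces) under a
#' seeded population specification and writes it with a metadata sidecar
#' echoing the resolved configuration, so any run can be reproduced from
#' its own outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [population_spec()].
#' @param config A [run_config()].
#' @param write_trace_trials Number of subject x condition trials for which
#'   raw traces are also written (default 0; traces are bulky and only
#'   needed to exercise the processing chain).
#' @return Invisibly, a list with the records tibble and the paths written.
#' @export
run_simulate <- function(out_dir, spec = population_spec(),
                         config = run_config(), write_trace_trials = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- simulate_footfalls(spec)
  rec_path <- file.path(out_dir, "footfalls.csv")
  write_footfalls(records, rec_path)

  paths <- rec_path
  if (write_trace_trials > 0) {
    trials <- records |>
      dplyr::group_by(.data$subject_id, .data$surface, .data$instructed_pattern) |>
      dplyr::group_split()
    trials <- trials[seq_len(min(write_trace_trials, length(trials)))]
    for (i in seq_along(trials)) {
      tr <- simulate_trial(trials[[i]],
                           split_zone_halfwidth = config$split_zone_halfwidth,
                           contact_threshold = config$contact_threshold)
      prefix <- file.path(out_dir, sprintf("trial_%03d", i))
      write_traces(tr, prefix, metadata = list(config = unclass(config)))
      paths <- c(paths, prefix)
    }
  }
  meta <- list(
    stage = "simulate",
    n_records = nrow(records),
    n_split_flagged = sum(records$split_belt),
    spec = unclass(spec),
    config = unclass(config)
  )
  jsonlite::write_json(meta, file.path(out_dir, "simulate_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  inform(sprintf("simulate: %d footfalls generated, %d flagged at the belt split",
                 nrow(records), sum(records$split_belt)))
  invisible(list(records = records, paths = paths))
}

#' Run the processing stage over a directory of trace files
#'
#' Applies the full chain (filter, segment, last-N, strike index, onsets,
#' OTD, split flag) to every `*.csv`/`*.json` trace pair in a directory and
#' stacks the per-trial footfall rows. A malformed trace pair is reported
#' by name and skipped; the remaining trials are still processed.
#'
#' @param trace_dir Directory of trace pairs written by [write_traces()].
#' @param out_csv Path of the combined footfall CSV to write (optional).
#' @param config A [run_config()].
#' @return The combined footfall tibble (invisibly if `out_csv` given).
#' @export
run_process <- function(trace_dir, out_csv = NULL, config = run_config()) {
  prefixes <- sub("\\.csv$", "", list.files(trace_dir, pattern = "\\.csv$",
                                            full.names = TRUE))
  prefixes <- prefixes[file.exists(paste0(prefixes, ".json"))]
  if (!length(prefixes)) abort(sprintf("No trace pairs found in %s", trace_dir))
  rows <- purrr::map(prefixes, function(p) {
    tryCatch(
      process_traces(read_traces(p), config = config),
      error = function(e) {
        warn(sprintf("Skipping malformed trace '%s': %s", p, conditionMessage(e)))
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  inform(sprintf("process: %d trials -> %d footfalls (%d split-belt flagged)",
                 length(prefixes), nrow(out), sum(out$split_belt)))
  if (!is.null(out_csv)) {
    write_footfalls(out, out_csv)
    return(invisible(out))
  }
  out
}

#' Run the analysis stage: agreement tables, windows, classification
#'
#' From a footfall record table, fits the agreement line for the pooled
#' scope and every surface present, derives the classification windows at
#' the strike-index boundaries, classifies every analysed footfall by both
#' routes (strike index vs surface-matched OTD window), and writes the
#' regression summary table, the cutoff table, the agreement report and a
#' metadata echo of the resolved configuration.
#'
#' @param records A footfall tibble or a CSV path.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param config A [run_config()].
#' @return A list: `fits` (regression summary tibble), `cutoffs`
#'   (`"cutoff_window"` tibble), `agreement` (`"agreement_report"`),
#'   `n_collected`, `n_excluded`, `n_analyzed`.
#' @export
run_analyze <- function(records, out_dir = NULL, config = run_config()) {
  if (is.character(records)) records <- read_footfalls(records)
  required <- c("si", "otd_norm")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort(paste0("Records are missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n_collected <- nrow(records)
  analyzed <- records
  if ("split_belt" %in% names(analyzed)) {
    analyzed <- dplyr::filter(analyzed, !.data$split_belt)
  }
  analyzed <- dplyr::filter(analyzed, !is.na(.data$otd_norm), !is.na(.data$si))
  n_analyzed <- nrow(analyzed)
  inform(sprintf("analyze: %d footfalls collected, %d excluded, %d analyzed",
                 n_collected, n_collected - n_analyzed, n_analyzed))

  fits <- fit_all_scopes(records)
  cutoffs <- derive_all_cutoffs(fits, si_targets = config$si_bands)

  truth <- classify_si(analyzed$si, bands = config$si_bands)
  if ("surface" %in% names(analyzed)) {
    pred <- factor(rep(NA_character_, nrow(analyzed)), levels = PATTERN_LEVELS)
    for (s in intersect(SURFACE_LEVELS, unique(as.character(analyzed$surface)))) {
      idx <- as.character(analyzed$surface) == s
      win <- dplyr::filter(cutoffs, .data$scope == s)
      pred[idx] <- classify_otd(analyzed$otd_norm[idx], win)
    }
  } else {
    pred <- classify_otd(analyzed$otd_norm,
                         dplyr::filter(cutoffs, .data$scope == "all"))
  }
  agreement <- agreement_report(truth, pred)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(fits, file.path(out_dir, "agreement_models.csv"))
    readr::write_csv(tibble::as_tibble(cutoffs), file.path(out_dir, "cutoff_windows.csv"))
    jsonlite::write_json(
      list(
        stage = "analyze",
        n_collected = n_collected,
        n_excluded = n_collected - n_analyzed,
        n_analyzed = n_analyzed,
        overall_agreement = agreement$overall,
        recall = as.list(agreement$recall),
        confusion = as.data.frame.table(agreement$confusion,
                                        responseName = "count"),
        config = unclass(config)
      ),
      file.path(out_dir, "analyze_meta.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  list(
    fits = fits, cutoffs = cutoffs, agreement = agreement,
    n_collected = n_collected,
    n_excluded = n_collected - n_analyzed,
    n_analyzed = n_analyzed
  )
}

#' Classify a table of OTDs with a stored window
#'
#' @param records A footfall tibble or CSV path with an `otd_norm` column
#'   (and optionally `surface`).
#' @param window A `"cutoff_window"` tibble, a JSON path written by
#'   [write_window()], or `NULL` to use the reference calibration.
#' @param out_csv Optional path for the labelled CSV.
#' @return The records with a `pattern_otd` factor column appended.
#' @export
run_classify <- function(records, window = NULL, out_csv = NULL) {
  if (is.character(records)) records <- read_footfalls(records)
  if (is.character(window)) window <- read_window(window)
  if (is.null(window)) {
    window <- derive_all_cutoffs(
      purrr::map(setNames(SCOPE_LEVELS, SCOPE_LEVELS), reference_line))
  }
  if (!"otd_norm" %in% names(records)) {
    abort("Records are missing required column(s): otd_norm")
  }
  scopes <- unique(window$scope)
  if ("surface" %in% names(records) && all(SURFACE_LEVELS %in% scopes)) {
    pattern <- factor(rep(NA_character_, nrow(records)), levels = PATTERN_LEVELS)
    for (s in intersect(SURFACE_LEVELS, unique(as.character(records$surface)))) {
      idx <- !is.na(records$surface) & as.character(records$surface) == s
      pattern[idx] <- classify_otd(records$otd_norm[idx],
                                   dplyr::filter(window, .data$scope == s))
    }
  } else {
    one <- if ("all" %in% scopes) "all" else scopes[1]
    pattern <- classify_otd(records$otd_norm,
                            dplyr::filter(window, .data$scope == one))
  }
  out <- dplyr::mutate(records, pattern_otd = pattern)
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  out
}
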