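#' Read and write footfall record tables
#'
#' Footfall records travel as plain CSV with a fixed column order:
#' `subject_id, surface, instructed_pattern, foot_length, si, otd_raw,
#' otd_norm, split_belt`. Extra columns are preserved after the fixed ones.
#'
#' @param records A footfall tibble ([simulate_footfalls()] or
#'   [process_traces()] output).
#' @param path File path.
#' @return `write_footfalls()` returns `path` invisibly; `read_footfalls()`
#'   returns a tibble with `surface`/`instructed_pattern` as factors.
#' @export
write_footfalls <- function(records, path) {
  stopifnot(is.data.frame(records))
  fixed <- c("subject_id", "surface", "instructed_pattern", "foot_length",
             "si", "otd_raw", "otd_norm", "split_belt")
  ordered <- c(intersect(fixed, names(records)),
               setdiff(names(records), fixed))
  readr::write_csv(records[ordered], path)
  invisible(path)
}

#' @rdname write_footfalls
#' @export
read_footfalls <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("surface" %in% names(out)) {
    out$surface <- factor(out$surface, levels = SURFACE_LEVELS)
  }
  if ("instructed_pattern" %in% names(out)) {
    out$instructed_pattern <- factor(out$instructed_pattern,
                                     levels = PATTERN_LEVELS)
  }
  out
}

#' Read and write sensor trace sets
#'
#' A trace set is stored as a samples CSV (one column per channel, one row
#' per sample) plus a JSON sidecar `<prefix>.json` holding the sampling
#' rate, foot length, ground-truth stance table and any configuration
#' echoed by the writer.
#'
#' @param traces A `"sensor_traces"` object.
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @param metadata Optional named list merged into the sidecar (e.g. a
#'   resolved configuration).
#' @return `write_traces()` returns `prefix` invisibly; `read_traces()`
#'   returns the reconstructed `"sensor_traces"` object.
#' @export
write_traces <- function(traces, prefix, metadata = list()) {
  stopifnot(inherits(traces, "sensor_traces"))
  readr::write_csv(tibble::as_tibble(traces), paste0(prefix, ".csv"))
  sidecar <- c(
    list(
      sampling_rate = attr(traces, "sampling_rate"),
      foot_length = attr(traces, "foot_length"),
      truth = attr(traces, "truth")
    ),
    metadata
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(prefix)
}

#' @rdname write_traces
#' @export
read_traces <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  side <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(side)) {
    abort(sprintf("Trace pair '%s.{csv,json}' not found.", prefix))
  }
  data <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new_sensor_traces(
    data,
    sampling_rate = meta$sampling_rate,
    foot_length = meta$foot_length,
    truth = tibble::as_tibble(meta$truth)
  )
}

#' Write / read a classification window as JSON
#'
#' @param window A `"cutoff_window"` tibble ([derive_cutoffs()] or
#'   [derive_all_cutoffs()]).
#' @param path JSON file path.
#' @return `write_window()` returns `path` invisibly; `read_window()`
#'   returns the `"cutoff_window"` tibble.
#' @export
write_window <- function(window, path) {
  stopifnot(inherits(window, "cutoff_window"))
  jsonlite::write_json(tibble::as_tibble(window), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_window
#' @export
read_window <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("cutoff_window", class(out))
  out
}

#' Read a supplementary-style per-footfall (surface, SI, OTD) table
#'
#' Loads an analysis-ready per-footfall table with one row per footfall and
#' columns naming the surface, the strike index (percent) and the OTD (ms,
#' treated as already foot-length-normalised), as shipped with published
#' calibrations. Column matching is case-insensitive on the prefixes
#' `surface`, `si`/`strike`, `otd`.
#'
#' @param path CSV file path.
#' @return A footfall tibble with columns `surface`, `si`, `otd_norm`,
#'   directly usable by [fit_si_on_otd()].
#' @export
read_si_otd_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nms <- tolower(names(raw))
  pick <- function(prefixes) {
    hit <- which(Reduce(`|`, lapply(prefixes, function(p) startsWith(nms, p))))
    if (!length(hit)) {
      abort(paste0("No column matching ", paste(prefixes, collapse = "/"),
                   " in ", path))
    }
    hit[1]
  }
  surface <- as.character(raw[[pick("surface")]])
  known <- tolower(surface) %in% SURFACE_LEVELS
  if (!all(known)) {
    # accept common synonyms for the level surface
    surface[tolower(surface) %in% c("level", "0", "flat")] <- "flat"
  }
  tibble::tibble(
    surface = factor(tolower(surface), levels = SURFACE_LEVELS),
    si = as.numeric(raw[[pick(c("si", "strike"))]]),
    otd_norm = as.numeric(raw[[pick("otd")]])
  )
}
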