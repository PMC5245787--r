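#' Read and write miniature-event tables
#'
#' Event tables are plain CSV with the header
#' `cell_id,group,drug,phase,amplitude_pA`.  Ground-truth annotations of a
#' synthetic population (the per-cell `amplified` flags and generator
#' parameters) travel in a JSON sidecar next to the CSV.
#'
#' @param events Event tibble (missing `drug`/`phase` columns are filled
#'   with `"none"`/`"pre"`).
#' @param path CSV path.
#' @param truth Optional list written as `<path>.truth.json`.
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` a tibble (with the sidecar, when present,
#'   attached as attribute `"truth"`).
#' @export
write_events_csv <- function(events, path, truth = NULL) {
  df <- as_tibble(events)
  if (!"drug" %in% names(df)) df$drug <- "none"
  if (!"phase" %in% names(df)) df$phase <- "pre"
  if (!"group" %in% names(df)) df$group <- "unknown"
  df <- df[c("cell_id", "group", "drug", "phase", "amplitude_pA")]
  utils::write.csv(df, path, row.names = FALSE)
  cells <- attr(events, "cells")
  if (is.null(truth) && !is.null(cells)) truth <- list(cells = cells)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    attr(df, "truth") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  df
}

#' Read and write waveform ensembles
#'
#' Waveform CSVs have the time axis (ms) in the first column and one
#' column of current samples (pA) per event.
#'
#' @param wf An [synth_nsfa_waveforms()]-style object (`time`, `current`).
#' @param path CSV path.
#' @return `write_waveforms_csv()` returns `path` invisibly;
#'   `read_waveforms_csv()` a list with `time`, `current` and `dt` usable
#'   by [preprocess_events()].
#' @export
write_waveforms_csv <- function(wf, path) {
  df <- data.frame(time_ms = wf$time, wf$current)
  names(df) <- c("time_ms", sprintf("event_%03d", seq_len(ncol(wf$current))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms_csv
#' @export
read_waveforms_csv <- function(path) {
  df <- utils::read.csv(path)
  time <- df[[1]]
  list(time = time, current = as.matrix(df[-1]),
       dt = stats::median(diff(time)))
}
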