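# Plain-text exchange formats: waveform CSV with a JSON sidecar carrying
# the sampling rate and units, and beat annotations as JSON.

#' Write and read waveform CSV files with JSON sidecars
#'
#' Waveforms travel as CSV with a `t` column (seconds) plus one column per
#' channel, and a `<path>.json` sidecar holding `fs`, `units`, and any
#' ground-truth metadata.
#'
#' @param data Data frame with a `t` column and channel columns.
#' @param path Output CSV path.
#' @param fs Sampling rate in Hz.
#' @param units Channel units string.
#' @param ground_truth Optional list serialized into the sidecar.
#' @return `write_waveform_csv()` returns `path` invisibly;
#'   `read_waveform_csv()` returns a tibble with attributes `fs`, `units`
#'   and `ground_truth`.
#' @export
write_waveform_csv <- function(data, path, fs, units = "mV",
                               ground_truth = NULL) {
  stopifnot(is.data.frame(data), "t" %in% names(data), fs > 0)
  utils::write.csv(data, path, row.names = FALSE)
  sidecar <- list(fs = fs, units = units)
  if (!is.null(ground_truth)) sidecar$ground_truth <- ground_truth
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    attr(out, "fs") <- sc$fs
    attr(out, "units") <- sc$units
    attr(out, "ground_truth") <- sc$ground_truth
  }
  out
}

#' Write and read beat annotations as JSON
#'
#' @param annotations Tibble of per-beat fiducial indices (as produced by
#'   [synth_ecg()] or [delineate()]).
#' @param path JSON path.
#' @return `write_annotations_json()` returns `path` invisibly;
#'   `read_annotations_json()` a tibble.
#' @export
write_annotations_json <- function(annotations, path) {
  stopifnot(is.data.frame(annotations))
  jsonlite::write_json(annotations, path, dataframe = "rows", na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_annotations_json
#' @export
read_annotations_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
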