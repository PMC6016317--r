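#' Write a signal as single-column CSV with a JSON sidecar
#'
#' The CSV has a header row (`amplitude_uv`) and one sample per line; the
#' sidecar `<path>.json` records `sample_rate`, `start_time` and `label`.
#'
#' @param record An `eeg_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  utils::write.csv(data.frame(amplitude_uv = record$samples), path,
                   row.names = FALSE)
  jsonlite::write_json(
    list(sample_rate = record$sampling_rate, start_time = record$start_time,
         label = record$label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a signal written by [write_signal_csv()]
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return An `eeg_record`.
#' @export
read_signal_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  x <- utils::read.csv(path)[[1]]
  eeg_record(x, meta$sample_rate, start_time = meta$start_time %||% 0,
             label = meta$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write event annotations as TSV
#' @param annotations Data frame (columns `animal_id`, `group`, `day`,
#'   `onset_s`, `duration_s`, `racine_stage`, `phase`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read event annotations from TSV
#' @param path TSV path.
#' @return Data frame of annotations.
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Dump a study configuration as YAML
#' @param config A study config list (see [study_config()]).
#' @param path Optional output path; when NULL the YAML text is returned.
#' @return YAML text (invisibly when written to `path`).
#' @export
dump_config_yaml <- function(config, path = NULL) {
  txt <- yaml::as.yaml(config)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
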