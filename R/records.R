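#' EEG record container
#'
#' A uniformly sampled single-channel voltage trace. Samples are in microvolts
#' (uV), time is in seconds. This is the unit of exchange between the
#' generator, the afterdischarge detector and the spectral module.
#'
#' @param samples Numeric vector of voltages (uV). Must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param label Optional text label.
#' @return An object of class `eeg_record` with fields `samples`,
#'   `sampling_rate`, `start_time`, `label`.
#' @examples
#' r <- eeg_record(sin(2 * pi * 6 * seq(0, 2, by = 1e-3)), 1000)
#' duration(r)
#' @export
eeg_record <- function(samples, sampling_rate, start_time = 0, label = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         start_time = start_time, label = label),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d samples @ %g Hz (%.3f s), start %.3f s\n",
              if (nzchar(x$label)) x$label else "unlabeled",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$start_time))
  invisible(x)
}

#' Duration of an EEG record in seconds
#' @param record An `eeg_record`.
#' @return Duration in seconds.
#' @export
duration <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  length(record$samples) / record$sampling_rate
}

#' Extract a time slice of a record
#'
#' Half-open interval `[from, to)` in seconds relative to `start_time`.
#'
#' @param record An `eeg_record`.
#' @param from,to Slice boundaries in seconds.
#' @return An `eeg_record` covering the requested interval.
#' @export
slice_record <- function(record, from, to) {
  stopifnot(inherits(record, "eeg_record"), to > from)
  fs <- record$sampling_rate
  i0 <- floor((from - record$start_time) * fs) + 1L
  i1 <- ceiling((to - record$start_time) * fs)
  i0 <- max(i0, 1L)
  i1 <- min(i1, length(record$samples))
  if (i1 < i0) stop("slice outside record", call. = FALSE)
  eeg_record(record$samples[i0:i1], fs,
             start_time = record$start_time + (i0 - 1L) / fs,
             label = record$label)
}

rms <- function(x) sqrt(mean(x^2))

#' Map a Racine stage to its seizure phase
#'
#' Stages 1 and 2 are initial seizure stages (ISS), stage 3 is the localized
#' seizure stage (LSS), stages 4 and 5 are generalized seizure stages (GSS).
#'
#' @param stage Integer vector of Racine stages (1--5).
#' @return Character vector in `c("ISS", "LSS", "GSS")`.
#' @export
stage_to_phase <- function(stage) {
  if (any(!stage %in% 1:5)) stop("Racine stages must be in 1..5", call. = FALSE)
  c("ISS", "ISS", "LSS", "GSS", "GSS")[stage]
}
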