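#' Sliding RMS envelope of a signal
#'
#' RMS in windows of `window` seconds advanced by `hop` seconds (50% overlap
#' at the defaults). Computed with cumulative sums, so cost is linear in the
#' record length.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param window Window length in seconds (default 0.5).
#' @param hop Hop between window starts in seconds (default `window / 2`).
#' @return Data frame with columns `t` (window start time, s) and `rms` (uV).
#' @keywords internal
sliding_rms <- function(x, fs, window = 0.5, hop = window / 2) {
  wlen <- max(2L, round(window * fs))
  hlen <- max(1L, round(hop * fs))
  n <- length(x)
  if (n < wlen) stop("record shorter than one envelope window", call. = FALSE)
  cs <- c(0, cumsum(x^2))
  starts <- seq(1L, n - wlen + 1L, by = hlen)
  data.frame(
    t = (starts - 1L) / fs,
    rms = sqrt((cs[starts + wlen] - cs[starts]) / wlen)
  )
}

#' Baseline amplitude statistics
#'
#' RMS amplitude of a baseline EEG window plus its sliding-RMS envelope.
#' Used as the reference against which afterdischarge amplitude is judged
#' (AD amplitude must reach `ratio` times this RMS).
#'
#' @param record An `eeg_record` containing (at least) the baseline.
#' @param window Length of the baseline window in seconds, taken from the
#'   start of the record (default 7).
#' @param envelope_window Sub-window for the envelope series (s, default 0.5).
#' @return A `baseline_stats` object: `rms` (uV), `envelope` (data frame
#'   t/rms), `window` (s).
#' @examples
#' r <- eeg_record(rnorm(7000), 1000)
#' baseline_stats(r)$rms
#' @export
baseline_stats <- function(record, window = 7, envelope_window = 0.5) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate
  nwin <- round(window * fs)
  if (length(record$samples) < nwin) {
    stop(sprintf("record (%.2f s) shorter than the baseline window (%g s)",
                 duration(record), window), call. = FALSE)
  }
  x <- record$samples[seq_len(nwin)]
  structure(
    list(rms = rms(x),
         envelope = sliding_rms(x, fs, window = envelope_window),
         window = window),
    class = "baseline_stats"
  )
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> rms = %.3f uV over %g s (envelope: %d windows)\n",
              x$rms, x$window, nrow(x$envelope)))
  invisible(x)
}

# Change-point edge localization. The instantaneous power steps from the
# baseline level b^2 to at least the detection-threshold level thr^2 at the
# boundary; the maximum-likelihood location of a step between two known
# power levels is the extremum of the CUSUM statistic
# D(t) = sum_{s<=t} (x_s^2 - lambda), with the reference level lambda midway
# between the two: the drift is negative before an onset and positive after
# it, so the onset is the argmin of D within the search window (argmax for
# an offset). lambda is centred on the threshold rather than on the event's
# interior power so that quiet between-spike stretches inside the event
# still drift upward and cannot capture the extremum. This locates edges at
# sample resolution and avoids fine-scale RMS, which is unstable at
# sub-cycle scales for delta-dominated activity.
locate_edge <- function(x, fs, t_coarse, b2, thr2, side, search = 0.75,
                        smooth = 0.025) {
  n <- length(x)
  i0 <- max(1L, floor((t_coarse - search) * fs) + 1L)
  i1 <- min(n, ceiling((t_coarse + search) * fs))
  if (i1 <= i0) return(t_coarse)
  p <- x[i0:i1]^2
  # light boxcar smoothing of the instantaneous power stabilizes the CUSUM
  # extremum against single-sample fluctuations at the boundary
  w <- max(1L, round(smooth * fs))
  if (w > 1L && length(p) > 2L * w) {
    cp <- c(0, cumsum(p))
    idx <- seq_len(length(p) - w + 1L)
    p <- (cp[idx + w] - cp[idx]) / w
  }
  d <- cumsum(p - (b2 + thr2) / 2)
  k <- if (side == "onset") which.min(d) else which.max(d)
  k <- k + if (w > 1L) w / 2 else 0      # centre of the smoothing window
  (i0 + k - 1L) / fs
}

#' Detect afterdischarge events
#'
#' Applies the amplitude/duration rule: maximal intervals where the
#' sliding-RMS envelope is at least `ratio` times the baseline RMS, kept only
#' if they last at least `min_duration` seconds. Sub-threshold dips of at
#' most `max_gap` seconds inside an event are bridged before the duration
#' rule is applied (spike-train ADs dip between spikes). Event existence is
#' decided on 0.5 s half-overlapping envelope windows; onset and offset are
#' then refined within the boundary windows by a 0.1 s RMS scan, and
#' reported as half-open intervals `[onset, onset + duration)` in seconds.
#'
#' @param record An `eeg_record`.
#' @param baseline A `baseline_stats` from the same recording context.
#' @param ratio Amplitude threshold as a multiple of baseline RMS
#'   (default 2.5).
#' @param min_duration Minimum event duration in seconds (default 6).
#' @param max_gap Longest sub-threshold gap (s) bridged inside an event
#'   (default 0.5).
#' @param window Envelope window length in seconds (default 0.5, 50% overlap).
#' @return Data frame with columns `onset` and `duration` (seconds),
#'   non-overlapping and sorted by onset; zero rows when nothing qualifies.
#' @export
detect_ad_events <- function(record, baseline, ratio = 2.5, min_duration = 6,
                             max_gap = 0.5, window = 0.5) {
  stopifnot(inherits(record, "eeg_record"), inherits(baseline, "baseline_stats"))
  if (ratio <= 0) stop("`ratio` must be positive", call. = FALSE)
  if (min_duration <= 0) stop("`min_duration` must be positive", call. = FALSE)
  fs <- record$sampling_rate
  threshold <- ratio * baseline$rms
  env <- sliding_rms(record$samples, fs, window = window)
  hop <- if (nrow(env) > 1L) env$t[2L] - env$t[1L] else window / 2
  above <- env$rms >= threshold
  if (!any(above)) {
    return(data.frame(onset = numeric(0), duration = numeric(0)))
  }
  # runs of super-threshold windows
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # bridge gaps <= max_gap between consecutive runs
  if (nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap_s <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * hop
      if (gap_s <= max_gap + 1e-9) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  onset <- numeric(0); dur <- numeric(0)
  b2 <- baseline$rms^2
  # the >= rule is enforced at envelope-grid resolution: the estimated
  # extent carries quantization error up to half a window, so a matching
  # allowance keeps boundary-duration events from flickering in and out
  dur_tol <- window / 2
  for (i in seq_len(nrow(runs))) {
    t_on <- locate_edge(record$samples, fs, env$t[runs$start[i]] + window / 2,
                        b2, threshold^2, "onset")
    t_off <- locate_edge(record$samples, fs, env$t[runs$end[i]] + window / 2,
                         b2, threshold^2, "offset")
    if (t_off - t_on >= min_duration - dur_tol) {
      onset <- c(onset, t_on)
      dur <- c(dur, t_off - t_on)
    }
  }
  data.frame(onset = onset + record$start_time, duration = dur)
}

#' Match detected events to stage annotations
#'
#' Each detected event is assigned the annotation with which it shares the
#' largest temporal overlap; events overlapping no annotation are flagged
#' unmatched (and should be excluded downstream). The AD duration (ADD) is
#' taken from the detected extent; stage, phase, animal and group come from
#' the annotation. Only the AD part of the signal is retained for spectral
#' analysis.
#'
#' @param events Data frame from [detect_ad_events()] (`onset`, `duration`).
#' @param annotations Data frame with columns `onset_s`, `duration_s`,
#'   `racine_stage`, and optionally `animal_id`, `group`, `day`. Must be
#'   sorted and non-overlapping.
#' @param tolerance Minimum overlap in seconds to accept a match (default 0:
#'   any positive overlap).
#' @return Data frame of AD segments: `onset`, `add` (detected duration, s),
#'   `racine_stage`, `phase`, `animal_id`, `group`, `matched` (logical).
#' @export
label_segments <- function(events, annotations, tolerance = 0) {
  ann <- annotations[order(annotations$onset_s), , drop = FALSE]
  if (nrow(ann) > 1L) {
    ends <- ann$onset_s + ann$duration_s
    if (any(ann$onset_s[-1L] < ends[-nrow(ann)] - 1e-9)) {
      stop("annotations overlap: invalid event file", call. = FALSE)
    }
  }
  out <- data.frame(
    onset = events$onset, add = events$duration,
    racine_stage = NA_integer_, phase = NA_character_,
    animal_id = NA_character_, group = NA_character_,
    matched = FALSE, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(events))) {
    e0 <- events$onset[i]; e1 <- e0 + events$duration[i]
    ov <- pmin(e1, ann$onset_s + ann$duration_s) - pmax(e0, ann$onset_s)
    if (nrow(ann) && max(ov) > tolerance) {
      j <- which.max(ov)
      out$racine_stage[i] <- as.integer(ann$racine_stage[j])
      out$phase[i] <- stage_to_phase(as.integer(ann$racine_stage[j]))
      out$animal_id[i] <- if ("animal_id" %in% names(ann)) as.character(ann$animal_id[j]) else NA_character_
      out$group[i] <- if ("group" %in% names(ann)) as.character(ann$group[j]) else NA_character_
      out$matched[i] <- TRUE
    }
  }
  out
}
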