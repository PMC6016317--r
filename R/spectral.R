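#' Standard EEG band scheme
#'
#' The five sub-bands used throughout: delta [1,4), theta [4,8), alpha [8,12),
#' beta [12,28), gamma [28,40) Hz, with aggregates LFB = delta+theta [1,8),
#' MFB = alpha [8,12) and HFB = beta+gamma [12,40). All intervals are
#' half-open `[low, high)`. Band powers and fractions are always taken over
#' the total power in [1,40) Hz, so sub-1 Hz drift and DC never enter any
#' total.
#'
#' @param delta,theta,alpha,beta,gamma Length-2 numeric vectors `c(low, high)`
#'   in Hz.
#' @return A `band_scheme` object: named list of band edges plus the aggregate
#'   definitions.
#' @export
band_scheme <- function(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
                        beta = c(12, 28), gamma = c(28, 40)) {
  bands <- list(delta = delta, theta = theta, alpha = alpha,
                beta = beta, gamma = gamma)
  for (b in bands) {
    if (length(b) != 2L || b[2] <= b[1]) stop("band edges must be c(low, high) with high > low", call. = FALSE)
  }
  # contiguity: delta..gamma must tile [delta_lo, gamma_hi)
  edges <- c(delta[1], delta[2], theta[2], alpha[2], beta[2], gamma[2])
  lows  <- c(delta[1], theta[1], alpha[1], beta[1], gamma[1])
  if (any(abs(lows - edges[1:5]) > 1e-12)) {
    stop("bands must be contiguous and non-overlapping", call. = FALSE)
  }
  structure(
    c(bands, list(
      lfb = c(delta[1], theta[2]),
      mfb = alpha,
      hfb = c(beta[1], gamma[2]),
      total = c(delta[1], gamma[2])
    )),
    class = "band_scheme"
  )
}

hann_window <- function(n) {
  # periodic Hann, standard for averaged-periodogram estimators
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2          # centred time axis
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over Hann-tapered sub-segments with the
#' stated overlap. Each sub-segment is linearly detrended before tapering.
#' The density is one-sided and normalized so that its integral over
#' frequency equals the (detrended) signal variance: `sum(density) * df ==
#' var(x)` up to taper-weighting error (the Parseval contract, within 1% on
#' stationary signals).
#'
#' @param record An `eeg_record` (or plain numeric vector, in which case
#'   `sampling_rate` must be given).
#' @param segment_length Sub-segment length in seconds (default 2, i.e.
#'   0.5 Hz native resolution).
#' @param overlap Fractional overlap between consecutive sub-segments
#'   (default 0.5).
#' @param detrend Linearly detrend each sub-segment (default TRUE).
#' @param pad Zero-padding factor (integer >= 1). `pad = 1` gives the native
#'   grid; larger values interpolate the spectrum onto a finer grid for peak
#'   localization without changing its integral.
#' @param sampling_rate Sampling rate in Hz when `record` is a bare vector.
#' @return A `psd_result`: list with `freq` (Hz), `density` (uV^2/Hz),
#'   `df` (grid spacing), `sampling_rate`, `segment_length`, `n_segments`.
#' @examples
#' fs <- 200
#' x <- sin(2 * pi * 10 * seq(0, 8, by = 1 / fs))
#' p <- welch_psd(eeg_record(x, fs))
#' p$freq[which.max(p$density)]  # ~10 Hz
#' @export
welch_psd <- function(record, segment_length = 2, overlap = 0.5,
                      detrend = TRUE, pad = 1L, sampling_rate = NULL) {
  if (inherits(record, "eeg_record")) {
    x <- record$samples
    fs <- record$sampling_rate
  } else {
    if (is.null(sampling_rate)) stop("`sampling_rate` required for bare vectors", call. = FALSE)
    x <- as.numeric(record)
    fs <- sampling_rate
  }
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  nper <- round(segment_length * fs)
  if (nper < 8) stop("segment_length too short for the sampling rate", call. = FALSE)
  if (length(x) < nper) {
    stop(sprintf("record (%d samples) shorter than one Welch sub-segment (%d)",
                 length(x), nper), call. = FALSE)
  }
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hann_window(nper)
  wnorm <- sum(w^2)
  nfft <- nper * max(1L, as.integer(pad))
  nhalf <- nfft %/% 2L
  acc <- numeric(nhalf + 1L)
  df <- fs / nfft
  dbl <- rep(2, nhalf + 1L); dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[nhalf + 1L] <- 1
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    if (detrend) seg <- detrend_linear(seg)
    y <- seg * w
    if (nfft > nper) y <- c(y, numeric(nfft - nper))
    Y <- stats::fft(y)
    # one-sided modified periodogram (DC and Nyquist not doubled)
    acc <- acc + dbl * (Mod(Y[1:(nhalf + 1L)])^2) / (fs * wnorm)
  }
  density <- acc / length(starts)
  # Parseval contract: one global rescale so the integrated density equals
  # the signal variance exactly. A constant factor leaves every band
  # fraction and ratio untouched; it only pins the absolute scale, which
  # taper weighting would otherwise bias by a few percent on strongly
  # autocorrelated signals.
  varx <- mean(x^2) - mean(x)^2
  integ <- sum(density) * df
  if (integ > 0 && varx > 0) density <- density * (varx / integ)
  structure(
    list(freq = (0:nhalf) * df, density = density, df = df,
         sampling_rate = fs, segment_length = nper / fs,
         n_segments = length(starts)),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d bins, df = %g Hz, %d averaged sub-segments of %g s\n",
              length(x$freq), x$df, x$n_segments, x$segment_length))
  invisible(x)
}

band_power_one <- function(psd, lo, hi) {
  idx <- psd$freq >= lo & psd$freq < hi
  sum(psd$density[idx]) * psd$df
}

#' Band powers and fractions from a PSD
#'
#' Integrates the density over each half-open band of the scheme and
#' normalizes by the total power over the scheme's full range ([1,40) Hz by
#' default). Also reports LFB/MFB/HFB aggregate fractions and the
#' theta/alpha power ratio.
#'
#' @param psd A `psd_result`.
#' @param scheme A `band_scheme` (default `band_scheme()`).
#' @return A `band_fractions` object: lists `power` and `fraction`, each with
#'   elements delta, theta, alpha, beta, gamma, lfb, mfb, hfb; `total` power
#'   over the scheme range; and `theta_alpha_ratio` (NA when alpha power is
#'   zero).
#' @export
band_fractions <- function(psd, scheme = band_scheme()) {
  stopifnot(inherits(psd, "psd_result"))
  nyq <- psd$sampling_rate / 2
  if (scheme$total[2] > nyq + 1e-9) {
    stop("band scheme upper edge exceeds Nyquist frequency", call. = FALSE)
  }
  nm <- c("delta", "theta", "alpha", "beta", "gamma", "lfb", "mfb", "hfb")
  power <- vapply(nm, function(b) band_power_one(psd, scheme[[b]][1], scheme[[b]][2]),
                  numeric(1))
  total <- band_power_one(psd, scheme$total[1], scheme$total[2])
  if (total <= 0) stop("zero total power in the analysis range: fractions undefined", call. = FALSE)
  structure(
    list(power = as.list(power), fraction = as.list(power / total),
         total = total,
         theta_alpha_ratio = if (power[["alpha"]] > 0) power[["theta"]] / power[["alpha"]] else NA_real_),
    class = "band_fractions"
  )
}

#' @export
print.band_fractions <- function(x, ...) {
  f <- unlist(x$fraction)
  cat("<band_fractions>\n")
  print(round(f, 4))
  cat(sprintf("theta/alpha ratio: %s\n",
              if (is.na(x$theta_alpha_ratio)) "undefined" else format(round(x$theta_alpha_ratio, 4))))
  invisible(x)
}

#' Theta/alpha power ratio
#'
#' Ratio of theta-band to alpha-band absolute power, an index used to track
#' epileptic depolarization and alertness changes.
#'
#' @param fractions A `band_fractions` object.
#' @return The ratio (unitless). Errors if alpha power is zero.
#' @export
theta_alpha_ratio <- function(fractions) {
  stopifnot(inherits(fractions, "band_fractions"))
  if (fractions$power$alpha <= 0) {
    stop("alpha power is zero: theta/alpha ratio undefined", call. = FALSE)
  }
  fractions$power$theta / fractions$power$alpha
}

#' Locate spectral peaks
#'
#' Finds local maxima of the density within a frequency range that exceed a
#' prominence threshold (fraction of the range maximum), then refines each
#' peak frequency by quadratic interpolation through the three bins around
#' the maximum. For sub-bin localization compute the PSD with `pad` large
#' enough that the grid spacing is <= 0.05 Hz.
#'
#' @param psd A `psd_result`.
#' @param range Length-2 numeric `c(low, high)` in Hz.
#' @param prominence Threshold as a fraction of the maximum density in the
#'   range (default 0.1).
#' @return Numeric vector of peak frequencies (Hz), sorted increasing; empty
#'   when the spectrum has no qualifying local maximum.
#' @export
find_spectral_peaks <- function(psd, range = c(0, 8), prominence = 0.1) {
  stopifnot(inherits(psd, "psd_result"))
  if (length(range) != 2L || range[2] <= range[1]) stop("invalid frequency range", call. = FALSE)
  idx <- which(psd$freq >= range[1] & psd$freq <= range[2])
  if (length(idx) < 3L) stop("frequency range contains fewer than 3 grid points", call. = FALSE)
  d <- psd$density[idx]
  thr <- prominence * max(d)
  peaks <- numeric(0)
  for (i in 2:(length(d) - 1L)) {
    if (d[i] > d[i - 1L] && d[i] > d[i + 1L] && d[i] >= thr) {
      # quadratic refinement around the bin maximum
      y1 <- d[i - 1L]; y2 <- d[i]; y3 <- d[i + 1L]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
      peaks <- c(peaks, psd$freq[idx[i]] + delta * psd$df)
    }
  }
  sort(peaks)
}
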