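# Frequency-domain synthesis primitives. Band components are built on
# disjoint DFT bins, so their sample covariances vanish exactly and per-band
# powers add without cross terms -- this is what makes closed-loop band
# calibration possible.

# real noise with support on DFT bins in [lo, hi) Hz, unit RMS; optional
# amplitude weights as a function of frequency
fft_band_noise <- function(n, fs, lo, hi, weight = NULL) {
  nhalf <- n %/% 2L
  k <- seq_len(nhalf - if (n %% 2L == 0L) 1L else 0L)  # exclude Nyquist bin
  freq <- k * fs / n
  sel <- k[freq >= lo & freq < hi]
  if (!length(sel)) return(numeric(n))
  Z <- complex(length.out = n)
  amp <- if (is.null(weight)) rep(1, length(sel)) else weight(sel * fs / n)
  co <- complex(real = stats::rnorm(length(sel)), imaginary = stats::rnorm(length(sel))) * amp
  Z[sel + 1L] <- co
  Z[n - sel + 1L] <- Conj(co)
  x <- Re(stats::fft(Z, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r == 0) numeric(n) else x / r
}

# biphasic spike train: Gaussian-derivative transients on a jittered grid
spike_train <- function(n, fs, rate, width, jitter = 0.2) {
  x <- numeric(n)
  if (rate <= 0) return(x)
  dur <- n / fs
  nspk <- max(1L, round(dur * rate))
  centers <- ((seq_len(nspk) - 0.5) / rate) +
    (stats::runif(nspk, -0.5, 0.5) * jitter / rate)
  amps <- stats::runif(nspk, 0.8, 1.2)
  half <- ceiling(4 * width * fs)
  tt <- (-half:half) / fs
  pulse <- -tt / width * exp(-tt^2 / (2 * width^2))  # biphasic, zero-mean
  for (i in seq_len(nspk)) {
    c0 <- round(centers[i] * fs)
    idx <- (c0 - half):(c0 + half) + 1L
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + amps[i] * pulse[keep]
  }
  x
}

# exact per-band mean-square powers via DFT masking
band_powers_exact <- function(x, fs, edges) {
  n <- length(x)
  X <- stats::fft(x)
  freq <- (0:(n - 1L)) * fs / n
  freq_folded <- pmin(freq, fs - freq)
  vapply(seq_len(nrow(edges)), function(i) {
    sel <- freq_folded >= edges[i, 1] & freq_folded < edges[i, 2]
    sum(Mod(X[sel])^2) / n^2
  }, numeric(1))
}

# nearest 5-smooth length within 3% (FFT cost for arbitrary prime lengths
# is quadratic); falls back to the next power-of-two-ish length upward
smooth_n <- function(n) {
  if (n < 16L) return(n)
  cand <- numeric(0)
  p5 <- 1
  while (p5 <= 2 * n) {
    p3 <- p5
    while (p3 <= 2 * n) {
      p2 <- p3
      while (p2 < n) p2 <- 2 * p2
      cand <- c(cand, p2, p2 / 2)
      p3 <- 3 * p3
    }
    p5 <- 5 * p5
  }
  cand <- unique(cand[cand >= 0.97 * n & cand <= 1.03 * n])
  if (!length(cand)) return(stats::nextn(n, c(2, 3, 5)))
  as.integer(cand[which.min(abs(cand - n))])
}

# assemble the AD spectrum in one pass: in-band spike coefficients plus
# disjoint-bin noise, each band's power matched to its target exactly,
# then a single inverse FFT
synth_ad_signal <- function(n, fs, s, p_target, edges,
                            spike_cap = 0.5, total_cap = 0.6) {
  S <- stats::fft(s)
  nhalf <- n %/% 2L
  k <- seq_len(nhalf - if (n %% 2L == 0L) 1L else 0L)
  freq <- k * fs / n
  sel_list <- lapply(seq_len(nrow(edges)), function(i) {
    k[freq >= edges[i, 1] & freq < edges[i, 2]]
  })
  p_spike <- vapply(sel_list, function(sel) {
    2 * sum(Mod(S[sel + 1L])^2) / n^2
  }, numeric(1))
  tot_spike <- sum(p_spike)
  if (tot_spike > 0) {
    lim <- p_target / pmax(p_spike, 1e-300)
    c2 <- min(spike_cap * lim[p_spike > 1e-12 * tot_spike],
              total_cap * sum(p_target) / tot_spike)
    c2 <- max(c2, 0)
  } else {
    c2 <- 0
  }
  Z <- complex(length.out = n)
  for (i in seq_along(sel_list)) {
    sel <- sel_list[[i]]
    if (!length(sel)) next
    co <- complex(real = stats::rnorm(length(sel)),
                  imaginary = stats::rnorm(length(sel)))
    p_noise <- max(p_target[i] - c2 * p_spike[i], 0)
    p_unit <- 2 * sum(Mod(co)^2) / n^2
    co <- if (p_unit > 0) co * sqrt(p_noise / p_unit) else co * 0
    zi <- sqrt(c2) * S[sel + 1L] + co
    Z[sel + 1L] <- zi
    Z[n - sel + 1L] <- Conj(zi)
  }
  Re(stats::fft(Z, inverse = TRUE)) / n
}

#' Generate a baseline EEG record
#'
#' Seeded 1/f^beta colored noise confined to the [1, 40) Hz analysis range,
#' scaled to exactly `baseline_amplitude` uV RMS. With the default exponent
#' (1.5) the low-frequency band (1--8 Hz) carries most of the power, as
#' baseline EEG does.
#'
#' @param config A [sim_config()].
#' @param duration Length in seconds (default `config$baseline_duration`).
#' @param seed Optional integer seed (defaults to `config$seed`; NULL leaves
#'   the RNG state alone).
#' @return An `eeg_record`.
#' @examples
#' b <- generate_baseline(sim_config(seed = 1))
#' duration(b)  # 7 s
#' @export
generate_baseline <- function(config, duration = config$baseline_duration,
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  n <- round(duration * fs)
  beta <- config$spectral_exponent
  x <- fft_band_noise(n, fs, 1, 40, weight = function(f) f^(-beta / 2))
  eeg_record(x * config$baseline_amplitude, fs, label = "baseline")
}

#' Generate one afterdischarge segment
#'
#' Builds an AD epoch as a biphasic spike train superposed on band-shaped
#' colored noise. The LFB/MFB/HFB target triple is expanded to five sub-band
#' targets (delta/theta and beta/gamma shares from the config), the spike
#' train's exact per-band powers are measured at generation time, and
#' disjoint-bin noise tops each band up to its target, so the segment's band
#' powers match the targets by construction. Total RMS targets
#' `ad_envelope_ratio * ad_margin` times the baseline amplitude, and a final
#' smooth gain pass lifts any 0.5 s window whose RMS would dip below the
#' `ad_envelope_ratio` floor.
#'
#' @param entry A phase entry of a [group_profile()] (list with `fractions`;
#'   `fraction_sd` is ignored here -- per-event jitter is applied by
#'   [simulate_session()]).
#' @param duration Segment length in seconds (> 0).
#' @param config A [sim_config()].
#' @param seed Optional integer seed (NULL leaves the RNG state alone).
#' @return An `eeg_record` of the AD epoch.
#' @export
generate_ad_segment <- function(entry, duration, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  fr3 <- entry$fractions
  if (length(fr3) != 3L || abs(sum(fr3) - 1) > 1e-9 || any(fr3 < 0)) {
    stop("profile fractions must be a non-negative triple summing to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  # segment length snapped to a nearby FFT-friendly sample count (<= 3%);
  # annotations always carry the realized length
  n <- smooth_n(round(duration * fs))

  frac5 <- c(
    delta = fr3[1] * config$lfb_delta_share,
    theta = fr3[1] * (1 - config$lfb_delta_share),
    alpha = fr3[2],
    beta  = fr3[3] * (1 - config$hfb_gamma_share),
    gamma = fr3[3] * config$hfb_gamma_share
  )
  edges <- rbind(c(1, 4), c(4, 8), c(8, 12), c(12, 28), c(28, 40))

  target_rms <- config$ad_envelope_ratio * config$ad_margin * config$baseline_amplitude
  p_target <- frac5 * target_rms^2

  s <- spike_train(n, fs, config$spike_rate, config$spike_width)
  x <- synth_ad_signal(n, fs, s, p_target, edges)

  # envelope floor: every 0.25 s window at any offset must stay above
  # ratio x baseline RMS, enforced on a densely sampled (0.05 s hop) window
  # grid with a smooth multiplicative gain. The quarter-second enforcement
  # scale (half the detector's envelope window) bounds how far an event
  # edge can be displaced by a locally quiet stretch.
  floor_rms <- config$ad_envelope_ratio * config$baseline_amplitude
  fwin <- 0.25
  wlen <- round(fwin * fs)
  if (floor_rms > 0 && n >= wlen) {
    for (pass in 1:3) {
      env <- sliding_rms(x, fs, window = fwin, hop = 0.05)
      gain_w <- pmax(1, 1.06 * floor_rms / pmax(env$rms, 1e-12))
      if (all(gain_w <= 1 + 1e-9)) break
      g <- stats::approx(env$t + fwin / 2, gain_w,
                         xout = (seq_len(n) - 0.5) / fs, rule = 2)$y
      x <- x * g
    }
  }
  eeg_record(x, fs, label = "ad_segment")
}

#' Closed-loop calibration of a profile entry
#'
#' The Welch band estimator smears a small amount of power across adjacent
#' band edges, so the measured LFB/MFB/HFB triple of a generated segment is
#' biased by up to ~0.015 relative to the generation target, with the bias
#' depending on the spectral contrast. This routine measures that bias on
#' trial segments and pre-compensates the target linearly
#' (`adjusted = target + (target - measured)`), so that segments generated
#' from the adjusted entry read back at the nominal fractions.
#'
#' @param entry Phase entry of a [group_profile()].
#' @param config A [sim_config()].
#' @param duration Trial segment duration in seconds (default the entry's
#'   `add_mean`).
#' @param n_trials Number of trial segments averaged (default 10).
#' @return The entry with compensated `fractions`.
#' @export
calibrate_profile_entry <- function(entry, config, duration = entry$add_mean,
                                    n_trials = 10) {
  tgt <- entry$fractions
  meas <- rowMeans(vapply(seq_len(n_trials), function(i) {
    seg <- generate_ad_segment(entry, duration, config, seed = NULL)
    bf <- band_fractions(welch_psd(seg))
    c(bf$fraction$lfb, bf$fraction$mfb, bf$fraction$hfb)
  }, numeric(3)))
  adj <- pmax(tgt + (tgt - meas), 1e-3)
  entry$fractions <- adj / sum(adj)
  entry
}

#' Simulate a full kindling session
#'
#' Lays out a continuous record: a leading baseline of
#' `config$baseline_duration` seconds, then each scheduled AD event followed
#' by an `inter_event_gap` baseline stretch. Per-event band-fraction targets
#' are drawn from a Dirichlet distribution centred on the phase profile
#' (spread set by `fraction_sd`), so event-to-event spectral variability
#' matches the group tables while the across-event mean stays on target.
#' If the schedule carries an `onset_s` column the events are placed at those
#' onsets instead (error when they overlap or precede the lead baseline).
#'
#' @param profile A [group_profile()].
#' @param schedule Data frame from [default_schedule()] (columns `phase`,
#'   `racine_stage`, `duration_s`, optionally `animal_id`, `group`, `day`,
#'   `onset_s`).
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param calibrate Apply [calibrate_profile_entry()] once per phase before
#'   generating events (default TRUE), so that measured band fractions match
#'   the profile's nominal targets.
#' @return List with `record` (one continuous `eeg_record`) and `annotations`
#'   (data frame `animal_id`, `group`, `day`, `onset_s`, `duration_s`,
#'   `racine_stage`, `phase`), annotations matching the embedded segments
#'   exactly.
#' @export
simulate_session <- function(profile, schedule, config, seed = config$seed,
                             calibrate = TRUE) {
  stopifnot(inherits(profile, "group_profile"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (calibrate && nrow(schedule) > 0L) {
    for (ph in unique(schedule$phase)) {
      profile$phases[[ph]] <- calibrate_profile_entry(profile$phases[[ph]], config)
    }
  }
  fs <- config$sampling_rate
  lead <- config$baseline_duration
  gap <- config$inter_event_gap
  n_ev <- nrow(schedule)

  mk_baseline <- function(dur) {
    generate_baseline(config, duration = dur, seed = NULL)$samples
  }

  explicit <- n_ev > 0L && "onset_s" %in% names(schedule)
  if (explicit) {
    schedule <- schedule[order(schedule$onset_s), , drop = FALSE]
    ends <- schedule$onset_s + schedule$duration_s
    if (any(schedule$onset_s < lead - 1e-9) ||
        (n_ev > 1L && any(schedule$onset_s[-1L] < ends[-n_ev] - 1e-9))) {
      stop("scheduled events overlap or start inside the lead baseline", call. = FALSE)
    }
  }

  pieces <- list(mk_baseline(if (explicit) schedule$onset_s[1L] else lead))
  onsets <- numeric(n_ev)
  t_cursor <- lead
  ann <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    e <- profile$phases[[schedule$phase[i]]]
    fr <- rdirichlet_mean(e$fractions, e$fraction_sd)
    seg <- generate_ad_segment(list(fractions = fr), schedule$duration_s[i],
                               config, seed = NULL)
    # exact annotation from the embedded extent
    dur_i <- length(seg$samples) / fs
    onsets[i] <- if (explicit) schedule$onset_s[i] else t_cursor
    pieces[[length(pieces) + 1L]] <- seg$samples
    nxt <- if (explicit) {
      if (i < n_ev) schedule$onset_s[i + 1L] else onsets[i] + dur_i + gap
    } else {
      onsets[i] + dur_i + gap
    }
    gap_dur <- nxt - (onsets[i] + dur_i)
    if (explicit && gap_dur < 0) {
      stop("realized segment overlaps the next scheduled onset", call. = FALSE)
    }
    if (gap_dur > 0) pieces[[length(pieces) + 1L]] <- mk_baseline(gap_dur)
    t_cursor <- onsets[i] + dur_i + gap
    ann[[i]] <- data.frame(
      animal_id = if ("animal_id" %in% names(schedule)) schedule$animal_id[i] else profile$group_label,
      group = profile$group_label,
      day = if ("day" %in% names(schedule)) schedule$day[i] else 1L,
      onset_s = onsets[i], duration_s = dur_i,
      racine_stage = schedule$racine_stage[i],
      phase = schedule$phase[i],
      stringsAsFactors = FALSE
    )
  }
  record <- eeg_record(unlist(pieces), fs,
                       label = sprintf("session_%s", profile$group_label))
  annotations <- if (n_ev > 0L) do.call(rbind, ann) else
    data.frame(animal_id = character(0), group = character(0), day = integer(0),
               onset_s = numeric(0), duration_s = numeric(0),
               racine_stage = integer(0), phase = character(0))
  list(record = record, annotations = annotations)
}

#' Afterdischarge-probability response curve
#'
#' Monotone probability of evoking an afterdischarge as a function of
#' stimulation intensity. `slope = 0` gives a deterministic step at the true
#' threshold; positive slopes give a logistic response. A non-responder
#' (`true_threshold = Inf` or `NULL`) never discharges.
#'
#' @param true_threshold Intensity (uA) at which the animal starts to
#'   respond; `Inf`/`NULL` for a non-responder.
#' @param slope Logistic scale in uA (default 0: deterministic step).
#' @return A `response_curve` object (callable via [ad_probability()]).
#' @export
response_curve <- function(true_threshold, slope = 0) {
  if (is.null(true_threshold)) true_threshold <- Inf
  if (slope < 0) stop("slope must be non-negative", call. = FALSE)
  structure(list(true_threshold = true_threshold, slope = slope),
            class = "response_curve")
}

#' Probability of afterdischarge at a stimulation intensity
#' @param curve A [response_curve()].
#' @param intensity Stimulation intensity in uA.
#' @return Probability in [0, 1], non-decreasing in intensity.
#' @export
ad_probability <- function(curve, intensity) {
  stopifnot(inherits(curve, "response_curve"))
  if (is.infinite(curve$true_threshold)) return(rep(0, length(intensity)))
  if (curve$slope == 0) {
    as.numeric(intensity >= curve$true_threshold)
  } else {
    stats::plogis((intensity - curve$true_threshold) / curve$slope)
  }
}

#' Simulate the AD-threshold titration staircase
#'
#' Intensity starts at 30 uA and rises in 15 uA increments; at each step a
#' Bernoulli draw from the response curve decides whether an afterdischarge
#' is evoked. Animals that never discharge by the 350 uA maximum are flagged
#' excluded.
#'
#' @param curve A [response_curve()].
#' @param start Starting intensity, uA (default 30).
#' @param step Increment, uA (default 15).
#' @param maximum Exclusion cap, uA (default 350).
#' @param seed Optional integer seed.
#' @return A `titration_result`: `threshold` (uA, NA when excluded),
#'   `excluded` (logical), `steps_taken`.
#' @examples
#' simulate_threshold_titration(response_curve(100))$threshold  # 105
#' @export
simulate_threshold_titration <- function(curve, start = 30, step = 15,
                                         maximum = 350, seed = NULL) {
  stopifnot(inherits(curve, "response_curve"))
  if (start > maximum) stop("start must not exceed maximum", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  intensities <- seq(start, maximum, by = step)
  for (i in seq_along(intensities)) {
    p <- ad_probability(curve, intensities[i])
    if (stats::runif(1) < p) {
      return(structure(list(threshold = intensities[i], excluded = FALSE,
                            steps_taken = i), class = "titration_result"))
    }
  }
  structure(list(threshold = NA_real_, excluded = TRUE,
                 steps_taken = length(intensities)),
            class = "titration_result")
}
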