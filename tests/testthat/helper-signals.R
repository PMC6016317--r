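# shared fixtures, built in code

# pure tone record; amp is the peak amplitude
make_tone <- function(freq, dur = 8, fs = 1000, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  eeg_record(amp * sin(2 * pi * freq * t + phase), fs)
}

# baseline + one constant-amplitude epoch + baseline, for detector rule tests;
# the epoch is a 6 Hz tone scaled so its RMS is `ratio` x the baseline RMS
make_epoch_record <- function(ratio, epoch_dur, fs = 500, seed = 3,
                              lead = 10, tail = 5, base_amp = 50) {
  cfg <- function(s) sim_config(sampling_rate = fs, baseline_amplitude = base_amp, seed = s)
  b1 <- generate_baseline(cfg(seed), lead)
  b2 <- generate_baseline(cfg(seed + 1), tail)
  t <- seq(0, epoch_dur - 1 / fs, by = 1 / fs)
  ep <- ratio * base_amp * sqrt(2) * sin(2 * pi * 6 * t)
  eeg_record(c(b1$samples, ep, b2$samples), fs)
}

# brute-force Welch oracle: direct-summation DFT periodogram average with
# the same contract (Hann taper, linear detrend via lm, one-sided density,
# global variance rescale), sharing no code with welch_psd
brute_force_welch <- function(x, fs, segment_length = 2, overlap = 0.5) {
  nper <- round(segment_length * fs)
  step <- round(nper * (1 - overlap))
  starts <- seq(1, length(x) - nper + 1, by = step)
  k <- 0:(nper - 1)
  w <- 0.5 - 0.5 * cos(2 * pi * k / nper)
  nhalf <- nper %/% 2
  acc <- numeric(nhalf + 1)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    fit <- stats::lm(seg ~ seq_along(seg))
    y <- stats::residuals(fit) * w
    for (m in 0:nhalf) {
      X <- sum(y * exp(-2i * pi * m * k / nper))
      dbl <- if (m == 0 || (nper %% 2 == 0 && m == nhalf)) 1 else 2
      acc[m + 1] <- acc[m + 1] + dbl * Mod(X)^2 / (fs * sum(w^2))
    }
  }
  dens <- acc / length(starts)
  df <- fs / nper
  varx <- mean(x^2) - mean(x)^2
  integ <- sum(dens) * df
  if (integ > 0 && varx > 0) dens <- dens * (varx / integ)
  list(freq = (0:nhalf) * df, density = dens)
}

# detected-vs-annotated comparison used by round-trip tests
roundtrip_errors <- function(sess, ratio = 2.5, min_duration = 6) {
  bs <- baseline_stats(sess$record)
  det <- detect_ad_events(sess$record, bs, ratio = ratio,
                          min_duration = min_duration)
  ann <- sess$annotations[order(sess$annotations$onset_s), , drop = FALSE]
  err <- vapply(seq_len(nrow(ann)), function(i) {
    a0 <- ann$onset_s[i]; a1 <- a0 + ann$duration_s[i]
    if (!nrow(det)) return(NA_real_)
    ov <- pmin(det$onset + det$duration, a1) - pmax(det$onset, a0)
    j <- which.max(ov)
    if (ov[j] <= 0) return(NA_real_)
    det$duration[j] - ann$duration_s[i]
  }, numeric(1))
  list(n_detected = nrow(det), add_error = err)
}

# run one phase of one group through simulate -> detect -> label -> measure
measure_group_phase <- function(group, phase, seed, profiles = default_group_profiles()) {
  prof <- profiles[[group]]
  cfg <- sim_config(seed = seed)
  sched <- default_schedule(prof, seed = seed, phases = phase)
  sess <- simulate_session(prof, sched, cfg, seed = seed)
  bs <- baseline_stats(sess$record)
  det <- detect_ad_events(sess$record, bs)
  lab <- label_segments(det, sess$annotations)
  kindleeg:::measure_segments(sess$record, lab[lab$matched & lab$phase == phase, ])
}
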