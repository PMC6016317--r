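#' Simulator configuration
#'
#' Parameters of the synthetic kindling-EEG generator. Defaults are the
#' desk-scale study conditions: 1000 Hz sampling (the acquisition-grade
#' 10 kHz is supported but unnecessary for a 0--40 Hz analysis; 1000 Hz still
#' leaves a 12.5x Nyquist margin over the gamma upper edge), a 7 s baseline
#' window, a 1/f^1.5 baseline spectrum over [1, 40) Hz so delta--theta
#' dominate, and afterdischarge segments generated at
#' `ad_envelope_ratio * ad_margin` times the baseline RMS so that every
#' 0.5 s window clears the 2.5x detection floor.
#'
#' @param sampling_rate Hz (default 1000). Must be at least 80 (Nyquist must
#'   cover the 40 Hz gamma edge).
#' @param baseline_duration Baseline window length in seconds (default 7).
#' @param spectral_exponent Baseline 1/f^beta slope (default 1.5).
#' @param baseline_amplitude Baseline RMS amplitude in uV (default 50).
#' @param ad_envelope_ratio Guaranteed AD envelope floor as a multiple of
#'   baseline RMS (default 2.5; must exceed 1).
#' @param ad_margin Generation margin above the floor (default 1.8, i.e. AD
#'   segments target 4.5x baseline RMS so the floor-enforcement gain rarely
#'   binds and stochastic envelope dips stay above 2.5x).
#' @param spike_rate Afterdischarge spike rate in Hz (default 5).
#' @param spike_width Width (Gaussian sigma, s) of the biphasic spike
#'   transient (default 0.04).
#' @param lfb_delta_share Share of LFB power assigned to delta when a profile
#'   specifies only the LFB/MFB/HFB triple (default 0.7; the remainder is
#'   theta).
#' @param hfb_gamma_share Share of HFB power assigned to gamma (default 0.35;
#'   the remainder is beta).
#' @param inter_event_gap Baseline gap between consecutive session events in
#'   seconds (default 5).
#' @param seed Optional integer seed consumed by generators that receive this
#'   config without an explicit seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 1000, baseline_duration = 7,
                       spectral_exponent = 1.5, baseline_amplitude = 50,
                       ad_envelope_ratio = 2.5, ad_margin = 1.8,
                       spike_rate = 5, spike_width = 0.04,
                       lfb_delta_share = 0.7, hfb_gamma_share = 0.35,
                       inter_event_gap = 5, seed = NULL) {
  if (sampling_rate < 80) stop("sampling_rate must be >= 80 Hz (2 x 40 Hz gamma edge)", call. = FALSE)
  if (baseline_duration <= 0) stop("baseline_duration must be positive", call. = FALSE)
  if (ad_envelope_ratio <= 1) stop("ad_envelope_ratio must exceed 1", call. = FALSE)
  if (ad_margin <= 1) stop("ad_margin must exceed 1", call. = FALSE)
  if (baseline_amplitude < 0) stop("baseline_amplitude must be non-negative", call. = FALSE)
  if (inter_event_gap <= 0) stop("inter_event_gap must be positive", call. = FALSE)
  structure(
    list(sampling_rate = sampling_rate, baseline_duration = baseline_duration,
         spectral_exponent = spectral_exponent,
         baseline_amplitude = baseline_amplitude,
         ad_envelope_ratio = ad_envelope_ratio, ad_margin = ad_margin,
         spike_rate = spike_rate, spike_width = spike_width,
         lfb_delta_share = lfb_delta_share, hfb_gamma_share = hfb_gamma_share,
         inter_event_gap = inter_event_gap, seed = seed),
    class = "sim_config"
  )
}

#' Group simulation profile
#'
#' Per-phase calibration of a treatment group: target LFB/MFB/HFB fractions,
#' across-event fraction spread, AD-duration mean/SD, and event count. The
#' fraction triple is renormalized to sum to exactly 1 (printed group tables
#' round to 3--4 decimals and can be off by ~0.002).
#'
#' @param group_label One of "Kindle", "LFSK", "KLFS" (free-form allowed).
#' @param phases Named list with entries `ISS`, `LSS`, `GSS`; each a list with
#'   `fractions` (length-3 LFB/MFB/HFB, non-negative, summing to ~1),
#'   `fraction_sd` (SD of the LFB fraction across events; 0 disables
#'   per-event jitter), `add_mean` (s, must be >= 6 so events stay
#'   detectable), `add_sd` (s), `event_count` (>= 0).
#' @param n_animals Number of animals carrying the group's events.
#' @return A `group_profile` object.
#' @export
group_profile <- function(group_label, phases, n_animals = 6) {
  for (ph in names(phases)) {
    e <- phases[[ph]]
    fr <- e$fractions
    if (length(fr) != 3L || any(fr < 0)) {
      stop("each phase needs a non-negative length-3 LFB/MFB/HFB fraction triple", call. = FALSE)
    }
    if (abs(sum(fr) - 1) > 0.02) {
      stop(sprintf("%s/%s fractions sum to %.4f, not ~1", group_label, ph, sum(fr)), call. = FALSE)
    }
    phases[[ph]]$fractions <- fr / sum(fr)
    if (is.null(e$fraction_sd)) phases[[ph]]$fraction_sd <- 0
    if (e$add_mean < 6) {
      stop("add_mean must be >= 6 s (minimum-duration detectability)", call. = FALSE)
    }
    if (e$event_count < 0) stop("event_count must be non-negative", call. = FALSE)
  }
  structure(list(group_label = group_label, phases = phases,
                 n_animals = n_animals),
            class = "group_profile")
}

#' Default study calibration
#'
#' The three treatment groups of the kindling/LFS study with phase-wise
#' band-fraction targets, AD durations and event counts taken from the
#' study's group tables and results: kindle 61 ISS / 42 LSS / 35 GSS events
#' (LSS mean 12.4285 s, GSS 22.28 s), LFSK 38/13/4 (9.373 s, 16.9 s), KLFS
#' 39/14/6 (10.064 s, 17.82 s). ISS durations (8 s) and GSS fraction triples
#' are generator choices documented in the methods vignette.
#'
#' @return Named list of `group_profile` objects (`Kindle`, `LFSK`, `KLFS`).
#' @export
default_group_profiles <- function() {
  list(
    Kindle = group_profile("Kindle", list(
      ISS = list(fractions = c(0.828, 0.082, 0.088), fraction_sd = 0.088,
                 add_mean = 8, add_sd = 1.5, event_count = 61),
      LSS = list(fractions = c(0.7091, 0.1323, 0.1557), fraction_sd = 0.1005,
                 add_mean = 12.4285, add_sd = 1.5, event_count = 42),
      GSS = list(fractions = c(0.60, 0.17, 0.23), fraction_sd = 0.08,
                 add_mean = 22.28, add_sd = 2, event_count = 35)
    ), n_animals = 7),
    LFSK = group_profile("LFSK", list(
      ISS = list(fractions = c(0.845, 0.065, 0.081), fraction_sd = 0.043,
                 add_mean = 8, add_sd = 1.5, event_count = 38),
      LSS = list(fractions = c(0.9124, 0.0451, 0.042), fraction_sd = 0.0223,
                 add_mean = 9.373, add_sd = 1.5, event_count = 13),
      GSS = list(fractions = c(0.75, 0.10, 0.15), fraction_sd = 0.05,
                 add_mean = 16.9, add_sd = 2, event_count = 4)
    ), n_animals = 6),
    KLFS = group_profile("KLFS", list(
      ISS = list(fractions = c(0.851, 0.065, 0.074), fraction_sd = 0.057,
                 add_mean = 8, add_sd = 1.5, event_count = 39),
      LSS = list(fractions = c(0.8825, 0.0582, 0.0592), fraction_sd = 0.0465,
                 add_mean = 10.064, add_sd = 1.5, event_count = 14),
      GSS = list(fractions = c(0.72, 0.11, 0.17), fraction_sd = 0.05,
                 add_mean = 17.82, add_sd = 2, event_count = 6)
    ), n_animals = 6)
  )
}

# truncated-normal draws (lower bound only) via inverse-CDF sampling
rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(pmax(mean, lower), n))
  plo <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(plo + stats::runif(n) * (1 - plo))
}

# Dirichlet draw around a mean triple with concentration derived from the
# target across-event SD of the first component
rdirichlet_mean <- function(mean, sd_first) {
  p <- mean[1]
  if (sd_first <= 0) return(mean)
  conc <- max(p * (1 - p) / sd_first^2 - 1, 5)
  g <- stats::rgamma(length(mean), shape = conc * pmax(mean, 1e-6))
  g / sum(g)
}

#' Build a session event schedule for one group
#'
#' Expands a `group_profile` into per-event rows: phase, Racine stage
#' (ISS events draw stage 1 or 2, GSS events stage 4 or 5), AD duration
#' drawn from a truncated normal (lower bound 6 s) at the profile's
#' mean/SD, and animal/day assignment (events distributed round-robin over
#' the group's animals and a 5-day acquisition). Row order is shuffled so
#' phases interleave as they would across kindling days.
#'
#' @param profile A `group_profile`.
#' @param seed Optional integer seed.
#' @param phases Which phases to include (default all present in the profile).
#' @return Data frame with columns `animal_id`, `group`, `day`, `phase`,
#'   `racine_stage`, `duration_s`.
#' @export
default_schedule <- function(profile, seed = NULL, phases = names(profile$phases)) {
  stopifnot(inherits(profile, "group_profile"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ph in phases) {
    e <- profile$phases[[ph]]
    n <- e$event_count
    if (n == 0L) next
    stage <- switch(ph,
      ISS = sample(1:2, n, replace = TRUE),
      LSS = rep(3L, n),
      GSS = sample(4:5, n, replace = TRUE)
    )
    rows[[ph]] <- data.frame(
      group = profile$group_label,
      phase = ph,
      racine_stage = stage,
      duration_s = rtrunc_norm(n, e$add_mean, e$add_sd, lower = 6),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(animal_id = character(0), group = character(0),
                      day = integer(0), phase = character(0),
                      racine_stage = integer(0), duration_s = numeric(0)))
  }
  sched <- do.call(rbind, rows)
  sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
  n <- nrow(sched)
  sched$animal_id <- sprintf("%s_%02d", profile$group_label,
                             rep_len(seq_len(profile$n_animals), n))
  sched$day <- rep_len(1:5, n)
  rownames(sched) <- NULL
  sched[, c("animal_id", "group", "day", "phase", "racine_stage", "duration_s")]
}
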