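---
title: "Quantitative EEG analysis of kindling afterdischarges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG analysis of kindling afterdischarges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(kindleeg)
```

## The scientific problem

Electrical kindling is a standard experimental model of temporal-lobe
epilepsy: repeated sub-convulsive stimulation of the amygdala progressively
produces generalized seizures. Each stimulation evokes an *afterdischarge*
(AD) — a train of large spikes superimposed on the EEG baseline — whose
duration (ADD) and spectral content track the progression of
epileptogenesis through the Racine stages (1–2: initial seizure stages,
ISS; 3: localized, LSS; 4–5: generalized, GSS). Low-frequency stimulation
(LFS, 1 Hz pulse trains) applied either immediately before daily kindling
(LFSK) or immediately after it (KLFS) is a candidate antiepileptogenic
intervention; its signature in the EEG is a shift of AD power toward the
low-frequency band and away from mid and high frequencies.

`kindleeg` implements the quantitative layer of such a study as a tested,
reusable pipeline: AD detection by an amplitude/duration rule, Welch
band-power decomposition of the detected AD segments, the theta/alpha-ratio
biomarker, and the group-level statistics — exercised end to end on a
synthetic kindling-EEG generator calibrated to the group-level band-fraction
tables and AD durations of the underlying study design, since raw rat EEG of
this kind is rarely deposited.

Frequency bands (all half-open `[low, high)` Hz):

| band  | range   | aggregate |
|-------|---------|-----------|
| delta | 1–4     | LFB (1–8) |
| theta | 4–8     | LFB       |
| alpha | 8–12    | MFB       |
| beta  | 12–28   | HFB (12–40) |
| gamma | 28–40   | HFB       |

Band powers and fractions are always normalized by the total power in
[1, 40) Hz. The lower edge is set at 1 Hz (not 0) deliberately: sub-1 Hz
energy is dominated by electrode drift and DC offset, and band tables in
this literature are internally inconsistent about whether delta starts at 0
or 1 Hz; excluding sub-1 Hz content from every total resolves the
inconsistency in favour of the definition used in the analysis methods and
keeps drift out of all fractions. The edges are configurable through
`band_scheme()`.

## The synthetic generator

`generate_baseline()` produces 1/f^β colored noise (default β = 1.5)
confined to [1, 40) Hz and scaled to exactly the configured RMS (default
50 µV). With this exponent the low-frequency band carries ≈ 77% of the
power, matching the delta–theta dominance of resting rodent EEG.

`generate_ad_segment()` builds an AD epoch as a biphasic spike train
(Gaussian-derivative transients, default 5 Hz rate with 20% timing jitter,
σ = 40 ms) superposed on band-shaped noise. The construction is spectral:
all components live on disjoint DFT bins inside [1, 40) Hz, so per-band
powers add without cross terms and the band-fraction targets are hit by
construction. The spike train's exact per-band powers are measured at
generation time and the noise tops each band up to its target; spike energy
is capped at half of any band's target so the targets always remain
feasible. The LFB/MFB/HFB triple of a profile is expanded to five sub-bands
with fixed shares (delta = 70% of LFB, gamma = 35% of HFB by default) —
the study tables constrain only the three aggregates.

Amplitude: segments target `ad_envelope_ratio * ad_margin` (= 2.5 × 1.8 =
4.5) times the baseline RMS, and a final smooth multiplicative gain pass
lifts any 0.25 s window whose RMS would dip below the 2.5× floor, evaluated
on a dense (0.05 s hop) grid. The enforcement scale is half the detector's
envelope window, which bounds how far a locally quiet stretch can displace
a detected edge. The margin default of 1.8 was chosen so the floor gain
rarely binds: gain modulation convolves the spectrum and at tighter margins
it measurably biases the low-frequency fraction of the generated segment.

Sampling rate defaults to 1000 Hz. Acquisition systems in this field
digitize at 10 kHz, which the generator supports, but a 0–40 Hz analysis
needs no more than a 12.5× Nyquist margin over the gamma edge, and the
desk-scale default keeps full-study simulation in seconds.

### Calibration to the study conditions

`default_group_profiles()` encodes the study conditions: per group and
phase, the target LFB/MFB/HFB fractions and their across-event spread, the
AD-duration mean/SD, and the event count (kindle 61 ISS / 42 LSS / 35 GSS;
LFSK 38/13/4; KLFS 39/14/6; LSS durations 12.4285 / 9.373 / 10.064 s and
GSS durations 22.28 / 16.9 / 17.82 s for kindle / LFSK / KLFS). Printed
fraction triples are renormalized to sum to exactly 1 (tables round to 3–4
decimals). Two quantities the tables do not state are generator choices:
ISS durations default to 8 s (plausibly between the 6 s detectability floor
and the LSS means), and GSS fraction triples follow the qualitative
description (mid- and high-frequency content higher in the kindle group's
GSS than its LSS, and reduced under LFS).

Event-to-event spectral variability is modelled as a Dirichlet draw centred
on the phase target with concentration chosen so the SD of the LFB fraction
matches the printed SD. The study tables do not state whether their SDs are
across events, animal-stage means, or animals (their degrees of freedom are
not fully consistent with any single reading); the generator treats them as
across-event SDs, the most conservative choice for inference, and exposes
the spread as a free parameter.

AD durations are truncated-normal draws with a lower bound of 6 s — the
detectability rule makes shorter events unobservable by definition, so the
simulated population respects it.

Because the Welch estimator smears a small amount of power across band
edges (below), a session generator that naively used the table targets
would read back biased by up to ~0.015. `calibrate_profile_entry()` closes
the loop: it measures the generator-to-estimator bias on trial segments and
pre-compensates the target linearly, so that the *measured* fractions of a
simulated session match the nominal targets. `simulate_session()` and
`run_study()` apply this calibration once per phase profile.

### Threshold titration

`simulate_threshold_titration()` models the AD-threshold staircase:
stimulation starts at 30 µA and rises in 15 µA steps; at each step a
Bernoulli draw from a monotone response curve (deterministic step or
logistic in intensity) decides whether an AD is evoked, and animals that
never respond by 350 µA are flagged excluded. The study protocol specifies
the staircase but no response model; the Bernoulli-per-step choice is the
simplest monotone stochastic model.

## The afterdischarge detector

The detection rule is the study's: an AD is an epoch of at least 6 s whose
amplitude is at least 2.5 times the baseline EEG. The paper does not define
its amplitude metric; `detect_ad_events()` operationalizes it as a
sliding-RMS envelope in 0.5 s windows with 50% overlap, compared against
the RMS of a 7 s baseline window (`baseline_stats()`). RMS is robust to
single-sample spikes, and the window is short enough to resolve the 6 s
minimum. Sub-threshold dips of at most 0.5 s inside an event are bridged
before the duration rule is applied: spike-train ADs dip between spikes,
and unbridged gaps would fragment events. The gap length is a parameter.

Event *existence* is decided on that coarse envelope. Event *edges* are
then localized by a change-point estimator: the instantaneous power steps
from the baseline level b² to at least the threshold level at the boundary,
and the maximum-likelihood location of a step between two known levels is
the extremum of the CUSUM statistic `D(t) = Σ (x² − λ)` with the reference
λ midway between baseline and threshold power. Two design details matter:

* λ is centred on the *threshold*, not on the event's interior power —
  quiet between-spike stretches inside an event then still drift upward and
  cannot capture the extremum;
* the instantaneous power is pre-smoothed with a 25 ms boxcar, stabilizing
  the extremum against single-sample fluctuations.

Fine-scale RMS thresholding was considered and rejected: at sub-cycle
scales (≲ 0.25 s) the RMS of delta-dominated activity dips near slow-wave
zero crossings, and a substantial fraction of 0.1 s windows inside a
genuine AD fall below any reasonable threshold.

The ≥ 6 s rule is enforced with an allowance of half an envelope window
(0.25 s), matching the quantization of the estimated extent; without it,
events drawn at the 6 s boundary of the duration distribution flicker in
and out of detection. Detected events are reported as half-open intervals
`[onset, onset + duration)` with onset in seconds.

`label_segments()` matches detections to stage annotations by maximal
temporal overlap, flags unmatched events, takes the ADD from the detected
extent and the stage/phase/animal/group from the annotation. Only the AD
part of the signal goes into spectral analysis.

Verified performance under the default study conditions (the test suite
recomputes this): 100% recall, zero false positives on pure baseline, and
per-event ADD error bounded by 0.5 s (typical |error| < 0.2 s) across
thousands of simulated events.

## The spectral estimator

`welch_psd()` is the averaged modified periodogram: 2 s sub-segments
(0.5 Hz native resolution), 50% overlap, periodic Hann taper, linear
detrend per sub-segment (electrode drift; the study methods are silent, and
detrending is standard practice). The 2 s sub-segment length means a
minimum-length 6 s AD still averages 5 periodograms. The density is
one-sided and finished with one global rescale so that its integral equals
the signal variance exactly. The rescale is a single constant across
frequency: it cannot change any band fraction or ratio, it only pins the
absolute scale, which taper weighting would otherwise bias by a few percent
on strongly autocorrelated signals. Per-segment rescaling was considered
and rejected — it couples the scale factor to each segment's realized
low-frequency content and measurably biases the high-frequency fraction
upward (a Jensen effect).

Known bias: the Hann kernel smears power across band edges in proportion to
the density contrast at the edge, biasing e.g. a 0.91-LFB profile's
measured LFB downward by ~0.01. This is inherent to any windowed estimator
at 0.5 Hz resolution; the generator's closed-loop calibration compensates
for it on the simulation side, and the acceptance checks measure through
the same estimator the study would have used.

`band_fractions()` integrates the density over the half-open bands and
normalizes by the [1, 40) Hz total; `theta_alpha_ratio()` is the ratio of
absolute theta to alpha power and errors (rather than returning infinity)
when alpha power is zero. `find_spectral_peaks()` reports local maxima
above a prominence threshold with quadratic sub-bin refinement; computing
the PSD with `pad` large enough for a ≤ 0.05 Hz grid gives the sub-bin
localization used for peak tables.

## The statistical layer

* `ks_normality()` — Kolmogorov–Smirnov normality check with mean and SD
  estimated from the sample, i.e. Lilliefors critical values
  (`nortest::lillie.test`). A plain KS test against the fitted normal would
  be anti-conservative. Requires n ≥ 4.
* `one_way_anova()` / `one_way_anova_summary()` — F from the
  sums-of-squares identities on (mean, SD, n) summaries; the raw-data route
  computes the summaries and calls the same formula, so the two agree to
  machine precision (and both agree with `aov`, which the tests verify
  independently).
* `bonferroni_pairwise()` — all pairwise t statistics using the pooled
  within-group mean square from the omnibus ANOVA (error df N − k), raw p
  multiplied by the number of comparisons and capped at 1.
* `two_way_anova()` — `car::Anova` Type-II sums of squares behind the
  module surface, because the group × phase design is heavily unbalanced
  (event counts differ by an order of magnitude across cells). A
  single-level factor reduces to the one-way analysis; an empty cell
  switches to the additive model and flags the interaction as missing
  rather than failing.
* `kruskal_wallis()` — `stats::kruskal.test` (tie-corrected H), with the
  all-ties case returning H = 0 instead of erroring.
* `pearson_r()` — `stats::cor.test`, with explicit errors for constant
  input.

`run_study()` aggregates at the event level by default (one row per AD);
per-animal aggregation is available through `study_config(aggregate =
"animal")`. The choice genuinely matters for degrees of freedom and the
study tables do not pin it down (their printed df are not consistent with
any single aggregation of the stated animal counts); per-event is the
default because it uses all information and makes the unbalanced design
explicit to the Type-II ANOVA. GSS inferential statistics are computed only
when every group carries at least 3 GSS events; otherwise the phase is
summarized descriptively — with 4–6 events per LFS group the tests would
be unreliable, which mirrors how such sparse cells are handled in practice.

## Problem sizes and determinism

The default full study simulates 19 animal-sessions (252 AD events,
roughly 1.5 h of synthetic EEG at 1000 Hz) in a few seconds. The test
suite's heavier checks use 100 seeded records for the detector suite,
10⁴ null simulations for the ANOVA type-I calibration, and 20 full study
runs for the direction-of-effect check; these sizes give Monte-Carlo
standard errors comfortably below the tolerances they are tested against.
Every generator and the study driver are pure functions of their seed:
identical seeds give bitwise-identical records, annotations and reports.

## What the synthetic data does and does not show

The generator reproduces the *statistical* structure the analysis consumes:
1/f baseline, spike-train ADs with calibrated band fractions and envelope
floor, stage-dependent durations and counts, event-to-event spectral
spread. It does not model biophysics (no neuron or network dynamics, no LFS
pulse interaction with tissue), non-stationarity within an AD (real ADs
evolve tonically→clonically; generated segments are stationary), artifacts
(movement, line noise, electrode pops), or within-animal correlation of
spectral profiles across days. Passing the closed-loop tests therefore
demonstrates that the pipeline measures what it claims on signals with the
study's declared statistical structure — it does not validate the detector
against artifact-laden recordings, and detector settings (ratio, minimum
duration, gap bridging) should be re-examined before use on real EEG.
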