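# kindleeg

Quantitative EEG analysis of afterdischarges in the amygdala rapid-kindling
model of temporal-lobe epilepsy, with a calibrated synthetic-EEG generator.

## What this is for

In the kindling model, repeated electrical stimulation of the amygdala
evokes *afterdischarges* (ADs) — trains of large spikes on the EEG
baseline — whose duration and spectral content track epileptogenesis
through the Racine stages (1–2 = initial, ISS; 3 = localized, LSS;
4–5 = generalized, GSS). Low-frequency stimulation (LFS) applied before
(LFSK) or after (KLFS) daily kindling is a candidate antiepileptogenic
intervention whose EEG signature is a shift of AD power toward low
frequencies. `kindleeg` is for researchers who want that analysis chain as
tested, seeded, reusable code:

* **AD detection** by the field's rule — amplitude ≥ 2.5 × baseline RMS for
  at least 6 s — with sliding-RMS envelope, gap bridging and change-point
  edge localization;
* **spectral decomposition** of detected AD segments: Hann-windowed,
  50 %-overlap Welch PSD, reduced to delta (1–4 Hz), theta (4–8), alpha
  (8–12), beta (12–28), gamma (28–40) sub-band powers, the LFB (1–8) /
  MFB (8–12) / HFB (12–40) aggregates as fractions of total 1–40 Hz power,
  the theta/alpha ratio, and spectral peaks;
* **group statistics**: Lilliefors (KS) normality, one-way ANOVA
  (F = MS_between/MS_within, also computable from (mean, SD, n) summaries),
  Bonferroni post hoc on the pooled error term, Type-II two-way
  group × phase ANOVA, Kruskal–Wallis H, and Pearson correlations between
  AD duration (ADD) and band powers;
* a **synthetic kindling-EEG generator** — 1/f baseline, biphasic spike
  trains on band-shaped noise with closed-loop band-fraction calibration,
  truncated-normal stage durations, per-group event counts, and the
  AD-threshold titration staircase (30 µA start, 15 µA steps, 350 µA
  exclusion cap) — so the whole pipeline can be exercised and validated
  end to end at desk scale.

## Worked example

Simulate three kindle-group events, detect them against the animal's own
7 s baseline, and decompose the first detected AD:

```r
library(kindleeg)

prof  <- default_group_profiles()$Kindle
sched <- default_schedule(prof, seed = 8)[1:3, ]
sess  <- simulate_session(prof, sched, sim_config(), seed = 8)
sess$record
#> <eeg_record> session_Kindle: 62816 samples @ 1000 Hz (62.816 s), start 0.000 s

bs <- baseline_stats(sess$record)
bs
#> <baseline_stats> rms = 50.000 uV over 7 s (envelope: 27 windows)

detect_ad_events(sess$record, bs)
#>     onset duration
#> 1  6.9895   21.622
#> 2 33.5915    9.834
#> 3 48.4305    9.397
```

The three annotated events (a 21.6 s GSS, a 9.8 s LSS, a 9.4 s ISS) are
recovered with onsets and durations within ~0.05 s of the embedded truth.
Cutting the first AD and measuring its band content:

```r
lab <- label_segments(detect_ad_events(sess$record, bs), sess$annotations)
seg <- slice_record(sess$record, lab$onset[1], lab$onset[1] + lab$add[1])
band_fractions(welch_psd(seg))
#> <band_fractions>
#>  delta  theta  alpha   beta  gamma    lfb    mfb    hfb
#> 0.4022 0.2095 0.1869 0.1345 0.0670 0.6116 0.1869 0.2015
#> theta/alpha ratio: 1.1207
```

A generalized-stage AD: the low-frequency band still dominates (61 %) but
mid and high frequencies carry a third of the power, as they do in late
kindling stages. `run_study(study_config(seed = 42))` runs the full
19-animal, 252-event study (simulate → detect → measure → test) in a few
seconds and `write_report()` emits the group tables, the statistics bundle
and a run manifest.

## Analysis workflow

The `analysis/` scripts are thin numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R   # group sessions + annotations
Rscript analysis/02_detect.R    # detector performance vs ground truth
Rscript analysis/03_spectra.R   # band-fraction tables per seizure phase
Rscript analysis/04_stats.R     # ANOVAs, theta/alpha, correlations
```

Each writes its tables under `results/`.

## Scope

The package models the statistical structure of kindling EEG, not its
biophysics; detector settings should be re-examined before use on real,
artifact-laden recordings. See the methods vignette
(`vignettes/kindling-eeg-methods.Rmd`) for the generator model, estimator
contracts, numerical choices and known limitations.
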