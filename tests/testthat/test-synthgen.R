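test_that("baseline generator produces the requested record", {
  cfg <- sim_config(seed = 1)
  b <- generate_baseline(cfg)
  expect_length(b$samples, 7000)
  expect_equal(rms(b$samples), cfg$baseline_amplitude, tolerance = 1e-9)

  # zero-amplitude config gives an all-zero trace
  b0 <- generate_baseline(sim_config(baseline_amplitude = 0, seed = 1))
  expect_true(all(b0$samples == 0))

  # identical seed, identical output
  expect_identical(generate_baseline(sim_config(seed = 5))$samples,
                   generate_baseline(sim_config(seed = 5))$samples)
  expect_error(generate_baseline(cfg, duration = 0), "positive")
  expect_error(sim_config(sampling_rate = 50), "80")
})

test_that("baseline spectrum is dominated by the low-frequency band", {
  lfb <- vapply(1:100, function(s) {
    b <- generate_baseline(sim_config(seed = s))
    band_fractions(welch_psd(b))$fraction$lfb
  }, numeric(1))
  expect_gt(mean(lfb), 0.6)
})

test_that("AD segments hit their band-fraction targets in closed loop", {
  cfg <- sim_config()
  # the kindle ISS profile triple and an extreme admissible triple
  cases <- list(c(0.828, 0.082, 0.088) / 0.998, c(0.4, 0.3, 0.3))
  for (tgt in cases) {
    rec <- vapply(1:50, function(s) {
      f <- band_fractions(welch_psd(
        generate_ad_segment(list(fractions = tgt), 8, cfg, seed = s)))
      c(f$fraction$lfb, f$fraction$mfb, f$fraction$hfb)
    }, numeric(3))
    expect_true(all(abs(rowMeans(rec) - tgt) <= 0.03))
  }
})

test_that("a pure-LFB target yields an essentially pure LFB segment", {
  # all LFB power placed in delta (narrowband low-frequency content)
  seg <- generate_ad_segment(list(fractions = c(1, 0, 0)), 8,
                             sim_config(lfb_delta_share = 1), seed = 2)
  f <- band_fractions(welch_psd(seg))
  expect_gte(f$fraction$lfb, 0.99)
})

test_that("AD segment envelope clears the detection floor in every window", {
  cfg <- sim_config()
  for (s in 1:10) {
    seg <- generate_ad_segment(list(fractions = c(0.7, 0.15, 0.15)), 10, cfg,
                               seed = s)
    env <- sliding_rms(seg$samples, cfg$sampling_rate, window = 0.5, hop = 0.1)
    expect_gte(min(env$rms), cfg$ad_envelope_ratio * cfg$baseline_amplitude)
  }
  expect_error(generate_ad_segment(list(fractions = c(0.5, 0.2, 0.2)), 8,
                                   cfg), "summing to 1")
  expect_error(generate_ad_segment(list(fractions = c(1, 0, 0)), 0, cfg),
               "positive")
})

test_that("sessions embed annotated events with exact counts and determinism", {
  cfg <- sim_config(seed = 7)
  prof <- default_group_profiles()$Kindle
  sched <- default_schedule(prof, seed = 7)
  expect_equal(as.vector(table(factor(sched$phase, c("ISS", "LSS", "GSS")))),
               c(61, 42, 35))
  expect_true(all(sched$duration_s >= 6))

  small <- sched[1:4, ]
  s1 <- simulate_session(prof, small, cfg, seed = 7)
  s2 <- simulate_session(prof, small, cfg, seed = 7)
  expect_identical(s1$record$samples, s2$record$samples)
  expect_identical(s1$annotations, s2$annotations)
  expect_equal(nrow(s1$annotations), 4)

  # annotations match the embedded extent: each annotated slice clears the
  # floor, and the record is long enough to contain them all
  for (i in seq_len(4)) {
    seg <- slice_record(s1$record, s1$annotations$onset_s[i],
                        s1$annotations$onset_s[i] + s1$annotations$duration_s[i])
    expect_gte(rms(seg$samples), 2.5 * cfg$baseline_amplitude)
  }

  empty <- simulate_session(prof, sched[0, ], cfg, seed = 7)
  expect_equal(nrow(empty$annotations), 0)
  expect_equal(duration(empty$record), cfg$baseline_duration)

  # overlapping explicit onsets are rejected
  bad <- small
  bad$onset_s <- c(8, 9, 40, 60)
  expect_error(simulate_session(prof, bad, cfg, seed = 7), "overlap")
})

test_that("titration walks the staircase and respects the exclusion cap", {
  # deterministic threshold at 100 uA -> first staircase value >= 100 is 105
  r <- simulate_threshold_titration(response_curve(100), seed = 1)
  expect_equal(r$threshold, 105)
  expect_false(r$excluded)
  expect_equal(r$steps_taken, 6)

  # non-responder excluded after the full staircase
  r2 <- simulate_threshold_titration(response_curve(Inf), seed = 1)
  expect_true(r2$excluded)
  expect_true(is.na(r2$threshold))
  expect_equal(r2$steps_taken, length(seq(30, 350, 15)))

  # responder below the starting intensity triggers at the first step
  expect_equal(simulate_threshold_titration(response_curve(10), seed = 1)$threshold, 30)

  # stochastic curves still land on the staircase grid
  grid <- seq(30, 350, 15)
  for (s in 1:25) {
    r3 <- simulate_threshold_titration(response_curve(90, slope = 20), seed = s)
    if (!r3$excluded) expect_true(r3$threshold %in% grid)
  }
  # response probability is monotone non-decreasing
  cv <- response_curve(90, slope = 20)
  p <- ad_probability(cv, seq(30, 350, 15))
  expect_true(all(diff(p) >= 0))
  expect_error(simulate_threshold_titration(response_curve(100), start = 400),
               "maximum")
})

test_that("profile validation enforces calibration invariants", {
  expect_error(group_profile("X", list(
    ISS = list(fractions = c(0.5, 0.2, 0.2), add_mean = 8, add_sd = 1,
               event_count = 5))), "sum")
  expect_error(group_profile("X", list(
    ISS = list(fractions = c(0.8, 0.1, 0.1), add_mean = 4, add_sd = 1,
               event_count = 5))), ">= 6")
  p <- default_group_profiles()
  for (g in names(p)) {
    for (ph in names(p[[g]]$phases)) {
      expect_equal(sum(p[[g]]$phases[[ph]]$fractions), 1, tolerance = 1e-9)
    }
  }
})
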