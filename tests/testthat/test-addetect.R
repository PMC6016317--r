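test_that("baseline statistics reproduce analytic RMS values", {
  fs <- 1000
  z <- eeg_record(numeric(8 * fs), fs)
  expect_equal(baseline_stats(z)$rms, 0)

  s <- make_tone(5, 8, fs)
  expect_equal(baseline_stats(s, window = 8)$rms, 1 / sqrt(2), tolerance = 1e-3)

  # concatenation invariance: stats of (x ++ x) equal stats of x
  set.seed(2)
  x <- rnorm(4 * fs)
  a <- baseline_stats(eeg_record(x, fs), window = 4)
  b <- baseline_stats(eeg_record(c(x, x), fs), window = 8)
  expect_equal(b$rms, a$rms, tolerance = 1e-12)

  expect_error(baseline_stats(eeg_record(rnorm(100), fs)), "shorter")
})

test_that("the amplitude/duration rule is enforced at its boundaries", {
  # 7 s epoch at 3x baseline: exactly one event of ~7 s
  r <- make_epoch_record(ratio = 3, epoch_dur = 7)
  d <- detect_ad_events(r, baseline_stats(r))
  expect_equal(nrow(d), 1)
  expect_equal(d$duration, 7, tolerance = 0.5)
  expect_equal(d$onset, 10, tolerance = 0.5)

  # 5 s at 3x fails the duration rule
  r5 <- make_epoch_record(ratio = 3, epoch_dur = 5)
  expect_equal(nrow(detect_ad_events(r5, baseline_stats(r5))), 0)

  # 10 s at 2.0x fails the amplitude rule
  r2 <- make_epoch_record(ratio = 2, epoch_dur = 10)
  expect_equal(nrow(detect_ad_events(r2, baseline_stats(r2))), 0)

  expect_error(detect_ad_events(r, baseline_stats(r), ratio = 0), "positive")
  expect_error(detect_ad_events(r, baseline_stats(r), min_duration = -1), "positive")
})

test_that("detection is invariant to common amplitude rescaling", {
  r <- make_epoch_record(ratio = 3, epoch_dur = 8)
  d1 <- detect_ad_events(r, baseline_stats(r))
  rs <- eeg_record(r$samples * 17.3, r$sampling_rate)
  d2 <- detect_ad_events(rs, baseline_stats(rs))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("lowering ratio or min_duration never removes a detected event", {
  cfg <- sim_config(seed = 31)
  prof <- default_group_profiles()$Kindle
  sched <- default_schedule(prof, seed = 31)[1:5, ]
  sess <- simulate_session(prof, sched, cfg, seed = 31)
  bs <- baseline_stats(sess$record)
  d_base <- detect_ad_events(sess$record, bs)
  d_lower_ratio <- detect_ad_events(sess$record, bs, ratio = 2.0)
  d_lower_dur <- detect_ad_events(sess$record, bs, min_duration = 3)
  # every baseline event is covered by an event in the relaxed settings
  covered <- function(d, relaxed) {
    all(vapply(seq_len(nrow(d)), function(i) {
      any(relaxed$onset <= d$onset[i] + d$duration[i] &
          relaxed$onset + relaxed$duration >= d$onset[i])
    }, logical(1)))
  }
  expect_gte(nrow(d_lower_ratio), nrow(d_base))
  expect_gte(nrow(d_lower_dur), nrow(d_base))
  expect_true(covered(d_base, d_lower_ratio))
  expect_true(covered(d_base, d_lower_dur))
})

test_that("generated sessions round-trip through the detector", {
  miss <- 0; errs <- c()
  for (s in 1:5) {
    prof <- default_group_profiles()$Kindle
    sched <- default_schedule(prof, seed = 100 + s)
    sched <- sched[seq(1, nrow(sched), by = 14), ]   # ~10 events per session
    sess <- simulate_session(prof, sched, sim_config(seed = 100 + s),
                             seed = 100 + s)
    rt <- roundtrip_errors(sess)
    miss <- miss + sum(is.na(rt$add_error))
    errs <- c(errs, rt$add_error)
  }
  expect_equal(miss, 0)
  expect_lte(max(abs(errs), na.rm = TRUE), 0.5)

  # mean GSS ADD of a kindle session matches the generator target
  ev <- measure_group_phase("Kindle", "GSS", seed = 77)
  expect_equal(mean(ev$add), 22.28, tolerance = 0.5)
})

test_that("segment labeling matches events to annotations by overlap", {
  ann <- data.frame(
    animal_id = c("a", "a"), group = c("Kindle", "Kindle"), day = 1L,
    onset_s = c(10, 40), duration_s = c(8, 7), racine_stage = c(3L, 5L),
    phase = c("LSS", "GSS")
  )
  ev <- data.frame(onset = c(10, 60), duration = c(8, 6.5))
  lab <- label_segments(ev, ann)
  expect_true(lab$matched[1])
  expect_equal(lab$phase[1], "LSS")
  expect_equal(lab$racine_stage[1], 3L)
  expect_false(lab$matched[2])   # overlaps nothing

  bad <- ann; bad$onset_s <- c(10, 15)
  expect_error(label_segments(ev, bad), "overlap")
  expect_equal(stage_to_phase(c(1, 2, 3, 4, 5)),
               c("ISS", "ISS", "LSS", "GSS", "GSS"))
  expect_error(stage_to_phase(6), "1..5")
})
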