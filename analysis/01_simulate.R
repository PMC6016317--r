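#!/usr/bin/env Rscript
# Step 1: simulate the three experimental groups' kindling sessions.
#
# One session per animal (kindle n=7, LFSK n=6, KLFS n=6), each a continuous
# EEG record: 7 s lead baseline, then the animal's share of the group's
# afterdischarge events (kindle 61 ISS / 42 LSS / 35 GSS; LFSK 38/13/4;
# KLFS 39/14/6) separated by 5 s baseline gaps. Band-fraction targets come
# from the group calibration tables; durations from truncated normals at the
# group means. Writes the event annotations and a short signal excerpt.

suppressMessages(library(kindleeg))

SEED <- 42
out <- "results"
dir.create(out, showWarnings = FALSE)

set.seed(SEED)
profiles <- default_group_profiles()
all_ann <- list()
for (g in names(profiles)) {
  prof <- profiles[[g]]
  sched <- default_schedule(prof, seed = NULL)
  for (ph in unique(sched$phase)) {
    prof$phases[[ph]] <- calibrate_profile_entry(prof$phases[[ph]], sim_config())
  }
  for (aid in unique(sched$animal_id)) {
    sess <- simulate_session(prof, sched[sched$animal_id == aid, ],
                             sim_config(), seed = NULL, calibrate = FALSE)
    all_ann[[length(all_ann) + 1L]] <- sess$annotations
    if (g == "Kindle" && aid == sched$animal_id[1]) {
      # illustrative excerpt around the first event (baseline into
      # afterdischarge), decimated to 250 Hz and rounded to keep it small
      ex <- slice_record(sess$record, 0, 15)
      dec <- eeg_record(round(ex$samples[seq(1, length(ex$samples), by = 4)], 1),
                        ex$sampling_rate / 4, label = "excerpt_250Hz")
      write_signal_csv(dec, file.path(out, "example_signal_excerpt.csv"))
    }
  }
  cat(sprintf("%s: %d events over %d animals (phases: %s)\n", g, nrow(sched),
              prof$n_animals,
              paste(names(table(sched$phase)), table(sched$phase),
                    sep = "=", collapse = ", ")))
}
ann <- do.call(rbind, all_ann)
write_events_tsv(ann, file.path(out, "annotations.tsv"))
cat(sprintf("wrote %d annotations to %s (seed %d)\n", nrow(ann),
            file.path(out, "annotations.tsv"), SEED))
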