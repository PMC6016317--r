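#' Study configuration
#'
#' Bundles everything [run_study()] needs: the simulator configuration, the
#' per-group calibration profiles, detector settings and the aggregation
#' level for group tables.
#'
#' @param seed Integer seed controlling every random draw of the study.
#' @param sim A [sim_config()].
#' @param profiles Named list of [group_profile()]s
#'   (default [default_group_profiles()]).
#' @param ratio Detector amplitude threshold (default 2.5 x baseline RMS).
#' @param min_duration Detector minimum AD duration, s (default 6).
#' @param aggregate Aggregation level for group fraction tables: "event"
#'   (default; one row per AD event) or "animal" (per-animal means). The
#'   level feeding the group statistics is a genuine analysis choice; the
#'   default is per-event.
#' @param gss_min_events Minimum events per group for GSS inferential
#'   statistics; below it GSS is summarized descriptively only (default 3).
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1, sim = sim_config(),
                         profiles = default_group_profiles(),
                         ratio = 2.5, min_duration = 6,
                         aggregate = c("event", "animal"),
                         gss_min_events = 3) {
  aggregate <- match.arg(aggregate)
  structure(list(seed = seed, sim = sim, profiles = profiles, ratio = ratio,
                 min_duration = min_duration, aggregate = aggregate,
                 gss_min_events = gss_min_events),
            class = "study_config")
}

stat_to_list <- function(s) {
  if (is.null(s)) return(NULL)
  if (!inherits(s, "stat_result")) return(s)
  list(test = s$test_name, statistic = s$statistic, df = s$df,
       p_value = s$p_value, note = s$note)
}

measure_segments <- function(record, segments, welch_length = 2) {
  rows <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    seg <- slice_record(record, segments$onset[i],
                        segments$onset[i] + segments$add[i])
    psd <- welch_psd(seg, segment_length = welch_length)
    bf <- band_fractions(psd)
    rows[[i]] <- data.frame(
      animal_id = segments$animal_id[i], group = segments$group[i],
      phase = segments$phase[i], racine_stage = segments$racine_stage[i],
      onset = segments$onset[i], add = segments$add[i],
      delta = bf$fraction$delta, theta = bf$fraction$theta,
      alpha = bf$fraction$alpha, beta = bf$fraction$beta,
      gamma = bf$fraction$gamma,
      lfb = bf$fraction$lfb, mfb = bf$fraction$mfb, hfb = bf$fraction$hfb,
      lfb_power = bf$power$lfb, mfb_power = bf$power$mfb,
      hfb_power = bf$power$hfb,
      theta_alpha = bf$theta_alpha_ratio,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

summarize_phase <- function(events, phase, bands = c("lfb", "mfb", "hfb")) {
  ev <- events[events$phase == phase, , drop = FALSE]
  if (!nrow(ev)) return(NULL)
  out <- list()
  for (g in unique(ev$group)) {
    sub <- ev[ev$group == g, , drop = FALSE]
    for (b in bands) {
      out[[length(out) + 1L]] <- data.frame(
        phase = phase, group = g, band = toupper(b), n_events = nrow(sub),
        mean = mean(sub[[b]]), sd = stats::sd(sub[[b]]),
        add_mean = mean(sub$add), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Run the full simulate--detect--measure--test study
#'
#' End-to-end driver: simulates one kindling session per animal for every
#' group, estimates each animal's baseline statistics from its leading 7 s
#' baseline, detects afterdischarges with the 2.5x / >= 6 s rule, matches
#' them to the stage annotations, measures band fractions of every AD
#' segment, and computes the study's statistical layer: baseline group
#' comparison, per-phase LFB/MFB/HFB group tables with one-way ANOVAs and
#' Bonferroni post hocs, per-sub-band two-way (group x phase) ANOVAs,
#' theta/alpha comparison, and ADD--band-power Pearson correlations for the
#' kindle group and the pooled LFS-treated (LFSK + KLFS) group. Fully
#' deterministic for a fixed seed.
#'
#' GSS inferential statistics are computed only when every group carries at
#' least `gss_min_events` events; otherwise the phase is summarized
#' descriptively (small, imbalanced GSS samples make the tests unreliable).
#'
#' @param config A [study_config()].
#' @param verbose Print one progress line per stage (default FALSE).
#' @return A `study_report` list: `events`, `baseline`, `tables` (per phase),
#'   `baseline_anova`, `phase_anova`, `posthoc`, `twoway`, `theta_alpha`,
#'   `correlations`, `add_summary`, `counts`, `misses`, `seed`.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  sim <- config$sim
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  all_events <- list()
  baseline_rows <- list()
  misses <- list()
  counts <- list()

  for (gname in names(config$profiles)) {
    profile <- config$profiles[[gname]]
    sched <- default_schedule(profile, seed = NULL)
    counts[[gname]] <- table(factor(sched$phase, levels = c("ISS", "LSS", "GSS")))
    # closed-loop band calibration once per group, shared by its animals
    for (ph in unique(sched$phase)) {
      profile$phases[[ph]] <- calibrate_profile_entry(profile$phases[[ph]], sim)
    }
    for (aid in unique(sched$animal_id)) {
      sub <- sched[sched$animal_id == aid, , drop = FALSE]
      sess <- simulate_session(profile, sub, sim, seed = NULL, calibrate = FALSE)
      bs <- baseline_stats(sess$record, window = sim$baseline_duration)
      det <- detect_ad_events(sess$record, bs, ratio = config$ratio,
                              min_duration = config$min_duration)
      lab <- label_segments(det, sess$annotations)
      matched <- lab[lab$matched, , drop = FALSE]
      # detector misses: annotated events with no matched detection
      n_miss <- nrow(sess$annotations) - nrow(matched)
      if (n_miss > 0) {
        misses[[length(misses) + 1L]] <- data.frame(
          animal_id = aid, group = gname, n_missed = n_miss,
          stringsAsFactors = FALSE)
      }
      if (nrow(matched)) {
        all_events[[length(all_events) + 1L]] <-
          measure_segments(sess$record, matched)
      }
      # baseline spectral profile of this animal
      bl <- slice_record(sess$record, 0, sim$baseline_duration)
      bf <- band_fractions(welch_psd(bl))
      baseline_rows[[length(baseline_rows) + 1L]] <- data.frame(
        animal_id = aid, group = gname,
        lfb = bf$fraction$lfb, mfb = bf$fraction$mfb, hfb = bf$fraction$hfb,
        stringsAsFactors = FALSE
      )
    }
    say("group %s: simulated, detected, measured", gname)
  }

  events <- do.call(rbind, all_events)
  baseline <- do.call(rbind, baseline_rows)
  rownames(events) <- rownames(baseline) <- NULL
  groups <- names(config$profiles)

  agg_events <- function(ev) {
    if (config$aggregate == "event") return(ev)
    sp <- split(ev, interaction(ev$animal_id, ev$phase, drop = TRUE))
    do.call(rbind, lapply(sp, function(d) {
      num <- vapply(d[, sapply(d, is.numeric), drop = FALSE], mean, numeric(1))
      cbind(d[1, c("animal_id", "group", "phase"), drop = FALSE],
            as.data.frame(as.list(num)))
    }))
  }
  ev_agg <- agg_events(events)

  # baseline comparison across groups (one-way ANOVA per aggregate band)
  baseline_anova <- lapply(c(lfb = "lfb", mfb = "mfb", hfb = "hfb"), function(b) {
    one_way_anova(split(baseline[[b]], factor(baseline$group, levels = groups)))
  })

  # per-phase group tables and one-way ANOVAs
  tables <- list(); phase_anova <- list(); posthoc <- list()
  for (ph in c("ISS", "LSS", "GSS")) {
    tables[[ph]] <- summarize_phase(events, ph)
    sub <- ev_agg[ev_agg$phase == ph, , drop = FALSE]
    cell_n <- table(factor(sub$group, levels = groups))
    enough <- all(cell_n >= 2) &&
      (ph != "GSS" || all(cell_n >= config$gss_min_events))
    if (nrow(sub) && enough) {
      phase_anova[[ph]] <- lapply(c(lfb = "lfb", mfb = "mfb", hfb = "hfb"),
        function(b) one_way_anova(split(sub[[b]], factor(sub$group, levels = groups))))
      posthoc[[ph]] <- lapply(c(lfb = "lfb", mfb = "mfb", hfb = "hfb"),
        function(b) bonferroni_pairwise(split(sub[[b]], factor(sub$group, levels = groups))))
    } else {
      phase_anova[[ph]] <- NULL
      say("phase %s: statistics skipped (insufficient events per group)", ph)
    }
  }

  # two-way group x phase ANOVA per sub-band fraction and theta/alpha ratio
  twoway <- lapply(
    c(delta = "delta", theta = "theta", alpha = "alpha", beta = "beta",
      gamma = "gamma", theta_alpha = "theta_alpha"),
    function(b) two_way_anova(ev_agg[[b]], ev_agg$group, ev_agg$phase)
  )

  theta_alpha <- do.call(rbind, lapply(groups, function(g) {
    v <- ev_agg$theta_alpha[ev_agg$group == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  }))
  theta_alpha_anova <- one_way_anova(
    split(ev_agg$theta_alpha, factor(ev_agg$group, levels = groups)))
  theta_alpha_posthoc <- bonferroni_pairwise(
    split(ev_agg$theta_alpha, factor(ev_agg$group, levels = groups)))

  # ADD vs band-power correlations: kindle alone, LFSK+KLFS pooled
  corr_for <- function(ev) {
    out <- list()
    for (ph in c("ISS", "LSS", "GSS")) {
      sub <- ev[ev$phase == ph, , drop = FALSE]
      for (b in c("lfb_power", "mfb_power", "hfb_power")) {
        ok <- nrow(sub) >= 3 && stats::sd(sub$add) > 0 && stats::sd(sub[[b]]) > 0
        r <- if (ok) pearson_r(sub$add, sub[[b]]) else NULL
        out[[length(out) + 1L]] <- data.frame(
          phase = ph, band = toupper(sub("_power", "", b)),
          n = nrow(sub),
          r = if (ok) r$r else NA_real_,
          p_value = if (ok) r$p_value else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  }
  correlations <- list(
    Kindle = corr_for(events[events$group == "Kindle", , drop = FALSE]),
    LFS_treated = corr_for(events[events$group %in% c("LFSK", "KLFS"), , drop = FALSE])
  )

  add_summary <- do.call(rbind, lapply(split(events, list(events$group, events$phase), drop = TRUE),
    function(d) data.frame(group = d$group[1], phase = d$phase[1],
                           n = nrow(d), add_mean = mean(d$add),
                           add_sd = stats::sd(d$add), stringsAsFactors = FALSE)))
  rownames(add_summary) <- NULL
  add_summary <- add_summary[order(add_summary$group, add_summary$phase), ]

  structure(
    list(events = events, baseline = baseline, tables = tables,
         baseline_anova = baseline_anova, phase_anova = phase_anova,
         posthoc = posthoc, twoway = twoway,
         theta_alpha = theta_alpha, theta_alpha_anova = theta_alpha_anova,
         theta_alpha_posthoc = theta_alpha_posthoc,
         correlations = correlations, add_summary = add_summary,
         counts = counts,
         misses = if (length(misses)) do.call(rbind, misses) else
           data.frame(animal_id = character(0), group = character(0),
                      n_missed = integer(0)),
         seed = config$seed, aggregate = config$aggregate),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d: %d AD events over %d animals, %d detector misses\n",
              x$seed, nrow(x$events), nrow(x$baseline), sum(x$misses$n_missed)))
  for (g in names(x$counts)) {
    cat(sprintf("  %s schedule: %s\n", g,
                paste(sprintf("%s=%d", names(x$counts[[g]]), x$counts[[g]]), collapse = ", ")))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits one TSV per table (events, baseline profiles, per-phase fraction
#' tables, ADD summary, correlations, theta/alpha summary), a JSON bundle of
#' every test statistic, and a run manifest (seed, aggregation level, event
#' counts, package version).
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$events, "events.tsv")
  wr(report$baseline, "baseline_profiles.tsv")
  for (ph in names(report$tables)) {
    if (!is.null(report$tables[[ph]])) {
      wr(report$tables[[ph]], sprintf("fractions_%s.tsv", tolower(ph)))
    }
  }
  wr(report$add_summary, "add_summary.tsv")
  wr(report$theta_alpha, "theta_alpha.tsv")
  for (g in names(report$correlations)) {
    wr(report$correlations[[g]], sprintf("correlations_%s.tsv", tolower(g)))
  }
  stats_bundle <- list(
    baseline_anova = lapply(report$baseline_anova, stat_to_list),
    phase_anova = lapply(report$phase_anova, function(ph) lapply(ph, stat_to_list)),
    twoway = lapply(report$twoway, function(b) lapply(b, stat_to_list)),
    theta_alpha_anova = stat_to_list(report$theta_alpha_anova)
  )
  p <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats_bundle, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, p)
  manifest <- list(
    seed = report$seed,
    aggregate = report$aggregate,
    n_events = nrow(report$events),
    n_animals = nrow(report$baseline),
    schedule_counts = lapply(report$counts, function(x) as.list(stats::setNames(as.integer(x), names(x)))),
    detector_misses = sum(report$misses$n_missed),
    package_version = as.character(utils::packageVersion("kindleeg"))
  )
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
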