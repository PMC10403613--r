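## ---------------------------------------------------------------------------
## End-to-end pipeline: simulate -> preprocess -> timecourse -> rings ->
## decay -> yfp -> stats, with a config snapshot and log next to the outputs.
## ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' A fully serializable nested list describing one pipeline run over
#' synthetic sessions: per-condition session counts, trial counts, the opto
#' pulse durations, acquisition geometry, ROI radius, ring/decay/bleach
#' parameters, the YFP simulation settings, the statistics windows, an
#' explicit session-exclusion list (for outlier sessions), and the master
#' seed from which per-session seeds are derived deterministically.
#'
#' @param out_dir output directory of the run.
#' @param seed master integer seed.
#' @param n_sessions named per-condition session counts.
#' @param n_trials,n_blank_trials per-session trial counts.
#' @param opto_pulses_ms pulse durations (ms) of the optostimulation
#'   conditions.
#' @return A config list for [runPipeline()].
#' @export
defaultPipelineConfig <- function(out_dir = file.path(tempdir(), "vsdpop_run"),
                                  seed = 1,
                                  n_sessions = list(short_exp = 2L,
                                                    long_exp = 2L,
                                                    icms = 2L),
                                  n_trials = 6L, n_blank_trials = 4L,
                                  opto_pulses_ms = c(2, 5, 10)) {
  list(
    out_dir = out_dir, seed = as.integer(seed),
    n_sessions = n_sessions,
    n_trials = as.integer(n_trials),
    n_blank_trials = as.integer(n_blank_trials),
    opto_pulses_ms = opto_pulses_ms,
    acq = slotsToList(AcquisitionSpec()),
    roi_radius_px = 5,
    smooth_px = 3L,
    ring = list(step_um = 50, max_radius_um = 2000),
    sum_window = list(t_from_ms = 20, t_to_ms = 100, r_to_um = 2000),
    decay_thresholds = c(0.7, 0.3),
    bleach = list(search_radius_um = 500, neg_threshold = -2e-3,
                  window_ms = c(10, 40)),
    slow_window_ms = c(60, 100),
    yfp = list(n_perm = 10000L, level = 0.6, background_sd = 0.02,
               extent_um = list(short_exp = 600, long_exp = 850)),
    exclude_sessions = character(0)
  )
}

pipelineSessionSeed <- function(seed, i) (seed * 131L + i * 7919L) %% 2147483647L

#' Run the full analysis pipeline on synthetic sessions
#'
#' Executes every stage in order on generator data: session simulation,
#' preprocessing (frame-zero division, blank subtraction, trial averaging,
#' artifact-frame and bleach-pixel masking, with every masking decision
#' logged), peak-ROI time courses with within-session normalization to the
#' 10 ms condition, grand averages, ring space-time analysis (raw and
#' center-normalized summed activation), decay-time maps at the 70% and 30%
#' thresholds with central/distal distributions, YFP expression-area counts
#' with the label-shuffle control, and the nonparametric group comparisons
#' (Bonferroni over the pairwise panel) plus the ICMS first-vs-last-trial
#' integrity check.  A config snapshot (`config.yaml`), a log (`log.txt`) and
#' all result tables (CSV) are written into `config$out_dir`; reruns with the
#' same config give byte-identical CSVs.
#'
#' @param config a config list from [defaultPipelineConfig()], or the path of
#'   a YAML file holding one.
#' @return Invisibly, a list with the per-session objects and all summary
#'   tables.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out, "config.yaml"))
  log_lines <- character(0)
  logit <- function(...) log_lines <<- c(log_lines, sprintf(...))

  acq <- acqFromList(config$acq)
  conds <- names(config$n_sessions)
  logit("pipeline start: conditions [%s], seed %d",
        paste(conds, collapse = ", "), config$seed)

  ## ---- simulate + preprocess -------------------------------------------
  sessions <- list()   # one entry per (condition, session): list of movies
  seed_i <- 0L
  for (cond in conds) {
    for (s in seq_len(config$n_sessions[[cond]])) {
      sid <- sprintf("%s_s%02d", cond, s)
      pulses <- if (cond == "icms") 20 else config$opto_pulses_ms
      movies <- list()
      truths <- list()
      for (p in pulses) {
        seed_i <- seed_i + 1L
        preset <- vsdPreset(cond, pulse_ms = p)
        lab <- if (cond == "icms") "icms" else sprintf("%gms", p)
        sim <- simulateSession(acq, preset$stim, preset$resp, preset$art,
                               config$n_trials, config$n_blank_trials,
                               seed = pipelineSessionSeed(config$seed, seed_i),
                               session_id = sid, condition = lab)
        if (is.null(sim$blank))
          stop(sprintf("preprocess: missing blank trials for session %s", sid))
        mv <- preprocessSession(
          sim$stimulated, sim$blank,
          search_radius_um = config$bleach$search_radius_um,
          neg_threshold = config$bleach$neg_threshold,
          window_ms = config$bleach$window_ms)
        logit("preprocess %s/%s: %d frame(s) masked, %d pixel(s) masked",
              sid, lab, sum(!validFrames(mv)), sum(!validPixels(mv)))
        movies[[lab]] <- mv
        truths[[lab]] <- sim$truth
      }
      sessions[[sid]] <- list(condition = cond, session_id = sid,
                              movies = movies, truths = truths)
    }
  }

  ## ---- time courses -----------------------------------------------------
  all_tcs <- list(); norm_tcs <- list(); peak_vals <- list()
  for (sid in names(sessions)) {
    ses <- sessions[[sid]]
    tcs <- lapply(ses$movies, function(mv) {
      ctr <- findPeakCenter(mv, smooth_px = config$smooth_px)
      extractTimeCourse(mv, ctr, radius_px = config$roi_radius_px)
    })
    all_tcs[[sid]] <- tcs
    ref <- if (ses$condition == "icms") "icms" else "10ms"
    peak_vals[[sid]] <- vapply(tcs, tcValueAt, numeric(1), t_ms = 20)
    if (ses$condition != "icms")
      norm_tcs[[sid]] <- normalizeTo10ms(tcs, ref_condition = "10ms")
  }

  ## grand averages per condition x pulse label
  grand <- list()
  for (cond in conds) {
    sids <- names(sessions)[vapply(sessions, function(s)
      s$condition == cond, logical(1))]
    labs <- names(all_tcs[[sids[1]]])
    for (lab in labs) {
      key <- paste(cond, lab, sep = ":")
      grand[[paste0(key, ":raw")]] <-
        grandAverage(lapply(sids, function(sid) all_tcs[[sid]][[lab]]))
      if (cond != "icms")
        grand[[paste0(key, ":norm")]] <-
          grandAverage(lapply(sids, function(sid) norm_tcs[[sid]][[lab]]))
    }
  }

  ## ---- ring space-time analysis ----------------------------------------
  summed <- data.frame()
  ring_sets <- list()
  for (sid in names(sessions)) {
    ses <- sessions[[sid]]
    lab <- if (ses$condition == "icms") "icms" else "10ms"
    mv <- ses$movies[[lab]]
    ctr <- findPeakCenter(mv, smooth_px = config$smooth_px)
    rs <- buildRings(ctr, acq, step_um = config$ring$step_um,
                     max_radius_um = config$ring$max_radius_um)
    ring_sets[[sid]] <- rs
    stm <- spaceTimeMap(mv, rs)
    stm_n <- normalizeToCenter(stm)
    sw <- config$sum_window
    summed <- rbind(summed, data.frame(
      session_id = sid, condition = ses$condition,
      summed_activation_raw = summedActivation(
        stm, sw$t_from_ms, sw$t_to_ms, sw$r_to_um),
      summed_activation_norm = summedActivation(
        stm_n, sw$t_from_ms, sw$t_to_ms, sw$r_to_um),
      stringsAsFactors = FALSE))
    writeSpaceTimeMap(stm, file.path(out, sprintf("spacetime_%s.csv", sid)))
    sessions[[sid]]$spacetime <- stm
    sessions[[sid]]$spacetime_norm <- stm_n
  }

  ## ---- decay maps -------------------------------------------------------
  decay_summ <- data.frame()
  for (cond in conds) {
    sids <- setdiff(
      names(sessions)[vapply(sessions, function(s) s$condition == cond,
                             logical(1))],
      config$exclude_sessions)
    if (length(sids) == 0L) next
    lab <- if (cond == "icms") "icms" else "10ms"
    for (thr in config$decay_thresholds) {
      maps <- lapply(sids, function(sid)
        decayTimeMap(sessions[[sid]]$movies[[lab]], thr))
      dd <- decayDistributions(maps, ring_sets[sids])
      dd$summary$condition <- cond
      dd$summary$threshold <- thr
      decay_summ <- rbind(decay_summ, dd$summary)
    }
  }

  ## ---- YFP expression ---------------------------------------------------
  yfp_counts <- data.frame()
  yfp_groups <- intersect(c("short_exp", "long_exp"), conds)
  seed_y <- 0L
  for (cond in yfp_groups) {
    for (s in seq_len(config$n_sessions[[cond]])) {
      seed_y <- seed_y + 1L
      img <- simulateYfpImage(
        acq, center_px = c(50, 50),
        extent_um = config$yfp$extent_um[[cond]],
        level = config$yfp$level,
        background_sd = config$yfp$background_sd,
        seed = pipelineSessionSeed(config$seed + 1L, seed_y),
        animal = sprintf("%s_a%02d", cond, s), group = cond)
      cnt <- countExpressingPixels(normalizeYfp(img))
      yfp_counts <- rbind(yfp_counts, data.frame(
        animal = img@animal, group = cond, count = cnt,
        stringsAsFactors = FALSE))
    }
  }
  yfp_shuffle <- NULL
  if (length(yfp_groups) == 2L && all(table(yfp_counts$group) >= 2)) {
    yfp_shuffle <- groupDifferenceShuffle(
      yfp_counts$count,
      factor(yfp_counts$group, levels = c("short_exp", "long_exp")),
      n_perm = config$yfp$n_perm, seed = config$seed)
    logit("yfp shuffle: observed %.1f, shuffled %.1f +/- %.1f (z = %.2f)",
          yfp_shuffle$observed, yfp_shuffle$shuffled_mean,
          yfp_shuffle$shuffled_sd, yfp_shuffle$z)
  }

  ## ---- statistics -------------------------------------------------------
  peak_by_cond <- lapply(conds, function(cond) {
    sids <- names(sessions)[vapply(sessions, function(s)
      s$condition == cond, logical(1))]
    lab <- if (cond == "icms") "icms" else "10ms"
    vapply(sids, function(sid) peak_vals[[sid]][[lab]], numeric(1))
  })
  names(peak_by_cond) <- conds
  comparisons <- data.frame()
  if (length(conds) >= 2L) {
    prs <- utils::combn(conds, 2, simplify = FALSE)
    rows <- lapply(prs, function(pr)
      rankSumTest(peak_by_cond[[pr[1]]], peak_by_cond[[pr[2]]],
                  label = sprintf("peak:%s_vs_%s", pr[1], pr[2])))
    comparisons <- adjustBonferroni(do.call(rbind, rows),
                                    n_comparisons = length(rows))
  }
  if ("icms" %in% conds && config$n_sessions$icms >= 2L) {
    icms_sids <- names(sessions)[vapply(sessions, function(s)
      s$condition == "icms", logical(1))]
    mats <- lapply(icms_sids, function(sid) {
      mv <- sessions[[sid]]$movies[["icms"]]
      ctr <- findPeakCenter(mv, smooth_px = config$smooth_px)
      trialMeans(mv, circleROI(mv, ctr, config$roi_radius_px))
    })
    flc <- firstLastTrialCheck(mats, frameTimes(acq),
                               slow_window_ms = config$slow_window_ms)
    comparisons <- rbind(comparisons, flc)
  }

  ## ---- write tables -----------------------------------------------------
  writeTimeCourses(unlist(all_tcs, recursive = FALSE),
                   file.path(out, "timecourses.csv"))
  ga_df <- do.call(rbind, lapply(names(grand), function(k) {
    g <- grand[[k]]; g$key <- k; g
  }))
  utils::write.csv(ga_df, file.path(out, "grand_average.csv"),
                   row.names = FALSE)
  utils::write.csv(summed, file.path(out, "summed_activation.csv"),
                   row.names = FALSE)
  utils::write.csv(decay_summ, file.path(out, "decay_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(yfp_counts, file.path(out, "yfp_counts.csv"),
                   row.names = FALSE)
  if (!is.null(yfp_shuffle))
    utils::write.csv(
      data.frame(observed = yfp_shuffle$observed,
                 shuffled_mean = yfp_shuffle$shuffled_mean,
                 shuffled_sd = yfp_shuffle$shuffled_sd,
                 z = yfp_shuffle$z, n_perm = yfp_shuffle$n_perm_used),
      file.path(out, "yfp_shuffle.csv"), row.names = FALSE)
  if (nrow(comparisons))
    utils::write.csv(comparisons, file.path(out, "comparisons.csv"),
                     row.names = FALSE)
  writeLines(log_lines, file.path(out, "log.txt"))

  invisible(list(sessions = sessions, grand = grand, summed = summed,
                 decay = decay_summ, yfp_counts = yfp_counts,
                 yfp_shuffle = yfp_shuffle, comparisons = comparisons,
                 peak_by_condition = peak_by_cond, out_dir = out))
}
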