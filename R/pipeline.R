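#' Process one trial: filter, detect events, trim, segment, normalize
#'
#' Runs the per-trial stages in order: optional zero-lag low-pass filtering
#' of all landmark and angle series, coordinate-based event detection,
#' foot-strike classification at the kept initial contacts, the
#' condition-specific trimming rule, cycle segmentation and 101-point time
#' normalization per side, duration QC flagging, and spatiotemporal
#' parameters over the kept window.
#'
#' @param recording a `trial_recording`.
#' @param config a [run_config()].
#' @return list with `cycles` (list of `normalized_cycle`), `st` (named
#'   numeric cadence/velocity/step_length), `events`, `foot_strikes`,
#'   `qc` (cycle table with flags), `discarded` (segmentation log).
#' @export
process_trial <- function(recording, config = run_config()) {
  fs <- recording$meta$fs
  rec <- recording
  if (!is.null(config$filter_cutoff)) {
    num_cols <- setdiff(names(rec$frames), "time_s")
    rec$frames[num_cols] <- lapply(rec$frames[num_cols], lowpass,
                                   fs = fs, cutoff = config$filter_cutoff)
  }
  events <- detect_events(rec,
                          min_prominence_frac = config$min_prominence_frac,
                          min_interval_s = config$min_interval_s)
  trim <- trim_cycles(events, rec$meta$condition)
  kept_ics <- trim$steps[trim$kept_steps, ]
  foot_strikes <- vapply(seq_len(nrow(kept_ics)), function(i)
    classify_foot_strike(rec, kept_ics$side[i], kept_ics$frame[i]),
    character(1))
  st <- spatiotemporal(rec, events, kept_steps = trim$kept_steps)
  qc <- qc_flag_cycles(trim$cycles, k = config$qc_sd_threshold)
  cycles <- list()
  discarded <- character(0)
  for (s in c("left", "right")) {
    ang <- as.matrix(rec$frames[, paste0(s, "_", c("hip", "knee", "ankle"),
                                         "_sagittal_deg")])
    colnames(ang) <- c("hip", "knee", "ankle")
    keep <- qc[!qc$flagged, c("side", "start_frame", "end_frame")]
    raw <- segment_cycles(ang, events, side = s, fs = fs, cycles = keep)
    discarded <- c(discarded, attr(raw, "discarded"))
    cycles <- c(cycles, lapply(raw, time_normalize))
  }
  list(cycles = cycles, st = st, events = events,
       foot_strikes = foot_strikes, qc = qc, discarded = discarded)
}

#' Representative features per participant and condition
#'
#' Processes every trial of a cohort, averages normalized cycles into one
#' representative waveform per participant x condition (cycles within trial
#' and side, then limbs, then trials), extracts the twelve joint-angle
#' parameters from the representative waveform, and averages the
#' spatiotemporal parameters across trials.
#'
#' @param cohort a `gait_cohort` (or any list with a `trials` element of
#'   `trial_recording`s carrying participant/group/condition metadata).
#' @param config a [run_config()].
#' @return list with `features` (tidy data.frame: participant, group,
#'   condition, cadence, velocity, step_length and the 12 parameters),
#'   `waveforms` (named list of `representative_waveform`), `log`
#'   (per-trial notes), `foot_strikes` (table of classifications).
#' @export
participant_features <- function(cohort, config = run_config()) {
  trials <- cohort$trials
  meta <- do.call(rbind, lapply(names(trials), function(k) {
    m <- trials[[k]]$meta
    data.frame(key = k, participant = m$participant, group = m$group,
               condition = m$condition, trial = m$trial)
  }))
  rows <- list(); waveforms <- list(); log <- list(); fstab <- character(0)
  for (pid in unique(meta$participant)) {
    for (cd in unique(meta$condition[meta$participant == pid])) {
      sel <- meta[meta$participant == pid & meta$condition == cd, ]
      cycles <- list(); sts <- list()
      for (i in seq_len(nrow(sel))) {
        pt <- process_trial(trials[[sel$key[i]]], config)
        cyc <- lapply(pt$cycles, function(cy) { cy$trial <- sel$trial[i]; cy })
        cycles <- c(cycles, cyc)
        sts[[i]] <- pt$st
        fstab <- c(fstab, pt$foot_strikes)
        if (length(pt$discarded))
          log[[paste(pid, cd, sel$trial[i])]] <- pt$discarded
      }
      rw <- average_waveforms(cycles)
      waveforms[[paste(pid, cd, sep = "_")]] <- rw
      part <- partition_phases(rw$to_percent,
                               mid_stance = config$mid_stance_percent)
      feats <- extract_features(rw$mean, part)
      st <- colMeans(do.call(rbind, sts))
      grp <- sel$group[1]
      rows[[length(rows) + 1]] <- cbind(
        data.frame(participant = pid, group = grp, condition = cd),
        as.data.frame(as.list(c(st, feats))))
    }
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  list(features = features, waveforms = waveforms, log = log,
       foot_strikes = table(fstab))
}

#' Run the full analysis pipeline
#'
#' Stages in order: filtering, event detection, trimming, segmentation,
#' normalization, hierarchical averaging, feature extraction, then the two
#' statistical tiers — pooled-variance t tests with per-parameter FDR and
#' Cohen's d on the spatiotemporal parameters, and velocity-adjusted LMMs
#' with type-III tests, EMM contrasts, pooled FDR and residual-SD effect
#' sizes on the joint-angle parameters (run when at least two conditions
#' are present). Deterministic given the input and configuration.
#'
#' @param input a `gait_cohort` or a directory of trial files.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, features, t-test
#'   and LMM tables are written as CSV and a results JSON embedding the
#'   full configuration is produced.
#' @return results bundle: list with `features`, `waveforms`, `ttests`,
#'   `lmm` (list: anova, contrasts, fits), `foot_strikes`, `log`, `config`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  cohort <- if (is.character(input)) read_cohort(input) else input
  stopifnot(inherits(cohort, "gait_cohort"))
  pf <- participant_features(cohort, config)
  features <- pf$features
  ttests <- ttest_battery(features, var_equal = config$var_equal,
                          fdr_family = config$fdr_family_spatiotemporal)
  lmm <- NULL
  if (length(unique(features$condition)) >= 2) {
    lmm <- lmm_battery(features,
                       gate_on_interaction = config$gate_on_interaction)
  } else message("single condition: LMM tier skipped")
  res <- list(features = features, waveforms = pf$waveforms, ttests = ttests,
              lmm = lmm, foot_strikes = pf$foot_strikes, log = pf$log,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(ttests, file.path(out_dir, "ttests.csv"),
                     row.names = FALSE)
    if (!is.null(lmm)) {
      utils::write.csv(lmm$anova, file.path(out_dir, "lmm_anova.csv"),
                       row.names = FALSE)
      utils::write.csv(lmm$contrasts, file.path(out_dir, "lmm_contrasts.csv"),
                       row.names = FALSE)
    }
    prov <- list(config = unclass(config),
                 package_version = as.character(utils::packageVersion("rampgait")),
                 foot_strikes = as.list(pf$foot_strikes),
                 log = pf$log)
    jsonlite::write_json(prov, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

#' Plot a representative waveform with its SD band
#'
#' Mean waveform per joint with a +/-1 SD ribbon across trial-level
#' waveforms (the band reflects between-trial variability within the
#' participant, matching the averaging hierarchy).
#'
#' @param rw a `representative_waveform`.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_representative_waveform <- function(rw) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  joints <- colnames(rw$mean)
  df <- do.call(rbind, lapply(joints, function(j)
    data.frame(joint = j, pct = 0:100, value = rw$mean[, j],
               lo = rw$mean[, j] - rw$sd[, j],
               hi = rw$mean[, j] + rw$sd[, j])))
  ggplot2::ggplot(df, ggplot2::aes(x = pct, y = value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = rw$to_percent, linetype = "dashed") +
    ggplot2::facet_wrap(~joint, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Gait cycle (%)", y = "Angle (deg)")
}
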