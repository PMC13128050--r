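#' Pipeline run configuration
#'
#' All tunable settings of the analysis pipeline, serialized into every
#' results file for provenance.
#'
#' @param filter_cutoff low-pass cutoff in Hz, or NULL to skip filtering
#'   (e.g. for noiseless synthetic cohorts, which are already band-limited).
#' @param min_prominence_frac,min_interval_s event-detector settings
#'   (see [detect_events()]).
#' @param mid_stance_percent fixed mid-stance location in % cycle, or NULL
#'   for the default temporal-midpoint-of-stance rule.
#' @param qc_sd_threshold cycle-duration QC threshold in SD units.
#' @param var_equal pooled-variance t tests (TRUE) or Welch (FALSE).
#' @param fdr_family_spatiotemporal `"per_parameter"` or `"global"`.
#' @param gate_on_interaction gate LMM simple effects on the interaction.
#' @param seed integer seed recorded for provenance.
#' @return list of class `run_config`.
#' @export
run_config <- function(filter_cutoff = 6,
                       min_prominence_frac = 0.2,
                       min_interval_s = 0.3,
                       mid_stance_percent = NULL,
                       qc_sd_threshold = 3,
                       var_equal = TRUE,
                       fdr_family_spatiotemporal = "per_parameter",
                       gate_on_interaction = TRUE,
                       seed = 1L) {
  structure(list(filter_cutoff = filter_cutoff,
                 min_prominence_frac = min_prominence_frac,
                 min_interval_s = min_interval_s,
                 mid_stance_percent = mid_stance_percent,
                 qc_sd_threshold = qc_sd_threshold,
                 var_equal = var_equal,
                 fdr_family_spatiotemporal = fdr_family_spatiotemporal,
                 gate_on_interaction = gate_on_interaction,
                 seed = as.integer(seed)),
            class = "run_config")
}

trial_columns <- function() {
  landmarks <- as.vector(outer(
    c("left", "right"),
    as.vector(outer(c("heel", "toe"), c("ap_m", "vert_m"), paste, sep = "_")),
    paste, sep = "_"))
  angles <- as.vector(outer(c("left", "right"),
                            paste0(c("hip", "knee", "ankle"), "_sagittal_deg"),
                            paste, sep = "_"))
  c("time_s", "pelvis_ap_m", "pelvis_vert_m", landmarks, angles)
}

#' Write a trial recording to the native tab-separated trial format
#'
#' `#`-prefixed header lines carry the metadata (participant, group,
#' condition, trial index, sampling rate, geometry), followed by a TSV body
#' with one row per frame.
#'
#' @param recording a `trial_recording`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trial <- function(recording, path) {
  m <- recording$meta
  g <- m$geometry
  hdr <- c(
    sprintf("# participant: %s", m$participant),
    sprintf("# group: %s", m$group),
    sprintf("# condition: %s", m$condition),
    sprintf("# trial: %d", as.integer(m$trial)),
    sprintf("# fs: %.10g", m$fs),
    sprintf("# incline_deg: %.10g", g$incline_deg),
    sprintf("# ramp_length_m: %.10g", g$ramp_length_m),
    sprintf("# level_length_m: %.10g", g$level_length_m),
    sprintf("# stance_fraction: %.10g", m$stance_fraction))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  cols <- intersect(trial_columns(), names(recording$frames))
  writeLines(paste(cols, collapse = "\t"), con)
  body <- do.call(cbind, lapply(recording$frames[cols], function(x)
    formatC(x, format = "g", digits = 12)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a trial recording from the native trial format
#'
#' Columns may appear in any order; all declared columns must be present,
#' time must advance monotonically at 1/fs spacing, and angles must be
#' finite. Malformed rows are reported with their line number.
#'
#' @param path path to a trial file written by [write_trial()].
#' @return a `trial_recording`.
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body_start <- which(!grepl("^#", lines))[1]
  header <- strsplit(lines[body_start], "\t", fixed = TRUE)[[1]]
  need <- trial_columns()
  miss <- setdiff(need, header)
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- lines[-seq_len(body_start)]
  rows <- rows[nzchar(rows)]
  fields <- strsplit(rows, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad))
    stop(sprintf("malformed row at line %d: %d fields, expected %d",
                 body_start + bad[1], nf[bad[1]], length(header)))
  mat <- matrix(as.numeric(unlist(fields)), ncol = length(header), byrow = TRUE)
  frames <- as.data.frame(mat)
  names(frames) <- header
  frames <- frames[, need]
  fs <- as.numeric(meta$fs)
  if (any(abs(diff(frames$time_s) - 1 / fs) > 1e-6))
    stop("non-monotone or irregular time column (expected 1/fs spacing)")
  ang <- grep("_deg$", names(frames), value = TRUE)
  if (any(!is.finite(as.matrix(frames[, ang]))))
    stop("non-finite joint angles")
  structure(list(
    meta = list(participant = meta$participant, group = meta$group,
                condition = meta$condition, trial = as.integer(meta$trial),
                fs = fs,
                stance_fraction = as.numeric(meta$stance_fraction),
                geometry = ramp_geometry(
                  incline_deg = as.numeric(meta$incline_deg),
                  ramp_length_m = as.numeric(meta$ramp_length_m),
                  level_length_m = as.numeric(meta$level_length_m))),
    frames = frames), class = "trial_recording")
}

#' Write a cohort to a directory of trial files plus ground-truth sidecar
#'
#' @param cohort a `gait_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$trials))
    write_trial(cohort$trials[[key]], file.path(dir, paste0(key, ".tsv")))
  gt <- list(participants = cohort$ground_truth$participants,
             events = cohort$ground_truth$events)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from a directory of trial files
#'
#' @param dir directory containing `.tsv` trial files (as written by
#'   [write_cohort()]).
#' @return a `gait_cohort` (ground truth included when the sidecar exists).
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no trial files in ", dir)
  trials <- lapply(files, read_trial)
  names(trials) <- sub("\\.tsv$", "", basename(files))
  gt <- NULL
  gtf <- file.path(dir, "ground_truth.json")
  if (file.exists(gtf)) gt <- jsonlite::read_json(gtf, simplifyVector = TRUE)
  structure(list(trials = trials, ground_truth = gt, spec = NULL),
            class = "gait_cohort")
}

#' Export events as CSV
#'
#' @param events named list of `event_series` (names = trial ids) or a
#'   single series.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_events_csv <- function(events, path) {
  if (inherits(events, "event_series")) events <- list(trial = events)
  rows <- do.call(rbind, lapply(names(events), function(id) {
    e <- as.data.frame(events[[id]])
    if (!nrow(e)) return(NULL)
    cbind(trial_id = id, e)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
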