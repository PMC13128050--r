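#' Gait event series
#'
#' Container for typed, side-labelled gait events. Per side, events must be
#' strictly increasing in time and alternate IC, TO, IC, ... beginning and
#' ending with an initial contact.
#'
#' @param df data.frame with columns `side` ("left"/"right"), `kind`
#'   ("IC"/"TO"), `frame` (1-based frame index), `time_s`.
#' @param fs sampling rate in Hz.
#' @param validate enforce the alternation/ordering invariants (default TRUE).
#' @return data.frame of class `event_series`, sorted by time, with
#'   attribute `fs`.
#' @export
event_series <- function(df, fs, validate = TRUE) {
  stopifnot(all(c("side", "kind", "frame", "time_s") %in% names(df)))
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "fs") <- fs
  class(df) <- c("event_series", "data.frame")
  if (validate) validate_event_series(df)
  df
}

#' Check event-series invariants
#'
#' Per side: strictly increasing times, alternation IC, TO, IC, ...
#' starting with an IC, and `time = (frame - 1) / fs`.
#'
#' @param events an `event_series`.
#' @return invisibly TRUE; errors with offending frames otherwise.
#' @export
validate_event_series <- function(events) {
  fs <- attr(events, "fs")
  for (s in unique(events$side)) {
    e <- events[events$side == s, ]
    if (any(diff(e$time_s) <= 0))
      stop("events for side ", s, " are not strictly increasing in time")
    expected <- rep(c("IC", "TO"), length.out = nrow(e))
    bad <- which(e$kind != expected)
    if (length(bad))
      stop("alternation violation for side ", s, " at frames: ",
           paste(e$frame[bad], collapse = ", "))
    if (!is.null(fs) && any(abs(e$time_s - (e$frame - 1) / fs) > 1e-8))
      stop("event times inconsistent with frame index and sampling rate")
  }
  invisible(TRUE)
}

# internal: local maxima with topographic prominence.
# Plateaus are assigned to their first frame (determinism).
find_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j == n || x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    lo <- x[p]; hi <- x[p]
    left_min <- x[p]
    k <- p
    while (k > 1L) { k <- k - 1L
      if (x[k] > x[p]) break
      left_min <- min(left_min, x[k]) }
    right_min <- x[p]
    k <- p
    while (k < n) { k <- k + 1L
      if (x[k] > x[p]) break
      right_min <- min(right_min, x[k]) }
    x[p] - max(left_min, right_min)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # enforce minimum spacing: keep the more prominent peak, ties to the earlier
  ord <- order(-promk, keep)
  sel <- logical(length(keep))
  for (o in ord) {
    if (!any(sel & abs(keep - keep[o]) < min_distance)) sel[o] <- TRUE
  }
  sort(keep[sel])
}

#' Walking direction and anterior-posterior projections
#'
#' Estimates the walking direction of a trial as the first principal axis of
#' the pelvis displacement in the sagittal (AP x vertical) plane, signed so
#' the projected pelvis position increases over the trial, and projects all
#' landmark positions onto it. On a ramp the principal axis is the slope
#' direction, so projected positions are along-slope. The orthogonal
#' (walkway-normal) projection is returned for foot-strike classification.
#'
#' @param recording a `trial_recording`.
#' @return list with `direction` (unit 2-vector in the stored (ap, vert)
#'   frame), and `ap` / `normal`: each a list with `pelvis` (numeric series)
#'   and `heel`, `toe` (lists with `left`/`right` series).
#' @export
walking_direction <- function(recording) {
  fr <- recording$frames
  pel <- cbind(fr$pelvis_ap_m, fr$pelvis_vert_m)
  disp <- pel[nrow(pel), ] - pel[1, ]
  cc <- sweep(pel, 2, colMeans(pel))
  cv <- crossprod(cc) / (nrow(pel) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  d <- ev$vectors[, 1]
  if (sum(d * disp) < 0) d <- -d
  if (abs(sum(pel[nrow(pel), ] * d) - sum(pel[1, ] * d)) < 0.5)
    stop("stationary trial: pelvis displacement below 0.5 m")
  nrm <- c(-d[2], d[1])
  if (nrm[2] < 0) nrm <- -nrm   # normal axis points upward
  proj <- function(xcol, zcol) fr[[xcol]] * d[1] + fr[[zcol]] * d[2]
  projn <- function(xcol, zcol) fr[[xcol]] * nrm[1] + fr[[zcol]] * nrm[2]
  sides <- c(left = "left", right = "right")
  list(
    direction = d,
    ap = list(
      pelvis = proj("pelvis_ap_m", "pelvis_vert_m"),
      heel = lapply(sides, function(s) proj(paste0(s, "_heel_ap_m"), paste0(s, "_heel_vert_m"))),
      toe = lapply(sides, function(s) proj(paste0(s, "_toe_ap_m"), paste0(s, "_toe_vert_m")))),
    normal = list(
      pelvis = projn("pelvis_ap_m", "pelvis_vert_m"),
      heel = lapply(sides, function(s) projn(paste0(s, "_heel_ap_m"), paste0(s, "_heel_vert_m"))),
      toe = lapply(sides, function(s) projn(paste0(s, "_toe_ap_m"), paste0(s, "_toe_vert_m")))))
}

#' Detect initial-contact and toe-off events (coordinate-based)
#'
#' Coordinate-based detection from landmark kinematics: per side, initial
#' contacts are local maxima of the heel-minus-pelvis AP displacement and
#' toe-offs are local minima of the toe-minus-pelvis AP displacement, with
#' peaks accepted above a prominence floor (a fraction of the signal's
#' interquartile range) and separated by a minimum interval. Toe-offs
#' before the first or after the last ipsilateral IC are dropped so each
#' side alternates IC, TO, ..., IC.
#'
#' @param recording a `trial_recording` (landmark tracks should be low-pass
#'   filtered for noisy data).
#' @param min_prominence_frac prominence floor as a fraction of the
#'   heel/toe-relative signal's IQR (default 0.2).
#' @param min_interval_s minimum interval between like events in seconds
#'   (default 0.3, admitting cadences up to 200 steps/min).
#' @param strict error on alternation violations (more than one TO between
#'   consecutive ICs); if FALSE the series is returned unvalidated for
#'   downstream per-cycle screening.
#' @return an `event_series`.
#' @export
detect_events <- function(recording, min_prominence_frac = 0.2,
                          min_interval_s = 0.3, strict = TRUE) {
  fs <- recording$meta$fs
  dir <- walking_direction(recording)
  mind <- ceiling(min_interval_s * fs)
  rows <- list()
  for (s in c("left", "right")) {
    hrel <- dir$ap$heel[[s]] - dir$ap$pelvis
    trel <- dir$ap$toe[[s]] - dir$ap$pelvis
    ic <- find_peaks(hrel, min_prominence = min_prominence_frac * stats::IQR(hrel),
                     min_distance = mind)
    to <- find_peaks(-trel, min_prominence = min_prominence_frac * stats::IQR(trel),
                     min_distance = mind)
    if (!length(ic)) next
    to <- to[to > min(ic) & to < max(ic)]
    rows[[s]] <- rbind(
      data.frame(side = s, kind = "IC", frame = ic),
      data.frame(side = s, kind = "TO", frame = to))
  }
  if (!length(rows)) {
    warning("no qualifying extrema: empty event series")
    df <- data.frame(side = character(0), kind = character(0),
                     frame = integer(0), time_s = numeric(0))
    return(event_series(df, fs, validate = FALSE))
  }
  df <- do.call(rbind, rows)
  df$time_s <- (df$frame - 1) / fs
  event_series(df, fs, validate = strict)
}

#' Classify foot strike at an initial contact
#'
#' A contact is a heel strike when the heel is at or below the toe along the
#' walkway-normal axis at the IC frame (so the criterion is slope-aware on
#' ramps), otherwise a forefoot strike. Missing landmark data yield
#' `"unknown"`.
#'
#' @param recording a `trial_recording`.
#' @param side `"left"` or `"right"`.
#' @param frame IC frame index.
#' @param threshold_m heel-above-toe tolerance in meters (default 0).
#' @return one of `"heel_strike"`, `"forefoot_strike"`, `"unknown"`.
#' @export
classify_foot_strike <- function(recording, side, frame, threshold_m = 0) {
  dir <- walking_direction(recording)
  h <- dir$normal$heel[[side]][frame]
  t <- dir$normal$toe[[side]][frame]
  if (!is.finite(h) || !is.finite(t)) return("unknown")
  if (h <= t + threshold_m) "heel_strike" else "forefoot_strike"
}

#' Trim a trial to its analyzable steps and cycles
#'
#' Steps are the initial contacts of either foot in temporal order, indexed
#' 1..N. Level-walking analysis keeps steps 3..N-3 (starts with the third
#' step, ends three steps before stopping); ramp analysis keeps steps
#' 2..N-1. A gait cycle is analyzable when both of its bounding ipsilateral
#' ICs fall in the kept range.
#'
#' @param events an `event_series`.
#' @param condition `"level"`, `"ascent"` or `"descent"`.
#' @return list with `kept_steps` (integer indices into the temporal step
#'   order), `steps` (data.frame of all ICs in order), and `cycles`
#'   (data.frame side, start_frame, end_frame, start_time, end_time).
#' @export
trim_cycles <- function(events, condition) {
  condition <- match.arg(condition, c("level", "ascent", "descent"))
  ics <- events[events$kind == "IC", , drop = FALSE]
  ics <- ics[order(ics$time_s), ]
  n <- nrow(ics)
  kept <- if (condition == "level") seq(3, n - 3) else seq(2, n - 1)
  if (n < 2 || length(kept) == 0 || kept[1] > kept[length(kept)] || kept[1] < 1)
    stop("trial too short for condition rule (", condition, ", ", n, " steps)")
  cyc <- list()
  for (s in unique(ics$side)) {
    idx <- which(ics$side == s)
    for (k in seq_len(length(idx) - 1)) {
      i1 <- idx[k]; i2 <- idx[k + 1]
      if (i1 %in% kept && i2 %in% kept)
        cyc[[length(cyc) + 1]] <- data.frame(
          side = s,
          start_frame = ics$frame[i1], end_frame = ics$frame[i2],
          start_time = ics$time_s[i1], end_time = ics$time_s[i2])
    }
  }
  cycles <- if (length(cyc)) do.call(rbind, cyc) else
    data.frame(side = character(0), start_frame = integer(0),
               end_frame = integer(0), start_time = numeric(0),
               end_time = numeric(0))
  cycles <- cycles[order(cycles$start_time), , drop = FALSE]
  rownames(cycles) <- NULL
  list(kept_steps = kept,
       steps = data.frame(index = seq_len(n), side = ics$side,
                          frame = ics$frame, time_s = ics$time_s),
       cycles = cycles)
}

#' Flag cycles with outlying duration
#'
#' Quality-control screen replacing manual event correction: cycles whose
#' duration deviates from the trial median by more than `k` standard
#' deviations are flagged for exclusion.
#'
#' @param cycles data.frame from [trim_cycles()]`$cycles`.
#' @param k flag threshold in SD units (default 3).
#' @return the cycles data.frame with logical column `flagged`.
#' @export
qc_flag_cycles <- function(cycles, k = 3) {
  dur <- cycles$end_time - cycles$start_time
  med <- stats::median(dur)
  s <- stats::sd(dur)
  cycles$duration_s <- dur
  cycles$flagged <- if (is.na(s) || s == 0) rep(FALSE, length(dur)) else
    abs(dur - med) > k * s
  cycles
}
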