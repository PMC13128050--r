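#' Partition the gait cycle into stance/swing phases
#'
#' Splits the 0--100% cycle at mid-stance and toe-off. Mid-stance is taken
#' as the temporal midpoint of stance (`to_percent / 2`), the only definition
#' computable from events alone; a different mid-stance location can be
#' supplied for sensitivity analyses.
#'
#' @param to_percent toe-off location in % cycle, strictly between 0 and 100.
#' @param mid_stance optional mid-stance location in % cycle; defaults to
#'   `to_percent / 2`.
#' @return object of class `phase_partition` with elements `st1`, `st2`,
#'   `swing` (each `c(from, to)` in % cycle), `mid_stance`, `to_percent`.
#'   `st1 = [0, mid)`, `st2 = [mid, to)`, `swing = [to, 100]`.
#' @export
partition_phases <- function(to_percent, mid_stance = NULL) {
  if (!is.finite(to_percent) || to_percent <= 0 || to_percent >= 100)
    stop("to_percent must lie strictly between 0 and 100")
  if (is.null(mid_stance)) mid_stance <- to_percent / 2
  if (mid_stance <= 0 || mid_stance >= to_percent)
    stop("mid_stance must lie strictly between 0 and to_percent")
  structure(
    list(st1 = c(0, mid_stance),
         st2 = c(mid_stance, to_percent),
         swing = c(to_percent, 100),
         mid_stance = mid_stance,
         to_percent = to_percent),
    class = "phase_partition")
}

#' @export
print.phase_partition <- function(x, ...) {
  cat(sprintf("<phase_partition> ST1 [0, %.1f)  ST2 [%.1f, %.1f)  swing [%.1f, 100]\n",
              x$mid_stance, x$mid_stance, x$to_percent, x$to_percent))
  invisible(x)
}

# internal: indices (1-based into a 101-sample waveform) of a % window.
# half_open drops the right endpoint, matching the [a, b) phase intervals.
window_idx <- function(from, to, half_open = TRUE) {
  i <- 0:100
  keep <- if (half_open) i >= from & i < to else i >= from & i <= to
  which(keep)
}

# internal: the twelve representative values, per joint, from one
# 101-sample waveform (flexion/dorsiflexion positive).
extract_joint_features <- function(samples, partition, joint) {
  stopifnot(length(samples) == 101)
  p <- partition
  stance <- window_idx(0, p$to_percent)
  st1 <- window_idx(0, p$mid_stance)
  st2 <- window_idx(p$mid_stance, p$to_percent)
  swing <- window_idx(p$to_percent, 100, half_open = FALSE)
  rom <- max(samples) - min(samples)
  switch(joint,
    hip = list(
      RoM = rom,
      MaxFlex_Stance = max(samples[stance]),
      MaxFlex_Swing = max(samples[swing]),
      # reported as the magnitude of peak stance extension
      MaxExt_Stance = -min(samples[stance])),
    knee = list(
      RoM = rom,
      MaxFlex_ST1 = max(samples[st1]),
      MaxFlex_Swing = max(samples[swing]),
      # reported signed; negative values indicate hyperextension
      MaxExt_Stance = min(samples[stance])),
    ankle = {
      pfwin <- window_idx(max(0, p$to_percent - 10),
                          min(100, p$to_percent + 10), half_open = FALSE)
      list(
        RoM = rom,
        MaxDorsiflexion_ST2 = max(samples[st2]),
        # magnitude of peak plantarflexion at the stance-to-swing transition
        MaxPlantarflexion_ST_SW = -min(samples[pfwin]),
        Ankle_InitialContact = samples[1])
    },
    stop("unknown joint: ", joint))
}

#' Extract the twelve representative sagittal joint-angle parameters
#'
#' Applies the representative-value definitions to 101-sample hip, knee and
#' ankle waveforms: range of motion over the full cycle, peak flexion/
#' extension within stance, stance-phase-1, stance-phase-2 or swing windows,
#' peak plantarflexion within +/-10% cycle of toe-off, and the ankle angle
#' at initial contact. Hip extension and ankle plantarflexion peaks are
#' reported as positive magnitudes; knee extension and the ankle IC angle
#' are signed (flexion/dorsiflexion positive).
#'
#' @param waveforms named list (or 101 x 3 matrix with columns
#'   `hip`, `knee`, `ankle`) of 101-sample waveforms in degrees.
#' @param partition a [partition_phases()] result.
#' @return named numeric vector of 12 parameters, names
#'   `<joint>_<parameter>`.
#' @export
extract_features <- function(waveforms, partition) {
  if (is.matrix(waveforms))
    waveforms <- list(hip = waveforms[, "hip"], knee = waveforms[, "knee"],
                      ankle = waveforms[, "ankle"])
  stopifnot(all(c("hip", "knee", "ankle") %in% names(waveforms)))
  out <- lapply(c("hip", "knee", "ankle"), function(j) {
    f <- extract_joint_features(waveforms[[j]], partition, j)
    stats::setNames(unlist(f), paste(j, names(f), sep = "_"))
  })
  unlist(out)
}

#' Names of the twelve joint-angle parameters
#' @return character vector of length 12.
#' @export
feature_parameter_names <- function() {
  c("hip_RoM", "hip_MaxFlex_Stance", "hip_MaxFlex_Swing", "hip_MaxExt_Stance",
    "knee_RoM", "knee_MaxFlex_ST1", "knee_MaxFlex_Swing", "knee_MaxExt_Stance",
    "ankle_RoM", "ankle_MaxDorsiflexion_ST2", "ankle_MaxPlantarflexion_ST_SW",
    "ankle_Ankle_InitialContact")
}

#' Spatiotemporal parameters from events and landmark tracks
#'
#' Computes cadence, walking velocity and step length over the kept
#' (post-trimming) window of one trial. Cadence uses the kept initial
#' contacts only; step length is the heel-to-heel distance projected on the
#' walking direction (along-slope on ramps) at each kept contact; velocity
#' is the pelvis displacement along the walking direction divided by the
#' kept-window duration.
#'
#' @param recording a `trial_recording`.
#' @param events an `event_series` for the trial.
#' @param kept_steps integer step indices kept by [trim_cycles()]; defaults
#'   to all steps.
#' @return named numeric: `cadence` (steps/min), `velocity` (m/s),
#'   `step_length` (m).
#' @export
spatiotemporal <- function(recording, events, kept_steps = NULL) {
  ev <- as.data.frame(events)
  ics <- ev[ev$kind == "IC", ]
  ics <- ics[order(ics$time_s), ]
  if (is.null(kept_steps)) kept_steps <- seq_len(nrow(ics))
  ics <- ics[kept_steps, , drop = FALSE]
  if (nrow(ics) < 2)
    stop("need at least 2 kept initial contacts for spatiotemporal parameters")

  dir <- walking_direction(recording)
  ap <- dir$ap   # list with $pelvis and per-side heel AP series
  dt <- ics$time_s[nrow(ics)] - ics$time_s[1]
  cadence <- 60 * (nrow(ics) - 1) / dt
  velocity <- (ap$pelvis[ics$frame[nrow(ics)]] - ap$pelvis[ics$frame[1]]) / dt

  steps <- vapply(seq(2, nrow(ics)), function(k) {
    fr <- ics$frame[k]
    lead <- ics$side[k]
    trail <- setdiff(c("left", "right"), lead)
    ap$heel[[lead]][fr] - ap$heel[[trail]][fr]
  }, numeric(1))
  c(cadence = cadence, velocity = velocity, step_length = mean(steps))
}
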