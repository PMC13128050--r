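#' Zero-lag low-pass filter
#'
#' Second-order Butterworth low-pass applied forward and backward (effective
#' fourth order, zero phase lag) with the dual-pass cutoff correction of
#' 1/0.802, so the net gain at the nominal cutoff is about -3 dB (within the
#' [-4, -2] dB contract). The series is extended by end-point-reflected
#' padding before filtering to suppress edge transients, so a constant
#' series passes through unchanged (DC gain 1).
#'
#' @param x numeric series (at least 20 samples).
#' @param fs sampling rate, Hz.
#' @param cutoff nominal cutoff frequency, Hz (default 6).
#' @return filtered series, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 6) {
  n <- length(x)
  if (n < 20) stop("series shorter than filter warm-up (< 20 frames)")
  fc <- cutoff / 0.802
  if (fs <= 2 * fc) stop("sampling rate must exceed twice the (corrected) cutoff")
  bf <- signal::butter(2, fc / (fs / 2))
  pad <- min(n - 1L, max(20L, as.integer(round(fs))))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]),
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' Segment ipsilateral IC-to-IC gait cycles
#'
#' Cuts a per-side angle series into raw cycles spanning consecutive
#' ipsilateral initial contacts. A cycle must contain exactly one
#' ipsilateral toe-off strictly inside it; cycles with zero or multiple
#' toe-offs are discarded and the reasons logged in the `"discarded"`
#' attribute.
#'
#' @param angles numeric matrix (frames x joints) or vector for one side.
#' @param events an `event_series`.
#' @param side `"left"` or `"right"`.
#' @param fs sampling rate, Hz.
#' @param cycles optional data.frame (side, start_frame, end_frame) from
#'   [trim_cycles()] restricting segmentation to kept cycles; defaults to
#'   all consecutive ipsilateral IC pairs.
#' @return list of raw cycles: each a list with `side`, `samples`
#'   (frames x joints matrix), `times`, `to_index` (toe-off row within the
#'   cycle), `start_frame`.
#' @export
segment_cycles <- function(angles, events, side, fs, cycles = NULL) {
  if (is.vector(angles)) angles <- matrix(angles, ncol = 1)
  ev <- events[events$side == side, , drop = FALSE]
  ics <- ev$frame[ev$kind == "IC"]
  tos <- ev$frame[ev$kind == "TO"]
  if (is.null(cycles)) {
    if (length(ics) < 2) {
      out <- list(); attr(out, "discarded") <- character(0); return(out)
    }
    cycles <- data.frame(start_frame = ics[-length(ics)], end_frame = ics[-1])
  } else {
    cycles <- cycles[cycles$side == side, , drop = FALSE]
  }
  out <- list()
  discarded <- character(0)
  for (i in seq_len(nrow(cycles))) {
    a <- cycles$start_frame[i]; b <- cycles$end_frame[i]
    tin <- tos[tos > a & tos < b]
    if (length(tin) != 1) {
      discarded <- c(discarded, sprintf(
        "%s cycle frames %d-%d: %d toe-offs (need exactly 1)", side, a, b, length(tin)))
      next
    }
    out[[length(out) + 1]] <- list(
      side = side,
      samples = angles[a:b, , drop = FALSE],
      times = (seq(a, b) - 1) / fs,
      to_index = tin - a + 1L,
      start_frame = a)
  }
  attr(out, "discarded") <- discarded
  out
}

#' Time-normalize a raw cycle to the 0-100% gait cycle grid
#'
#' Resamples each joint's series onto 101 points (0, 1, ..., 100% of the
#' cycle) by cubic interpolation on the cycle's own time base; endpoints
#' are preserved exactly. The toe-off location is carried over as a
#' percentage of cycle duration.
#'
#' @param raw_cycle one element of [segment_cycles()] output.
#' @return object of class `normalized_cycle`: list with `samples`
#'   (101 x joints), `to_percent`, `side`.
#' @export
time_normalize <- function(raw_cycle) {
  tm <- raw_cycle$times
  m <- length(tm)
  if (m < 10) stop("raw cycle shorter than 10 frames")
  dur <- tm[m] - tm[1]
  if (dur <= 0) stop("degenerate zero-duration cycle")
  grid <- tm[1] + dur * seq(0, 1, length.out = 101)
  x <- raw_cycle$samples
  samples <- apply(x, 2, function(col) {
    y <- stats::spline(tm, col, xout = grid, method = "fmm")$y
    y[1] <- col[1]; y[101] <- col[m]   # preserve endpoints exactly
    y
  })
  to_percent <- 100 * (tm[raw_cycle$to_index] - tm[1]) / dur
  structure(list(samples = samples, to_percent = to_percent,
                 side = raw_cycle$side),
            class = "normalized_cycle")
}

#' Hierarchical averaging into a representative waveform
#'
#' Averaging order mirrors the study design: (i) mean across a trial's
#' cycles per side, (ii) mean of left and right within the trial, (iii) mean
#' across trials. The SD band is computed across the trial-level (limb-
#' averaged) waveforms. Toe-off percentages are averaged with the same
#' hierarchy. If a trial has cycles on only one side, the single-side mean
#' is used with a warning.
#'
#' @param cycles list of `normalized_cycle` objects, each additionally
#'   tagged with a `trial` element.
#' @return object of class `representative_waveform`: `mean` and `sd`
#'   (101 x joints matrices), `to_percent`, `n_cycles`, `n_trials`.
#' @export
average_waveforms <- function(cycles) {
  if (!length(cycles)) stop("no cycles to average")
  trials <- unique(vapply(cycles, function(cy) cy$trial, numeric(1)))
  trial_means <- list()
  trial_tos <- numeric(0)
  for (tr in trials) {
    in_trial <- Filter(function(cy) cy$trial == tr, cycles)
    side_means <- list(); side_tos <- numeric(0)
    for (s in c("left", "right")) {
      on_side <- Filter(function(cy) cy$side == s, in_trial)
      if (!length(on_side)) next
      arr <- lapply(on_side, `[[`, "samples")
      side_means[[s]] <- Reduce(`+`, arr) / length(arr)
      side_tos <- c(side_tos, mean(vapply(on_side, `[[`, numeric(1), "to_percent")))
    }
    if (length(side_means) == 1)
      warning("trial ", tr, ": one side missing, using single-side mean")
    trial_means[[length(trial_means) + 1]] <-
      Reduce(`+`, side_means) / length(side_means)
    trial_tos <- c(trial_tos, mean(side_tos))
  }
  k <- length(trial_means)
  mu <- Reduce(`+`, trial_means) / k
  sdm <- if (k > 1) {
    vs <- Reduce(`+`, lapply(trial_means, function(m) (m - mu)^2)) / (k - 1)
    sqrt(vs)
  } else mu * 0
  structure(list(mean = mu, sd = sdm, to_percent = mean(trial_tos),
                 n_cycles = length(cycles), n_trials = k),
            class = "representative_waveform")
}

#' @export
print.representative_waveform <- function(x, ...) {
  cat(sprintf("<representative_waveform> %d joints x 101 samples, %d cycles in %d trials, TO at %.1f%%\n",
              ncol(x$mean), x$n_cycles, x$n_trials, x$to_percent))
  invisible(x)
}
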