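#' Walkway geometry
#'
#' @param incline_deg ramp incline in degrees (>= 0; default 7).
#' @param ramp_length_m ramp surface length in meters (default 3.25).
#' @param level_length_m level walkway length in meters (default 7).
#' @param approach_m,exit_m level ground available before/after the walkway
#'   where the first/last steps of a trial fall (default 1.5 m each).
#' @return list of class `ramp_geometry`.
#' @export
ramp_geometry <- function(incline_deg = 7, ramp_length_m = 3.25,
                          level_length_m = 7, approach_m = 1.5, exit_m = 1.5) {
  stopifnot(incline_deg >= 0, ramp_length_m > 0, level_length_m > 0,
            approach_m >= 0, exit_m >= 0)
  structure(list(incline_deg = incline_deg, ramp_length_m = ramp_length_m,
                 level_length_m = level_length_m, approach_m = approach_m,
                 exit_m = exit_m),
            class = "ramp_geometry")
}

#' Published spatiotemporal calibration targets
#'
#' Group-level means and SDs of walking velocity (m/s) and step length (m),
#' and mean cadence (steps/min), per group and condition. These are the
#' generator's default calibration; cadence is derived from velocity and
#' step length at simulation time (velocity = step length x cadence / 60).
#'
#' @return data.frame with columns group, condition, cadence, velocity,
#'   velocity_sd, step_length, step_length_sd.
#' @export
default_spatiotemporal_targets <- function() {
  data.frame(
    group = rep(c("young", "older"), each = 3),
    condition = rep(c("level", "ascent", "descent"), 2),
    cadence = c(114.14, 104.16, 112.60, 114.13, 102.04, 112.04),
    velocity = c(1.39, 1.24, 1.27, 1.28, 1.08, 1.11),
    velocity_sd = c(0.13, 0.10, 0.15, 0.18, 0.10, 0.16),
    step_length = c(0.73, 0.72, 0.67, 0.67, 0.64, 0.59),
    step_length_sd = c(0.06, 0.05, 0.07, 0.07, 0.05, 0.07),
    stringsAsFactors = FALSE)
}

#' Published joint-angle calibration targets
#'
#' Group-level extremum targets (degrees) for each joint and condition,
#' following the reporting conventions of [extract_features()]. Range of
#' motion is not a calibration target: it is emergent from the extrema of a
#' single waveform (published group EMMs, being adjusted model means, are
#' not mutually constrained by waveform algebra).
#'
#' @return data.frame with columns group, condition, joint, parameter, value.
#' @export
default_angle_targets <- function() {
  row <- function(group, condition, joint, parameter, value)
    data.frame(group = group, condition = condition, joint = joint,
               parameter = parameter, value = value, stringsAsFactors = FALSE)
  tab <- rbind(
    # level walking
    row("young", "level", "hip", "MaxFlex_Stance", 24.1),
    row("young", "level", "hip", "MaxFlex_Swing", 27.9),
    row("young", "level", "hip", "MaxExt_Stance", 16.2),
    row("young", "level", "knee", "MaxFlex_ST1", 13.7),
    row("young", "level", "knee", "MaxFlex_Swing", 66.2),
    row("young", "level", "knee", "MaxExt_Stance", 1.4),
    row("young", "level", "ankle", "MaxDorsiflexion_ST2", 14.1),
    row("young", "level", "ankle", "MaxPlantarflexion_ST_SW", 18.5),
    row("young", "level", "ankle", "Ankle_InitialContact", -2.0),
    row("older", "level", "hip", "MaxFlex_Stance", 26.7),
    row("older", "level", "hip", "MaxFlex_Swing", 30.2),
    row("older", "level", "hip", "MaxExt_Stance", 16.2),
    row("older", "level", "knee", "MaxFlex_ST1", 17.3),
    row("older", "level", "knee", "MaxFlex_Swing", 66.6),
    row("older", "level", "knee", "MaxExt_Stance", -1.5),
    row("older", "level", "ankle", "MaxDorsiflexion_ST2", 14.1),
    row("older", "level", "ankle", "MaxPlantarflexion_ST_SW", 16.7),
    row("older", "level", "ankle", "Ankle_InitialContact", -0.6),
    # ramp ascent
    row("young", "ascent", "hip", "MaxFlex_Stance", 42.6),
    row("young", "ascent", "hip", "MaxFlex_Swing", 38.9),
    row("young", "ascent", "hip", "MaxExt_Stance", 17.3),
    row("young", "ascent", "knee", "MaxFlex_ST1", 25.0),
    row("young", "ascent", "knee", "MaxFlex_Swing", 61.0),
    row("young", "ascent", "knee", "MaxExt_Stance", -4.0),
    row("young", "ascent", "ankle", "MaxDorsiflexion_ST2", 19.3),
    row("young", "ascent", "ankle", "MaxPlantarflexion_ST_SW", 20.5),
    row("young", "ascent", "ankle", "Ankle_InitialContact", 1.3),
    row("older", "ascent", "hip", "MaxFlex_Stance", 43.7),
    row("older", "ascent", "hip", "MaxFlex_Swing", 39.3),
    row("older", "ascent", "hip", "MaxExt_Stance", 20.4),
    row("older", "ascent", "knee", "MaxFlex_ST1", 33.4),
    row("older", "ascent", "knee", "MaxFlex_Swing", 64.3),
    row("older", "ascent", "knee", "MaxExt_Stance", -5.2),
    row("older", "ascent", "ankle", "MaxDorsiflexion_ST2", 20.0),
    row("older", "ascent", "ankle", "MaxPlantarflexion_ST_SW", 15.4),
    row("older", "ascent", "ankle", "Ankle_InitialContact", 3.8),
    # ramp descent
    row("young", "descent", "hip", "MaxFlex_Stance", 21.9),
    row("young", "descent", "hip", "MaxFlex_Swing", 24.8),
    row("young", "descent", "hip", "MaxExt_Stance", 14.8),
    row("young", "descent", "knee", "MaxFlex_ST1", 23.5),
    row("young", "descent", "knee", "MaxFlex_Swing", 69.9),
    row("young", "descent", "knee", "MaxExt_Stance", 0.5),
    row("young", "descent", "ankle", "MaxDorsiflexion_ST2", 15.3),
    row("young", "descent", "ankle", "MaxPlantarflexion_ST_SW", 13.8),
    row("young", "descent", "ankle", "Ankle_InitialContact", -0.3),
    row("older", "descent", "hip", "MaxFlex_Stance", 25.7),
    row("older", "descent", "hip", "MaxFlex_Swing", 28.2),
    row("older", "descent", "hip", "MaxExt_Stance", 12.5),
    row("older", "descent", "knee", "MaxFlex_ST1", 28.7),
    row("older", "descent", "knee", "MaxFlex_Swing", 72.6),
    row("older", "descent", "knee", "MaxExt_Stance", -4.1),
    row("older", "descent", "ankle", "MaxDorsiflexion_ST2", 17.4),
    row("older", "descent", "ankle", "MaxPlantarflexion_ST_SW", 9.9),
    row("older", "descent", "ankle", "Ankle_InitialContact", 2.2))
  tab
}

# internal: periodic pchip through (phase, value) keypoints
periodic_curve <- function(phase, value) {
  n <- length(phase)
  k <- min(3L, n)
  xe <- c(phase[(n - k + 1L):n] - 1, phase, phase[1:k] + 1)
  ye <- c(value[(n - k + 1L):n], value, value[1:k])
  function(ph) pracma::pchip(xe, ye, ph %% 1)
}

#' Simulate one walking trial
#'
#' Synthesizes a trial recording at a fixed sampling rate: sagittal joint
#' angles resampled from the waveform templates at each side's cycle phase,
#' and heel/toe/pelvis trajectories from a single-support/double-support
#' timing model in which the stance foot is stationary on the walking
#' surface (so the heel-minus-pelvis AP displacement peaks exactly at
#' initial contact and the toe-minus-pelvis displacement troughs at
#' toe-off). Ramp trials advance the pelvis along the incline; the vertical
#' coordinate follows the slope.
#'
#' @param templates named list of hip/knee/ankle [waveform_template()]s.
#' @param cadence steps per minute (> 0).
#' @param step_length step length in meters.
#' @param n_steps number of steps (>= 8 level, >= 4 ramp so trimming leaves
#'   at least one cycle... defaults in [generate_cohort()] use 9 and 6).
#' @param geometry a [ramp_geometry()].
#' @param condition `"level"`, `"ascent"` or `"descent"`.
#' @param noise_sd frame-level angle noise SD, degrees.
#' @param pos_noise_m landmark position noise SD, meters; default scales
#'   with `noise_sd` (0.004 m per degree, about the arc of 1 degree over a
#'   foot's length).
#' @param angle_offsets named numeric (hip/knee/ankle) waveform shifts in
#'   degrees (a participant's random intercept).
#' @param fs sampling rate, Hz (default 60).
#' @param lead_in_s standing lead-in/out before the first and after the
#'   last contact, seconds.
#' @param foot_length_m heel-to-toe distance, meters.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used, as [generate_cohort()] does).
#' @param meta optional named list merged into the recording metadata.
#' @return list with `recording` (a `trial_recording`) and `ground_truth`
#'   (list with `events` data.frame, analytic contact times, cadence,
#'   velocity, step length).
#' @export
simulate_trial <- function(templates, cadence, step_length, n_steps,
                           geometry = ramp_geometry(), condition = "level",
                           noise_sd = 0, pos_noise_m = 0.004 * noise_sd,
                           angle_offsets = c(hip = 0, knee = 0, ankle = 0),
                           fs = 60, lead_in_s = 0.5, foot_length_m = 0.22,
                           seed = NULL, meta = list()) {
  condition <- match.arg(condition, c("level", "ascent", "descent"))
  stopifnot(cadence > 0, step_length > 0, n_steps >= 2)
  if (!is.null(seed)) set.seed(seed)

  usable <- geometry$approach_m + geometry$exit_m +
    if (condition == "level") geometry$level_length_m else geometry$ramp_length_m
  if (step_length * (n_steps + 1) > usable) {
    n_new <- max(2L, as.integer(floor(usable / step_length)) - 1L)
    warning(sprintf("trial truncated: %d steps of %.2f m exceed the %.2f m path (keeping %d steps)",
                    n_steps, step_length, usable, n_new))
    n_steps <- n_new
  }

  Ts <- 60 / cadence           # step period, s
  Tstride <- 2 * Ts
  v <- step_length * cadence / 60
  L <- step_length
  sf <- templates$hip$stance_fraction
  ic_times <- lead_in_s + (seq_len(n_steps) - 1) * Ts
  ic_sides <- rep(c("right", "left"), length.out = n_steps)  # trials start on the right foot
  dur <- ic_times[n_steps] + lead_in_s
  n <- as.integer(floor(dur * fs)) + 1L
  tm <- (seq_len(n) - 1) / fs

  a <- 0.5 * L
  f <- foot_length_m
  # collinear knots surrounding phase 0.5 keep the interpolant exactly
  # linear where the trailing foot sits at a contralateral IC, so heel
  # separation at any IC equals the step length by construction
  stance_ph <- c(0, 0.2, 0.45, 0.55, sf)
  heel_rel <- periodic_curve(
    c(stance_ph, sf + 0.5 * (1 - sf)),
    c(a - 2 * L * stance_ph, a - 2 * L * sf + 0.55 * 2 * L * sf))
  toe_rel <- periodic_curve(
    c(stance_ph, sf + 0.5 * (1 - sf)),
    c(a + f - 2 * L * stance_ph, a + f - 2 * L * sf + 0.55 * 2 * L * sf))
  heel_nrm <- periodic_curve(
    c(0, 0.3 * sf, 0.7 * sf, sf, sf + 0.4 * (1 - sf), sf + 0.8 * (1 - sf)),
    c(0, 0, 0.004, 0.03, 0.10, 0.03))
  toe_nrm <- periodic_curve(
    c(0, 0.12, 0.5 * sf, sf, sf + 0.5 * (1 - sf), 1 - 0.05),
    c(0.02, 0, 0, 0, 0.08, 0.035))

  theta <- switch(condition, level = 0,
                  ascent = geometry$incline_deg * pi / 180,
                  descent = -geometry$incline_deg * pi / 180)
  rot <- function(u, nrm) list(x = u * cos(theta) - nrm * sin(theta),
                               z = u * sin(theta) + nrm * cos(theta))

  first_ic <- c(right = ic_times[1],
                left = if (n_steps >= 2) ic_times[2] else ic_times[1] + Ts)
  phase_of <- function(s) ((tm - first_ic[[s]]) / Tstride) %% 1

  u_pelvis <- v * tm
  pel <- rot(u_pelvis, 0.9)
  frames <- data.frame(time_s = tm, pelvis_ap_m = pel$x, pelvis_vert_m = pel$z)

  gt_rows <- list()
  noiseless_angles <- list()
  for (s in c("left", "right")) {
    ph <- phase_of(s)
    hu <- u_pelvis + heel_rel(ph)
    tu <- u_pelvis + toe_rel(ph)
    hn <- heel_nrm(ph)
    tn2 <- toe_nrm(ph)
    if (pos_noise_m > 0) {
      hu <- hu + stats::rnorm(n, 0, pos_noise_m)
      tu <- tu + stats::rnorm(n, 0, pos_noise_m)
      hn <- hn + stats::rnorm(n, 0, pos_noise_m)
      tn2 <- tn2 + stats::rnorm(n, 0, pos_noise_m)
    }
    h <- rot(hu, hn); t2 <- rot(tu, tn2)
    frames[[paste0(s, "_heel_ap_m")]] <- h$x
    frames[[paste0(s, "_heel_vert_m")]] <- h$z
    frames[[paste0(s, "_toe_ap_m")]] <- t2$x
    frames[[paste0(s, "_toe_vert_m")]] <- t2$z
    for (j in c("hip", "knee", "ankle")) {
      ang <- eval_template(templates[[j]], ph) + angle_offsets[[j]]
      noiseless_angles[[paste(s, j, sep = "_")]] <- ang
      if (noise_sd > 0) ang <- ang + stats::rnorm(n, 0, noise_sd)
      frames[[paste0(s, "_", j, "_sagittal_deg")]] <- ang
    }
    # ground-truth events: extremum frames of the noiseless relative signals
    # around each analytic contact/lift time (consistent by construction)
    hrel0 <- heel_rel(ph)
    trel0 <- toe_rel(ph)
    win <- as.integer(round(0.3 * Tstride * fs))
    side_ics <- ic_times[ic_sides == s]
    for (tic in side_ics) {
      fr0 <- as.integer(round(tic * fs)) + 1L
      lo <- max(1L, fr0 - win); hi <- min(n, fr0 + win)
      frm <- lo - 1L + which.max(hrel0[lo:hi])
      gt_rows[[length(gt_rows) + 1]] <- data.frame(side = s, kind = "IC", frame = frm)
      tto <- tic + sf * Tstride
      if (tto < dur - 0.05 && tic < max(side_ics)) {
        fr0 <- as.integer(round(tto * fs)) + 1L
        lo <- max(1L, fr0 - win); hi <- min(n, fr0 + win)
        frm <- lo - 1L + which.min(trel0[lo:hi])
        gt_rows[[length(gt_rows) + 1]] <- data.frame(side = s, kind = "TO", frame = frm)
      }
    }
  }
  gt <- do.call(rbind, gt_rows)
  gt$time_s <- (gt$frame - 1) / fs
  gt <- gt[order(gt$time_s), ]
  rownames(gt) <- NULL

  recording <- structure(
    list(meta = utils::modifyList(
           list(fs = fs, condition = condition, geometry = geometry,
                participant = NA_character_, group = NA_character_,
                trial = 1L, stance_fraction = sf),
           meta),
         frames = frames),
    class = "trial_recording")

  list(recording = recording,
       ground_truth = list(events = gt, ic_times = ic_times,
                           ic_sides = ic_sides, cadence = cadence,
                           velocity = v, step_length = step_length,
                           angle_offsets = angle_offsets))
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s %s trial %s: %d frames at %g Hz\n",
              x$meta$participant, x$meta$condition, x$meta$trial,
              nrow(x$frames), x$meta$fs))
  invisible(x)
}

#' Cohort specification
#'
#' Describes a two-group synthetic cohort. Group/condition targets default
#' to the published group tables; `participant_sd` is the SD of the
#' per-participant random waveform offset (degrees, one draw per participant
#' and joint, constant across conditions — the random-intercept structure),
#' `noise_sd` the frame-level measurement noise (degrees). When
#' `standardize` is TRUE (the calibration contract) participant draws are
#' standardized to exact mean 0 and exact target SD within each group, so
#' realized group means equal the calibration targets.
#'
#' @param n_young,n_old participants per group (>= 1).
#' @param conditions subset of level/ascent/descent.
#' @param trials_per_condition trials per participant and condition (default 5).
#' @param participant_sd between-participant waveform offset SD, degrees.
#' @param noise_sd frame-level angle noise SD, degrees.
#' @param st_targets spatiotemporal calibration table
#'   (see [default_spatiotemporal_targets()]).
#' @param angle_targets joint-angle calibration table
#'   (see [default_angle_targets()]).
#' @param stance_fractions named vector per condition.
#' @param geometry a [ramp_geometry()].
#' @param n_steps named integer vector of steps per condition.
#' @param fs sampling rate, Hz.
#' @param standardize standardize participant draws to exact moments.
#' @param seed integer seed; identical settings yield bit-identical cohorts.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 20, n_old = 20,
                        conditions = c("level", "ascent", "descent"),
                        trials_per_condition = 5,
                        participant_sd = 3, noise_sd = 2,
                        st_targets = default_spatiotemporal_targets(),
                        angle_targets = default_angle_targets(),
                        stance_fractions = default_stance_fractions(),
                        geometry = ramp_geometry(),
                        n_steps = c(level = 9, ascent = 6, descent = 6),
                        fs = 60, standardize = TRUE, seed = 1L) {
  conditions <- match.arg(conditions, c("level", "ascent", "descent"),
                          several.ok = TRUE)
  stopifnot(n_young >= 1, n_old >= 1, trials_per_condition >= 1,
            participant_sd >= 0, noise_sd >= 0)
  structure(list(n_young = n_young, n_old = n_old, conditions = conditions,
                 trials_per_condition = trials_per_condition,
                 participant_sd = participant_sd, noise_sd = noise_sd,
                 st_targets = st_targets, angle_targets = angle_targets,
                 stance_fractions = stance_fractions, geometry = geometry,
                 n_steps = n_steps, fs = fs, standardize = standardize,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# internal: center/scale draws to exact moments (n>1), respecting target sd
standardized_draws <- function(n, sd_target) {
  if (sd_target == 0 || n == 1) return(rep(0, n))
  x <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  x * sd_target
}

#' Generate a synthetic two-group gait cohort
#'
#' Draws per-participant spatiotemporal targets (velocity and step length;
#' cadence derived) and per-participant joint waveform offsets, then
#' simulates every trial. Draw order is fixed for reproducibility: for each
#' group, (1) velocity offsets per condition, (2) step-length offsets per
#' condition, (3) joint waveform offsets, then (4) per-trial frame noise in
#' trial order. Identical specs (including seed) give identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `gait_cohort` with `trials` (list of
#'   `trial_recording`), `ground_truth` (participant targets, per-trial
#'   events), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- list(young = spec$n_young, older = spec$n_old)
  participants <- list()
  for (g in names(groups)) {
    ng <- groups[[g]]
    ids <- sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(ng))
    draws <- function(sd) if (spec$standardize) standardized_draws(ng, sd) else
      stats::rnorm(ng, 0, sd)
    vel_off <- matrix(unlist(lapply(spec$conditions, function(cd) {
      row <- spec$st_targets[spec$st_targets$group == g &
                               spec$st_targets$condition == cd, ]
      draws(row$velocity_sd)
    })), nrow = ng, dimnames = list(NULL, spec$conditions))
    sl_off <- matrix(unlist(lapply(spec$conditions, function(cd) {
      row <- spec$st_targets[spec$st_targets$group == g &
                               spec$st_targets$condition == cd, ]
      draws(row$step_length_sd)
    })), nrow = ng, dimnames = list(NULL, spec$conditions))
    joint_off <- matrix(unlist(lapply(c("hip", "knee", "ankle"),
                                      function(j) draws(spec$participant_sd))),
                        nrow = ng,
                        dimnames = list(NULL, c("hip", "knee", "ankle")))
    participants[[g]] <- list(ids = ids, vel_off = vel_off, sl_off = sl_off,
                              joint_off = joint_off)
  }

  # template sets are group x condition (participants differ by offsets)
  tsets <- list()
  for (g in names(groups)) for (cd in spec$conditions)
    tsets[[paste(g, cd)]] <- default_template_set(
      g, cd, stance_fraction = spec$stance_fractions[[cd]],
      angle_targets = spec$angle_targets)

  trials <- list()
  gt_events <- list()
  pt_rows <- list()
  for (g in names(groups)) {
    pp <- participants[[g]]
    for (i in seq_along(pp$ids)) {
      pid <- pp$ids[i]
      for (cd in spec$conditions) {
        row <- spec$st_targets[spec$st_targets$group == g &
                                 spec$st_targets$condition == cd, ]
        vel <- row$velocity + pp$vel_off[i, cd]
        sl <- row$step_length + pp$sl_off[i, cd]
        cad <- 60 * vel / sl
        offs <- c(hip = unname(pp$joint_off[i, "hip"]),
                  knee = unname(pp$joint_off[i, "knee"]),
                  ankle = unname(pp$joint_off[i, "ankle"]))
        pt_rows[[length(pt_rows) + 1]] <- data.frame(
          participant = pid, group = g, condition = cd,
          velocity = vel, step_length = sl, cadence = cad,
          hip_offset = offs[["hip"]], knee_offset = offs[["knee"]],
          ankle_offset = offs[["ankle"]])
        for (tr in seq_len(spec$trials_per_condition)) {
          sim <- simulate_trial(
            tsets[[paste(g, cd)]], cadence = cad, step_length = sl,
            n_steps = spec$n_steps[[cd]], geometry = spec$geometry,
            condition = cd, noise_sd = spec$noise_sd, fs = spec$fs,
            angle_offsets = offs,
            meta = list(participant = pid, group = g, trial = tr))
          key <- paste(pid, cd, tr, sep = "_")
          trials[[key]] <- sim$recording
          gt_events[[key]] <- sim$ground_truth$events
        }
      }
    }
  }
  structure(list(trials = trials,
                 ground_truth = list(participants = do.call(rbind, pt_rows),
                                     events = gt_events,
                                     templates = tsets),
                 spec = spec),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials: %d young + %d older, conditions %s, %d trials/condition\n",
              length(x$trials), x$spec$n_young, x$spec$n_old,
              paste(x$spec$conditions, collapse = "/"),
              x$spec$trials_per_condition))
  invisible(x)
}
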