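tplset <- function(cond = "level", group = "young")
  default_template_set(group, cond)

test_that("trial duration and frame count follow cadence arithmetic", {
  sim <- simulate_trial(tplset(), cadence = 120, step_length = 0.6,
                        n_steps = 10, lead_in_s = 0.5)
  # 9 step intervals of 0.5 s plus lead-in/out
  expect_equal(nrow(sim$recording$frames), floor((9 * 0.5 + 1.0) * 60) + 1)
  expect_equal(diff(sim$ground_truth$ic_times), rep(0.5, 9))
})

test_that("noiseless trials yield exact event recovery and template waveforms", {
  for (cond in c("level", "ascent", "descent")) {
    n_steps <- if (cond == "level") 9 else 6
    sim <- simulate_trial(tplset(cond), cadence = 110, step_length = 0.65,
                          n_steps = n_steps, condition = cond)
    ev <- detect_events(sim$recording)
    expect_equal(as.data.frame(ev)[, c("side", "kind", "frame")],
                 sim$ground_truth$events[, c("side", "kind", "frame")],
                 label = cond)
  }
})

test_that("pelvis advances monotonically and mean velocity matches cadence x step length", {
  sim <- simulate_trial(tplset(), cadence = 114.14, step_length = 0.73,
                        n_steps = 9)
  rec <- sim$recording
  dir <- walking_direction(rec)
  expect_true(all(diff(dir$ap$pelvis) > 0))
  v <- (dir$ap$pelvis[nrow(rec$frames)] - dir$ap$pelvis[1]) /
    (rec$frames$time_s[nrow(rec$frames)] - rec$frames$time_s[1])
  expect_equal(v, 1.39, tolerance = 0.02 * 1.39 / 1.39)
  expect_equal(v, 114.14 / 60 * 0.73, tolerance = 1e-6)
})

test_that("heel-pelvis displacement peaks once per ipsilateral step at ground-truth ICs", {
  sim <- simulate_trial(tplset(), cadence = 105, step_length = 0.7, n_steps = 9)
  dir <- walking_direction(sim$recording)
  gt <- sim$ground_truth$events
  for (s in c("left", "right")) {
    hrel <- dir$ap$heel[[s]] - dir$ap$pelvis
    pk <- oracle_peaks(hrel, min_prominence = 0.2 * IQR(hrel),
                       min_distance = 18)
    expect_equal(pk, gt$frame[gt$side == s & gt$kind == "IC"])
  }
})

test_that("overlong trials are truncated with a warning", {
  expect_warning(
    sim <- simulate_trial(tplset("ascent"), cadence = 100, step_length = 0.7,
                          n_steps = 12, condition = "ascent"),
    "truncated")
  expect_lt(length(sim$ground_truth$ic_times), 12)
})

test_that("ramp trials advance along the incline with matching slope", {
  sim <- simulate_trial(tplset("ascent"), cadence = 100, step_length = 0.6,
                        n_steps = 6, condition = "ascent")
  fr <- sim$recording$frames
  fitln <- stats::lm(pelvis_vert_m ~ pelvis_ap_m, data = fr)
  expect_equal(unname(coef(fitln)[2]), tan(7 * pi / 180), tolerance = 1e-6)
  sim2 <- simulate_trial(tplset("descent"), cadence = 100, step_length = 0.6,
                         n_steps = 6, condition = "descent")
  fit2 <- stats::lm(pelvis_vert_m ~ pelvis_ap_m, data = sim2$recording$frames)
  expect_equal(unname(coef(fit2)[2]), -tan(7 * pi / 180), tolerance = 1e-6)
})

test_that("identical cohort specs give bit-identical cohorts", {
  spec <- cohort_spec(n_young = 2, n_old = 2, conditions = "level",
                      trials_per_condition = 2, participant_sd = 2,
                      noise_sd = 1, seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$ground_truth$participants, c2$ground_truth$participants)
})

test_that("noiseless cohorts reproduce configured targets through the full pipeline", {
  spec <- cohort_spec(n_young = 2, n_old = 2, trials_per_condition = 2,
                      participant_sd = 0, noise_sd = 0, seed = 5)
  coh <- generate_cohort(spec)
  pf <- participant_features(coh, run_config(filter_cutoff = NULL))
  f <- pf$features
  tab <- default_angle_targets()
  st <- default_spatiotemporal_targets()
  for (i in seq_len(nrow(f))) {
    tg <- tab[tab$group == f$group[i] & tab$condition == f$condition[i], ]
    for (k in seq_len(nrow(tg))) {
      nm <- paste(tg$joint[k], tg$parameter[k], sep = "_")
      expect_equal(f[[nm]][i], tg$value[k], tolerance = 0.1,
                   label = paste(f$participant[i], f$condition[i], nm))
    }
    strow <- st[st$group == f$group[i] & st$condition == f$condition[i], ]
    gt <- coh$ground_truth$participants
    gtrow <- gt[gt$participant == f$participant[i] &
                  gt$condition == f$condition[i], ]
    expect_equal(f$velocity[i], gtrow$velocity, tolerance = 0.01)
    expect_equal(f$step_length[i], gtrow$step_length, tolerance = 0.01)
    expect_equal(f$cadence[i], gtrow$cadence, tolerance = 0.01)
  }
})

test_that("event detection stays accurate under angle and position noise", {
  set.seed(202)
  errs <- c()
  f1 <- c()
  for (rep in 1:25) {
    sim <- simulate_trial(tplset(), cadence = runif(1, 95, 125),
                          step_length = runif(1, 0.55, 0.75), n_steps = 9,
                          noise_sd = 1)
    ev <- suppressWarnings(detect_events(sim$recording, strict = FALSE))
    gt <- sim$ground_truth$events
    for (s in c("left", "right")) for (k in c("IC", "TO")) {
      got <- ev$frame[ev$side == s & ev$kind == k]
      want <- gt$frame[gt$side == s & gt$kind == k]
      matched <- 0
      for (w in want) {
        hit <- got[abs(got - w) <= 3]
        if (length(hit)) { matched <- matched + 1; errs <- c(errs, min(abs(hit - w))) }
      }
      prec <- if (length(got)) matched / length(got) else 0
      rec <- matched / length(want)
      f1 <- c(f1, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
    }
  }
  expect_gte(mean(f1), 0.98)
  expect_lte(median(errs), 1)
})
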