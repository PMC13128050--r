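test_that("low-pass filter preserves DC, passes 1 Hz, and kills 15 Hz", {
  fs <- 60
  expect_equal(lowpass(rep(5, 200), fs), rep(5, 200), tolerance = 1e-6)
  tm <- seq(0, 10, by = 1 / fs)
  gain <- function(f) {
    y <- lowpass(sin(2 * pi * f * tm), fs)
    mid <- y[150:(length(y) - 150)]
    max(abs(mid))
  }
  expect_gt(gain(1), 0.99)
  expect_lt(gain(15), 0.10)
  g6 <- 20 * log10(gain(6))
  expect_gt(g6, -4); expect_lt(g6, -2)
})

test_that("the filter is zero-phase", {
  fs <- 60
  tm <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 2 * tm)
  y <- lowpass(x, fs)
  # cross-correlation peak at zero lag
  cc <- stats::ccf(x, y, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("too-short series are rejected by the filter", {
  expect_error(lowpass(rnorm(10), 60), "warm-up")
})

test_that("segmentation counts cycles and discards toe-off glitches", {
  fs <- 60
  ics <- c(10, 70, 130, 190, 250)
  tos <- c(45, 105, 165, 225)
  df <- rbind(data.frame(side = "left", kind = "IC", frame = ics),
              data.frame(side = "left", kind = "TO", frame = tos))
  df$time_s <- (df$frame - 1) / fs
  ev <- event_series(df, fs)
  ang <- matrix(rnorm(300 * 3), ncol = 3,
                dimnames = list(NULL, c("hip", "knee", "ankle")))
  cyc <- segment_cycles(ang, ev, "left", fs)
  expect_length(cyc, 4)
  expect_true(all(vapply(cyc, function(cy) cy$to_index > 1, logical(1))))

  # glitch: two TOs inside the first cycle
  df2 <- rbind(df, data.frame(side = "left", kind = "TO", frame = 50,
                              time_s = 49 / fs))
  ev2 <- event_series(df2, fs, validate = FALSE)
  cyc2 <- segment_cycles(ang, ev2, "left", fs)
  expect_length(cyc2, 3)
  expect_match(attr(cyc2, "discarded"), "2 toe-offs")
})

test_that("time normalization is exact for constant and linear cycles", {
  mk <- function(vals) list(side = "left", samples = matrix(vals, ncol = 1),
                            times = seq_along(vals) / 60, to_index = 40L,
                            start_frame = 1L)
  nc <- time_normalize(mk(rep(30, 101)))
  expect_equal(unname(nc$samples[, 1]), rep(30, 101))
  lin <- seq(0, 50, length.out = 101)
  nc <- time_normalize(mk(lin))
  expect_equal(unname(nc$samples[, 1]), 0.5 * (0:100), tolerance = 1e-9)
  expect_equal(nc$to_percent, 100 * 39 / 100)
})

test_that("normalization is idempotent on a 101-sample uniform cycle", {
  set.seed(4)
  w <- random_waveform()
  raw <- list(side = "left", samples = matrix(w, ncol = 1),
              times = seq(0, 1, length.out = 101), to_index = 61L,
              start_frame = 1L)
  nc <- time_normalize(raw)
  expect_equal(unname(nc$samples[, 1]), w, tolerance = 1e-9)
})

test_that("normalized extrema match a dense-resampling oracle", {
  fs <- 60
  dur <- 1.05
  tm <- seq(0, dur, by = 1 / fs)
  amp <- 37
  x <- amp * sin(2 * pi * tm / dur)
  raw <- list(side = "left", samples = matrix(x, ncol = 1), times = tm,
              to_index = 38L, start_frame = 1L)
  nc <- time_normalize(raw)
  expect_lt(abs(max(nc$samples[, 1]) - amp) / amp, 0.005)
  expect_error(time_normalize(list(samples = matrix(1:5), times = rep(0, 5),
                                   to_index = 2L, side = "left")),
               "10 frames")
})

test_that("hierarchical averaging follows the trial-then-limb-then-trial order", {
  mkcy <- function(val, side, trial, to = 60)
    structure(list(samples = matrix(val, nrow = 101, ncol = 3,
                                    dimnames = list(NULL, c("hip", "knee", "ankle"))),
                   to_percent = to, side = side, trial = trial),
              class = "normalized_cycle")
  # identical cycles: mean equals the cycle, sd 0
  rw <- average_waveforms(list(mkcy(7, "left", 1), mkcy(7, "right", 1),
                               mkcy(7, "left", 2), mkcy(7, "right", 2)))
  expect_equal(unique(as.vector(rw$mean)), 7)
  expect_equal(max(rw$sd), 0)
  # left 10, right 20 -> 15
  rw <- average_waveforms(list(mkcy(10, "left", 1), mkcy(20, "right", 1)))
  expect_equal(unique(as.vector(rw$mean)), 15)
  # unbalanced cycle counts: within-trial mean first, so 3 left cycles at 10
  # and 1 right at 20 still average to 15
  rw <- average_waveforms(list(mkcy(10, "left", 1), mkcy(10, "left", 1),
                               mkcy(10, "left", 1), mkcy(20, "right", 1)))
  expect_equal(unique(as.vector(rw$mean)), 15)
  expect_warning(average_waveforms(list(mkcy(10, "left", 1))), "one side missing")
})

test_that("hierarchical averaging matches a brute-force recomputation", {
  set.seed(88)
  for (rep in 1:100) {
    n_trials <- sample(2:4, 1)
    cycles <- list()
    store <- list()
    for (tr in seq_len(n_trials)) for (s in c("left", "right")) {
      for (k in seq_len(sample(1:3, 1))) {
        w <- matrix(rnorm(101 * 3, 20, 8), ncol = 3,
                    dimnames = list(NULL, c("hip", "knee", "ankle")))
        to <- runif(1, 55, 65)
        cycles[[length(cycles) + 1]] <- structure(
          list(samples = w, to_percent = to, side = s, trial = tr),
          class = "normalized_cycle")
        store[[length(store) + 1]] <- list(w = w, to = to, s = s, tr = tr)
      }
    }
    rw <- average_waveforms(cycles)
    # brute force: explicit three-level loop
    acc <- 0; acc_to <- 0
    tr_means <- list()
    for (tr in seq_len(n_trials)) {
      side_sum <- 0; side_n <- 0; side_to <- 0
      for (s in c("left", "right")) {
        el <- Filter(function(e) e$tr == tr && e$s == s, store)
        cw <- 0; cto <- 0
        for (e in el) { cw <- cw + e$w; cto <- cto + e$to }
        side_sum <- side_sum + cw / length(el)
        side_to <- side_to + cto / length(el)
        side_n <- side_n + 1
      }
      tr_means[[tr]] <- side_sum / side_n
      acc <- acc + side_sum / side_n
      acc_to <- acc_to + side_to / side_n
    }
    expect_equal(rw$mean, acc / n_trials, tolerance = 1e-12)
    expect_equal(rw$to_percent, acc_to / n_trials, tolerance = 1e-12)
    mu <- acc / n_trials
    v <- 0
    for (tm in tr_means) v <- v + (tm - mu)^2
    expect_equal(rw$sd, sqrt(v / (n_trials - 1)), tolerance = 1e-12)
  }
})

test_that("averaging commutes with constant shifts", {
  set.seed(9)
  base <- lapply(1:4, function(i)
    structure(list(samples = matrix(rnorm(101 * 3), ncol = 3,
                                    dimnames = list(NULL, c("hip", "knee", "ankle"))),
                   to_percent = 60,
                   side = c("left", "right")[1 + i %% 2],
                   trial = ceiling(i / 2)),
              class = "normalized_cycle"))
  shifted <- lapply(base, function(cy) { cy$samples <- cy$samples + 5; cy })
  expect_equal(average_waveforms(shifted)$mean,
               average_waveforms(base)$mean + 5, tolerance = 1e-12)
})
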