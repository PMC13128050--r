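# Independent brute-force oracles. These deliberately re-derive every
# quantity with explicit loops/scans, sharing no code with the package.

# explicit-window feature scan over a 101-sample waveform
oracle_features <- function(w, to_percent, mid = to_percent / 2) {
  i <- 0:100
  scan_max <- function(keep) { m <- -Inf; for (k in which(keep)) m <- max(m, w[k]); m }
  scan_min <- function(keep) { m <- Inf; for (k in which(keep)) m <- min(m, w[k]); m }
  list(
    rom = scan_max(rep(TRUE, 101)) - scan_min(rep(TRUE, 101)),
    max_stance = scan_max(i < to_percent),
    min_stance = scan_min(i < to_percent),
    max_st1 = scan_max(i < mid),
    max_st2 = scan_max(i >= mid & i < to_percent),
    max_swing = scan_max(i >= to_percent),
    min_pf_window = scan_min(i >= to_percent - 10 & i <= to_percent + 10),
    at_ic = w[1])
}

# hand-coded BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (k in (m - 1):1) if (m > 1) adj[k] <- min(adj[k], adj[k + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independently coded pooled-SD standardized mean difference
oracle_d <- function(m1, s1, n1, m2, s2, n2) {
  num <- (n1 - 1) * s1 * s1 + (n2 - 1) * s2 * s2
  (m1 - m2) / sqrt(num / (n1 + n2 - 2))
}

# O(n^2) peak scan: all strict local maxima (plateaus -> first frame),
# prominence by explicit outward scans, greedy min-distance by prominence
oracle_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  n <- length(x)
  cand <- c()
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j == n || x[j + 1] < x[i]) cand <- c(cand, i)
    }
  }
  if (!length(cand)) return(integer(0))
  prom <- sapply(cand, function(p) {
    lmin <- x[p]
    for (k in seq(p, 1)) { if (x[k] > x[p]) break; lmin <- min(lmin, x[k]) }
    rmin <- x[p]
    for (k in seq(p, n)) { if (x[k] > x[p]) break; rmin <- min(rmin, x[k]) }
    x[p] - max(lmin, rmin)
  })
  keep <- cand[prom >= min_prominence]
  pk <- prom[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  sel <- integer(0)
  for (o in order(-pk, keep)) {
    if (!length(sel) || all(abs(keep[o] - sel) >= min_distance))
      sel <- c(sel, keep[o])
  }
  sort(sel)
}

# random smooth 101-sample waveform (band-limited harmonic mixture)
random_waveform <- function() {
  t <- seq(0, 1, length.out = 101)
  w <- rnorm(1, 0, 10)
  for (h in 1:5) w <- w + rnorm(1, 0, 8 / h) * sin(2 * pi * h * t + runif(1, 0, 2 * pi))
  w
}

# minimal hand-built recording: supply relative AP signals, pelvis advances
# at constant speed; all other columns flat/zero offsets
toy_recording <- function(heel_rel_left, toe_rel_left,
                          heel_rel_right = heel_rel_left,
                          toe_rel_right = toe_rel_left,
                          fs = 60, v = 1.3,
                          heel_vert = NULL, toe_vert = NULL) {
  n <- length(heel_rel_left)
  tm <- (seq_len(n) - 1) / fs
  pel <- v * tm
  z0 <- rep(0, n)
  fr <- data.frame(
    time_s = tm, pelvis_ap_m = pel, pelvis_vert_m = rep(0.9, n),
    left_heel_ap_m = pel + heel_rel_left, left_heel_vert_m = heel_vert %||% z0,
    left_toe_ap_m = pel + toe_rel_left, left_toe_vert_m = toe_vert %||% z0,
    right_heel_ap_m = pel + heel_rel_right, right_heel_vert_m = heel_vert %||% z0,
    right_toe_ap_m = pel + toe_rel_right, right_toe_vert_m = toe_vert %||% z0,
    left_hip_sagittal_deg = z0, left_knee_sagittal_deg = z0,
    left_ankle_sagittal_deg = z0,
    right_hip_sagittal_deg = z0, right_knee_sagittal_deg = z0,
    right_ankle_sagittal_deg = z0)
  structure(list(meta = list(fs = fs, condition = "level",
                             geometry = rampgait::ramp_geometry(),
                             participant = "T01", group = "young", trial = 1L,
                             stance_fraction = 0.6),
                 frames = fr),
            class = "trial_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# feature table simulated directly at the representative-value level,
# for exercising the statistical tier in isolation
simulate_feature_table <- function(n_per_group = 20,
                                   conditions = c("level", "ascent", "descent"),
                                   participant_sd = 3, resid_sd = 2,
                                   cond_effects = c(level = 0, ascent = 5, descent = -3),
                                   group_effect = 0, interaction = NULL,
                                   beta_velocity = 2, base = 20) {
  rows <- list()
  for (g in c("young", "older")) {
    for (i in seq_len(n_per_group)) {
      pid <- paste0(substr(g, 1, 1), i)
      u <- rnorm(1, 0, participant_sd)
      for (cd in conditions) {
        v <- rnorm(1, 1.2, 0.15)
        y <- base + u + cond_effects[[cd]] + beta_velocity * (v - 1.2) +
          group_effect * (g == "older") + rnorm(1, 0, resid_sd)
        if (!is.null(interaction))
          y <- y + interaction * (g == "older" && cd == "ascent")
        rows[[length(rows) + 1]] <- data.frame(
          participant = pid, group = g, condition = cd, velocity = v, y = y)
      }
    }
  }
  do.call(rbind, rows)
}
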