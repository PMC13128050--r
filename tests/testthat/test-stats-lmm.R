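test_that("noiseless data generated from known effects are recovered", {
  # y determined exactly by group x condition cells plus velocity slope
  set.seed(50)
  d <- expand.grid(participant = sprintf("P%02d", 1:40),
                   condition = c("level", "ascent", "descent"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("P", "", d$participant)) <= 20,
                    "young", "older")
  d$velocity <- rnorm(nrow(d), 1.2, 0.15)
  cell <- c(level = 20, ascent = 25, descent = 17)
  d$y <- cell[d$condition] + 3 * (d$group == "older") +
    2 * (d$group == "older" & d$condition == "ascent") +
    1.5 * (d$velocity - 1.2)
  # a zero-residual response trips lme4's convergence heuristics even though
  # the estimates are exact; the assertions below verify the recovery
  fit <- suppressWarnings(fit_lmm(d, "y"))
  expect_lt(fit$residual_sd, 1e-6)
  # velocity slope recovered
  expect_equal(unname(fit$beta["velocity"]), 1.5, tolerance = 1e-6)
  # cell means recovered through the EMMs at the grand-mean velocity
  se <- simple_effects(fit, gate_on_interaction = FALSE)
  asc <- se[se$condition == "ascent", ]
  expect_equal(asc$estimate, -(3 + 2), tolerance = 1e-6)
  lev <- se[se$condition == "level", ]
  expect_equal(lev$estimate, -3, tolerance = 1e-6)
})

test_that("with velocity orthogonal to the factors, EMMs equal cell means", {
  # same velocity values in every cell -> exact orthogonality
  d <- expand.grid(i = 1:10, g = c("young", "older"),
                   condition = c("level", "ascent"), stringsAsFactors = FALSE)
  d$participant <- paste0(d$g, d$i)
  d$group <- d$g
  v <- seq(1.0, 1.45, length.out = 10)
  d$velocity <- v[d$i]
  set.seed(51)
  mu <- c(young.level = 20, older.level = 23, young.ascent = 26, older.ascent = 31)
  d$y <- mu[paste(d$group, d$condition, sep = ".")] + 0.5 * (d$velocity - mean(v)) +
    rep(rnorm(20, 0, 2), 2)[as.integer(factor(d$participant))] +
    rnorm(nrow(d), 0, 1)
  fit <- fit_lmm(d, "y")
  se <- simple_effects(fit, gate_on_interaction = FALSE)
  raw_diff <- vapply(c("level", "ascent"), function(cd)
    mean(d$y[d$group == "young" & d$condition == cd]) -
      mean(d$y[d$group == "older" & d$condition == cd]), numeric(1))
  got <- setNames(se$estimate, se$condition)[c("level", "ascent")]
  expect_equal(unname(got), unname(raw_diff), tolerance = 1e-6)
  # and the EMMs themselves equal the velocity-adjusted cell means = cell means
  emm <- se[se$condition == "level", c("emm_young", "emm_old")]
  expect_equal(unname(unlist(emm)),
               unname(c(mean(d$y[d$group == "young" & d$condition == "level"]),
                        mean(d$y[d$group == "older" & d$condition == "level"]))),
               tolerance = 1e-6)
})

test_that("the one-condition reduction reproduces the two-sample t test", {
  set.seed(52)
  d <- data.frame(participant = sprintf("P%02d", 1:40),
                  group = rep(c("young", "older"), each = 20),
                  condition = "level",
                  velocity = rnorm(40, 1.2, 0.1))
  d$y <- 20 + 2 * (d$group == "older") + rnorm(40, 0, 3)
  fit <- fit_lmm(d, "y", covariate = NULL)
  expect_false(fit$is_mixed)
  a <- anova_type3(fit)
  tt <- t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(a$F[a$term == "group"], unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(a$p[a$term == "group"], tt$p.value, tolerance = 1e-9)
  expect_equal(a$df_den[a$term == "group"], 38)
})

test_that("Satterthwaite df agree with the balanced-design closed form", {
  # balanced compound-symmetric design, no covariate imbalance:
  # between-group test df ~ n - 2, within tests df ~ (n - 2)(c - 1)
  set.seed(53)
  d <- expand.grid(participant = sprintf("P%02d", 1:40),
                   condition = c("level", "ascent", "descent"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("P", "", d$participant)) <= 20,
                    "young", "older")
  d$velocity <- 1.2   # constant; dropped from the design below
  u <- rnorm(40, 0, 3)
  d$y <- 20 + u[as.integer(factor(d$participant))] +
    2 * (d$condition == "ascent") + rnorm(nrow(d), 0, 2)
  fit <- fit_lmm(d, "y", covariate = NULL)
  a <- anova_type3(fit)
  expect_equal(a$df_den[a$term == "group"], 38, tolerance = 0.10 * 38)
  expect_equal(a$df_den[a$term == "condition"], 76, tolerance = 0.10 * 76)
  expect_equal(a$df_den[a$term == "group:condition"], 76, tolerance = 0.10 * 76)
})

test_that("interaction gating controls which contrasts are evaluated", {
  set.seed(54)
  d <- simulate_feature_table(n_per_group = 15, group_effect = 0,
                              interaction = NULL)
  fit <- fit_lmm(d, "y")
  se <- simple_effects(fit, gate_on_interaction = TRUE)
  # additive model: interaction should rarely pass the gate at this n;
  # regardless, the gate decision must match the interaction p-value
  expect_equal(unique(se$evaluated), unique(se$interaction_p < 0.05))
  se2 <- simple_effects(fit, gate_on_interaction = FALSE)
  expect_true(all(se2$evaluated))
})

test_that("non-evaluated contrasts stay out of the pooled FDR family", {
  set.seed(55)
  f <- simulate_feature_table(n_per_group = 12, interaction = 6)
  f$p_null <- f$y
  # second parameter: pure noise, no interaction
  f$flat <- rnorm(nrow(f), 20, 2)
  names(f)[names(f) == "y"] <- "strong"
  res <- lmm_battery(f, parameters = c("strong", "flat"))
  cc <- res$contrasts
  expect_true(all(is.na(cc$p_fdr[!cc$evaluated])))
  ev <- cc$evaluated
  if (any(ev)) expect_equal(cc$p_fdr[ev], fdr_adjust(cc$p[ev]))
  # every reported magnitude label agrees with its |d| band
  expect_equal(cc$magnitude, magnitude_label(cc$d))
})

test_that("singular fits are retained and flagged", {
  set.seed(56)
  d <- simulate_feature_table(n_per_group = 10, participant_sd = 0,
                              resid_sd = 1)
  fit <- fit_lmm(d, "y")
  expect_s3_class(fit, "gait_lmm")
  expect_true(is.finite(fit$residual_sd))
  expect_gte(fit$sigma2_participant, 0)
})
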