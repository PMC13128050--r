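#' Fit the velocity-adjusted linear mixed model for one parameter
#'
#' REML fit of `value ~ velocity + group * condition + (1 | participant)`,
#' the model used for each joint-angle parameter: walking velocity as a
#' covariate, age group as a between-participant factor, walking condition
#' as a within-participant factor, and a participant random intercept for
#' the repeated measures. Factors are coded with sum-to-zero contrasts so
#' type-III tests are meaningful.
#'
#' @param data data.frame with columns `participant`, `group`
#'   (young/older), `condition`, `velocity` (unless `covariate = NULL`),
#'   and the response.
#' @param response name of the response column.
#' @param covariate name of the covariate column (default `"velocity"`);
#'   `NULL` fits the unadjusted model.
#' @return object of class `gait_lmm`: list with the fitted model (`fit`),
#'   `response`, `beta`, `vcov_beta`, `sigma2_participant`, `sigma2_resid`,
#'   `residual_sd`, `loglik_reml`, `singular`, `is_mixed`. When every
#'   participant contributes a single observation the random intercept is
#'   unidentifiable and a fixed-effects (lm) fit is returned with
#'   `is_mixed = FALSE`.
#' @export
fit_lmm <- function(data, response, covariate = "velocity") {
  stopifnot(all(c("participant", "group", "condition", response)
                %in% names(data)))
  d <- data
  d$.y <- d[[response]]
  d$group <- factor(d$group, levels = c("young", "older"))
  d$condition <- factor(d$condition)
  d$participant <- factor(d$participant)
  contrasts(d$group) <- stats::contr.sum(nlevels(d$group))
  multi_cond <- nlevels(d$condition) > 1
  if (multi_cond) contrasts(d$condition) <- stats::contr.sum(nlevels(d$condition))
  rhs <- c(covariate, if (multi_cond) "group * condition" else "group")
  one_obs <- max(table(d$participant)) == 1
  if (one_obs) {
    fml <- stats::reformulate(rhs, response = ".y")
    fit <- stats::lm(fml, data = d)
    s2p <- 0
    s2e <- stats::sigma(fit)^2
    singular <- FALSE
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fml <- stats::reformulate(c(rhs, "(1 | participant)"), response = ".y")
    fit <- lmerTest::lmer(fml, data = d, REML = TRUE,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2p <- vc$vcov[vc$grp == "participant"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    singular <- lme4::isSingular(fit)
    ll <- as.numeric(stats::logLik(fit))
  }
  structure(list(fit = fit, response = response,
                 beta = if (one_obs) stats::coef(fit) else lme4::fixef(fit),
                 vcov_beta = as.matrix(stats::vcov(fit)),
                 sigma2_participant = s2p, sigma2_resid = s2e,
                 residual_sd = sqrt(s2e),
                 loglik_reml = ll,
                 singular = singular,
                 is_mixed = !one_obs,
                 has_interaction = multi_cond),
            class = "gait_lmm")
}

#' @export
print.gait_lmm <- function(x, ...) {
  cat(sprintf("<gait_lmm> %s: participant SD %.3f, residual SD %.3f%s\n",
              x$response, sqrt(x$sigma2_participant), x$residual_sd,
              if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' Type-III ANOVA with Satterthwaite degrees of freedom
#'
#' F tests of each fixed term (velocity, group, condition, group x
#' condition) with sum-to-zero coding and Satterthwaite denominator degrees
#' of freedom (obtained by numerical differentiation of the variance of the
#' estimable functions with respect to the variance parameters).
#'
#' @param lmm a [fit_lmm()] result.
#' @return data.frame: term, F, df_num, df_den, p.
#' @export
anova_type3 <- function(lmm) {
  stopifnot(inherits(lmm, "gait_lmm"))
  if (lmm$is_mixed) {
    a <- stats::anova(lmm$fit, type = 3, ddf = "Satterthwaite")
    return(data.frame(term = rownames(a),
                      F = a[["F value"]],
                      df_num = a[["NumDF"]],
                      df_den = a[["DenDF"]],
                      p = a[["Pr(>F)"]],
                      row.names = NULL))
  }
  # fixed-effects fallback: exact type-III F tests, residual df
  a <- car::Anova(lmm$fit, type = 3)
  keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
  data.frame(term = rownames(a)[keep],
             F = a[["F value"]][keep],
             df_num = a[["Df"]][keep],
             df_den = stats::df.residual(lmm$fit),
             p = a[["Pr(>F)"]][keep],
             row.names = NULL)
}

#' Group contrasts of estimated marginal means within each condition
#'
#' Estimated marginal means per group x condition, evaluated at the grand
#' mean of the velocity covariate, and young-minus-older contrasts with
#' Satterthwaite degrees of freedom. When `gate_on_interaction` is TRUE the
#' contrasts are only marked `evaluated` if the group x condition
#' interaction is significant (unadjusted p < `alpha_gate`), mirroring the
#' simple-main-effects convention; non-evaluated contrasts should be
#' excluded from any FDR family. The standardized effect size is the EMM
#' difference divided by the model's residual SD.
#'
#' @param lmm a [fit_lmm()] result.
#' @param gate_on_interaction gate contrasts on interaction significance.
#' @param alpha_gate gate threshold (default 0.05, unadjusted).
#' @return data.frame: parameter, condition, emm_young, emm_old, estimate,
#'   se, df, p, d, magnitude, interaction_p, evaluated.
#' @export
simple_effects <- function(lmm, gate_on_interaction = TRUE, alpha_gate = 0.05) {
  stopifnot(inherits(lmm, "gait_lmm"))
  a3 <- anova_type3(lmm)
  int_p <- a3$p[grepl(":", a3$term)]
  evaluated <- !gate_on_interaction || (length(int_p) == 1 && int_p < alpha_gate)
  spec_fml <- if (lmm$has_interaction) ~ group | condition else ~ group
  em <- if (lmm$is_mixed)
    emmeans::emmeans(lmm$fit, spec_fml, lmer.df = "satterthwaite")
  else emmeans::emmeans(lmm$fit, spec_fml)
  ems <- as.data.frame(em)
  prs <- as.data.frame(emmeans::contrast(em, method = "pairwise"))
  if (!lmm$has_interaction) {
    ems$condition <- "all"; prs$condition <- "all"
  }
  out <- do.call(rbind, lapply(seq_len(nrow(prs)), function(i) {
    cd <- as.character(prs$condition[i])
    ey <- ems$emmean[ems$group == "young" & ems$condition == cd]
    eo <- ems$emmean[ems$group == "older" & ems$condition == cd]
    d <- prs$estimate[i] / lmm$residual_sd
    data.frame(parameter = lmm$response, condition = cd,
               emm_young = ey, emm_old = eo,
               estimate = prs$estimate[i], se = prs$SE[i],
               df = prs$df[i], p = prs$p.value[i],
               d = d, magnitude = magnitude_label(d))
  }))
  out$interaction_p <- if (length(int_p)) int_p else NA_real_
  out$evaluated <- evaluated
  rownames(out) <- NULL
  out
}

#' Velocity-adjusted mixed-model comparisons for all joint-angle parameters
#'
#' Fits one LMM per parameter, runs the type-III tests, evaluates
#' group-within-condition contrasts for parameters with a significant
#' interaction, applies Benjamini-Hochberg correction to all evaluated
#' simple-effect p-values pooled across parameters and conditions, and
#' labels residual-SD effect sizes.
#'
#' @param features data.frame with `participant`, `group`, `condition`,
#'   `velocity` and the parameter columns.
#' @param parameters parameter column names
#'   (default [feature_parameter_names()]).
#' @param gate_on_interaction gate contrasts on interaction significance
#'   (default TRUE).
#' @return list with `fits` (named list of `gait_lmm`), `anova`
#'   (data.frame), `contrasts` (data.frame with pooled `p_fdr`, NA where
#'   not evaluated).
#' @export
lmm_battery <- function(features, parameters = feature_parameter_names(),
                        gate_on_interaction = TRUE) {
  fits <- list(); anv <- list(); ctr <- list()
  for (pm in parameters) {
    lmm <- fit_lmm(features, pm)
    fits[[pm]] <- lmm
    a <- anova_type3(lmm)
    a$parameter <- pm
    anv[[pm]] <- a
    ctr[[pm]] <- simple_effects(lmm, gate_on_interaction = gate_on_interaction)
  }
  contrasts <- do.call(rbind, ctr)
  contrasts$p_fdr <- NA_real_
  ev <- which(contrasts$evaluated)
  if (length(ev)) contrasts$p_fdr[ev] <- fdr_adjust(contrasts$p[ev])
  rownames(contrasts) <- NULL
  list(fits = fits, anova = do.call(rbind, c(anv, make.row.names = FALSE)),
       contrasts = contrasts)
}
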