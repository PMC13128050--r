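#' Pooled-SD Cohen's d
#'
#' Standardized mean difference `d = (m1 - m2) / s_p` with the pooled SD
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. The sign of
#' the difference is preserved.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return Cohen's d (numeric scalar).
#' @export
cohens_d_pooled <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(0)
    stop("zero pooled SD with unequal means: infinite effect size")
  }
  (m1 - m2) / sp
}

#' Effect-size magnitude label
#'
#' Half-open bands on |d|: negligible (< 0.2), small (< 0.5), medium
#' (< 0.8), large (>= 0.8).
#'
#' @param d Cohen's d (finite; vectorized).
#' @return character vector of labels.
#' @export
magnitude_label <- function(d) {
  stopifnot(all(is.finite(d)))
  a <- abs(d)
  ifelse(a < 0.2, "negligible",
         ifelse(a < 0.5, "small",
                ifelse(a < 0.8, "medium", "large")))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `adj_(i) = min_{j >= i} ( p_(j) * m / j )`,
#' capped at 1. Order-preserving and idempotent.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Shapiro-Wilk normality check
#'
#' Reporting-only normality assessment (never gates the pipeline).
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1) stop("constant input: Shapiro-Wilk undefined")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Between-group t tests for spatiotemporal parameters
#'
#' Independent two-tailed t tests (pooled variance by default; Welch
#' optionally) comparing young vs older per parameter and condition, with
#' Benjamini-Hochberg correction and pooled-SD Cohen's d. The default FDR
#' family is the set of conditions within each parameter
#' (`fdr_family = "per_parameter"`); `"global"` pools all p-values.
#'
#' @param features data.frame with columns `participant`, `group`
#'   (young/older), `condition`, and the parameter columns.
#' @param parameters character vector of parameter column names.
#' @param var_equal pooled-variance t test (default TRUE).
#' @param fdr_family `"per_parameter"` or `"global"`.
#' @return data.frame: parameter, condition, group means/SDs, t, df, p,
#'   p_fdr, d, magnitude.
#' @export
ttest_battery <- function(features,
                          parameters = c("cadence", "velocity", "step_length"),
                          var_equal = TRUE,
                          fdr_family = c("per_parameter", "global")) {
  fdr_family <- match.arg(fdr_family)
  rows <- list()
  for (pm in parameters) {
    for (cd in unique(features$condition)) {
      sub <- features[features$condition == cd, ]
      y <- sub[[pm]][sub$group == "young"]
      o <- sub[[pm]][sub$group == "older"]
      if (length(y) < 2 || length(o) < 2)
        stop("each group needs at least 2 participants for ", pm, "/", cd)
      tt <- stats::t.test(y, o, var.equal = var_equal)
      d <- cohens_d_pooled(mean(y), stats::sd(y), length(y),
                           mean(o), stats::sd(o), length(o))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = pm, condition = cd,
        mean_young = mean(y), sd_young = stats::sd(y), n_young = length(y),
        mean_older = mean(o), sd_older = stats::sd(o), n_older = length(o),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, d = d, magnitude = magnitude_label(d))
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  if (fdr_family == "per_parameter") {
    for (pm in parameters) {
      i <- out$parameter == pm
      out$p_fdr[i] <- fdr_adjust(out$p[i])
    }
  } else out$p_fdr <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}
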