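#' Prepare an amplitude table for mixed-effects modelling
#'
#' Applies the package's factor coding: SOA as a factor with reference level
#' 900 ms, Condition with reference STD, Group with reference TD. Rows must
#' be one observation per subject x SOA x condition.
#'
#' @param table data.frame with columns `subject_id`, `group`, `age`,
#'   `cln3_stage` (may be NA), `soa`, `condition`, `amplitude`
#' @return the recoded data.frame
#' @export
prepare_measure_table <- function(table) {
  need <- c("subject_id", "group", "age", "soa", "condition", "amplitude")
  if (!all(need %in% names(table)))
    stopf("invalid argument: table needs columns %s", paste(need, collapse = ", "))
  if (any(table$age <= 0)) stopf("invalid argument: ages must be positive")
  table$subject_id <- factor(table$subject_id)
  table$soa <- factor(as.character(table$soa),
                      levels = c("900", "450", "1800"))
  table$condition <- factor(table$condition, levels = c("STD", "DEV"))
  table$group <- factor(table$group, levels = c("TD", "CLN3"))
  table
}

#' Fit the study's linear mixed-effects models
#'
#' Two model families. `model = "group"` fits
#' `amplitude ~ SOA * Condition * Group + (random | subject)` on both
#' groups; `model = "score"` fits
#' `amplitude ~ SOA * Condition * Score + (random | subject)` within the
#' CLN3 group, with the clinical stage score as a continuous covariate.
#' Estimation is by REML by default. The random part defaults to a subject
#' intercept; `random = "age_slope"` honours the `(1 + Age | Subject)` form,
#' which with a single age per subject is degenerate (the fit is returned
#' with its singularity/convergence messages recorded, never silently).
#'
#' @param table a measure table (see [prepare_measure_table()])
#' @param model `"group"` or `"score"`
#' @param random `"intercept"` or `"age_slope"`
#' @param reml logical; REML (default) or ML
#' @param compute_anova logical; include term-wise F tests
#'   (Satterthwaite denominator df)
#' @return object of class `mmn_lme`: `fit` (the merMod), `coefficients`
#'   (beta, SE, df, t, p, 95% CI), `anova`, `logLik`, `warnings`, `spec`
#' @export
fit_lme <- function(table, model = c("group", "score"),
                    random = c("intercept", "age_slope"),
                    reml = TRUE, compute_anova = TRUE) {
  model <- match.arg(model)
  random <- match.arg(random)
  d <- prepare_measure_table(table)
  if (model == "score") {
    d <- d[d$group == "CLN3", , drop = FALSE]
    if (!nrow(d)) stopf("invalid argument: no CLN3 rows for the score model")
    d$score <- as.numeric(d$cln3_stage)
    fixed <- "soa * condition * score"
  } else {
    if (length(unique(d$group)) < 2 ||
        min(table(unique(d[c("subject_id", "group")])$group)) < 2)
      stopf("invalid argument: need at least 2 subjects per group")
    fixed <- "soa * condition * group"
  }
  re <- if (random == "age_slope") "(1 + age | subject_id)" else "(1 | subject_id)"
  fml <- stats::as.formula(paste("amplitude ~", fixed, "+", re))
  warns <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = d, REML = reml),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      warns <<- c(warns, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (lme4::isSingular(fit))
    warns <- c(warns, "singular random-effects structure")
  cf <- as.data.frame(summary(fit)$coefficients)
  names(cf) <- c("beta", "se", "df", "t", "p")[seq_len(ncol(cf))]
  crit <- qt(0.975, pmax(cf$df, 1))
  cf$ci_lo <- cf$beta - crit * cf$se
  cf$ci_hi <- cf$beta + crit * cf$se
  an <- if (compute_anova)
    tryCatch(stats::anova(fit), error = function(e) NULL) else NULL
  structure(list(fit = fit, coefficients = cf, anova = an,
                 logLik = as.numeric(logLik(fit)),
                 warnings = warns,
                 spec = list(model = model, random = random, reml = reml)),
            class = "mmn_lme")
}

#' @export
print.mmn_lme <- function(x, ...) {
  cat(sprintf("<mmn_lme> %s model (%s random part, %s)\n", x$spec$model,
              x$spec$random, if (x$spec$reml) "REML" else "ML"))
  print(round(x$coefficients, 4))
  if (length(x$warnings))
    cat("notes:", paste(unique(x$warnings), collapse = "; "), "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' Both models are refit by maximum likelihood (REML log-likelihoods are not
#' comparable across fixed-effects structures) and compared by
#' `chi^2 = 2 (logLik_full - logLik_reduced)` with df equal to the
#' parameter-count difference.
#'
#' @param fit_full,fit_reduced `mmn_lme` objects (or merMod fits) on the
#'   same data, with the reduced fixed-effects structure nested in the full
#' @return list `chi2`, `df`, `p`
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  mf <- if (inherits(fit_full, "mmn_lme")) fit_full$fit else fit_full
  mr <- if (inherits(fit_reduced, "mmn_lme")) fit_reduced$fit else fit_reduced
  if (stats::nobs(mf) != stats::nobs(mr))
    stopf("invalid argument: models were fit to different data")
  tf <- colnames(stats::model.matrix(mf))
  tr <- colnames(stats::model.matrix(mr))
  if (!all(tr %in% tf))
    stopf("invalid argument: models are not nested")
  mf_ml <- if (lme4::isREML(mf)) lme4::refitML(mf) else mf
  mr_ml <- if (lme4::isREML(mr)) lme4::refitML(mr) else mr
  llf <- logLik(mf_ml)
  llr <- logLik(mr_ml)
  df <- attr(llf, "df") - attr(llr, "df")
  chi2 <- max(0, 2 * (as.numeric(llf) - as.numeric(llr)))
  p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else 1
  list(chi2 = chi2, df = df, p = p)
}

#' Planned paired comparison of deviant vs standard amplitudes
#'
#' Paired t-test between per-subject DEV and STD window means. One-sided
#' alternatives yield one-sided confidence intervals. Zero-variance
#' differences are degenerate for the t statistic and are resolved by
#' continuity: identical vectors give t = 0 with two-sided p = 1, and a
#' constant nonzero difference gives p = 0 with a point CI.
#'
#' @param dev_values,std_values paired numeric vectors (n >= 3)
#' @param tail `"two"`, `"less"` (DEV < STD) or `"greater"`
#' @param conf_level confidence level (default 0.95)
#' @return list `t`, `df`, `p`, `ci`, `mean_diff`, `n`
#' @export
planned_paired_comparison <- function(dev_values, std_values,
                                      tail = c("two", "less", "greater"),
                                      conf_level = 0.95) {
  tail <- match.arg(tail)
  if (length(dev_values) != length(std_values) || length(dev_values) < 3)
    stopf("invalid argument: need paired vectors with n >= 3")
  d <- dev_values - std_values
  alt <- c(two = "two.sided", less = "less", greater = "greater")[[tail]]
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1,
                  p = if (tail == "two") 1 else 0.5,
                  ci = c(0, 0), mean_diff = 0, n = length(d)))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                ci = c(mean(d), mean(d)), mean_diff = mean(d),
                n = length(d)))
  }
  tt <- t.test(dev_values, std_values, paired = TRUE, alternative = alt,
               conf.level = conf_level)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = as.numeric(tt$conf.int),
       mean_diff = mean(d), n = length(d))
}
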