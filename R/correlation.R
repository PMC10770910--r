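#' Spearman correlation with percentile-bootstrap confidence interval
#'
#' Spearman's rho on midranks, with a paired-resampling percentile bootstrap
#' confidence interval; the association is called significant when the CI
#' excludes zero (the robust-correlation convention).
#'
#' @param x,y paired numeric vectors, n >= 5, no missing values
#' @param n_boot bootstrap resamples (default 1000)
#' @param alpha two-sided alpha for the CI (default 0.05)
#' @param seed integer seed for the resampling
#' @return object of class `correlation_result`: `rs`, `ci95`, `n_boot`,
#'   `significant`, `n`
#' @export
robust_spearman_bootstrap <- function(x, y, n_boot = 1000, alpha = 0.05,
                                      seed = 1L) {
  n <- length(x)
  if (length(y) != n || n < 5)
    stopf("invalid argument: need paired vectors with n >= 5")
  if (anyNA(x) || anyNA(y)) stopf("invalid argument: missing pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("undefined correlation: constant input")
  rs <- cor(x, y, method = "spearman")
  rb <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (sd(x[i]) == 0 || sd(y[i]) == 0) return(NA_real_)
      cor(x[i], y[i], method = "spearman")
    }, numeric(1))
  })
  ci <- unname(quantile(rb, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  structure(list(rs = rs, ci95 = ci, n_boot = n_boot,
                 significant = ci[1] > 0 || ci[2] < 0, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rs = %.3f, 95%% CI [%.3f, %.3f] (%s, n = %d)\n",
              x$rs, x$ci95[1], x$ci95[2],
              if (x$significant) "significant" else "n.s.", x$n))
  invisible(x)
}

#' Age-MMN correlation with SOAs concatenated
#'
#' Pools the (age, MMN amplitude) pairs of one group across all three SOAs
#' into a single bootstrap Spearman correlation (each subject contributes
#' one pair per SOA), and returns per-SOA linear fits for overlay plots.
#'
#' @param measures MMN measure table: one row per subject x SOA with columns
#'   `subject_id`, `group`, `age`, `soa`, `amplitude`
#' @param group `"TD"` or `"CLN3"`
#' @param n_boot,alpha,seed passed to [robust_spearman_bootstrap()]
#' @return list `correlation` (a `correlation_result`) and `per_soa_fits`
#'   (data.frame `soa`, `intercept`, `slope`)
#' @export
concatenated_age_correlation <- function(measures, group, n_boot = 1000,
                                         alpha = 0.05, seed = 1L) {
  d <- measures[measures$group == group, , drop = FALSE]
  if (!nrow(d)) stopf("invalid argument: group %s absent", group)
  soas <- sort(unique(measures$soa))
  if (!all(soas %in% d$soa))
    stopf("invalid argument: measures for all SOAs must be present")
  res <- robust_spearman_bootstrap(d$age, d$amplitude, n_boot = n_boot,
                                   alpha = alpha, seed = seed)
  fits <- do.call(rbind, lapply(soas, function(s) {
    di <- d[d$soa == s, ]
    cf <- coef(lm(amplitude ~ age, data = di))
    data.frame(soa = s, intercept = cf[1], slope = cf[2], row.names = NULL)
  }))
  list(correlation = res, per_soa_fits = fits)
}
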