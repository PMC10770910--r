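#' Simulate an amplitude measure table with known fixed effects
#'
#' Generates the long-format table the mixed-effects layer consumes (one row
#' per subject x SOA x condition) directly at the measure level:
#' `amplitude = X beta + b_subject + noise`, where `X` uses the package's
#' treatment coding (SOA reference 900, condition reference STD, group
#' reference TD). Used for parameter-recovery and calibration simulations
#' where the full EEG chain is not the object under test.
#'
#' @param n_td,n_cln3 group sizes
#' @param betas named vector of fixed-effect coefficients; names must match
#'   `colnames(model.matrix(~ soa * condition * group))` under the package
#'   coding. Missing terms default to zero.
#' @param sd_subject between-subject (random intercept) SD, uV
#' @param sd_resid residual SD, uV
#' @param seed integer seed
#' @return data.frame with columns `subject_id`, `group`, `age`,
#'   `cln3_stage`, `soa`, `condition`, `amplitude`; the true coefficient
#'   vector is attached as attribute `"betas"`
#' @export
simulate_measure_table <- function(n_td = 41, n_cln3 = 21,
                                   betas = c("(Intercept)" = 0.5,
                                             "conditionDEV" = -1.2,
                                             "groupCLN3" = 0.3,
                                             "conditionDEV:groupCLN3" = 0.4,
                                             "soa1800:conditionDEV:groupCLN3" = 0.8),
                                   sd_subject = 0.5, sd_resid = 0.5,
                                   seed = 1L) {
  n <- n_td + n_cln3
  d <- expand.grid(subject_index = seq_len(n),
                   soa = c(450, 900, 1800),
                   condition = c("STD", "DEV"),
                   stringsAsFactors = FALSE)
  d <- d[order(d$subject_index), ]
  with_seed(seed, {
    grp <- c(rep("TD", n_td), rep("CLN3", n_cln3))
    age <- c(rtruncnorm1(n_td, 13.9, 5.2, 6, 26),
             rtruncnorm1(n_cln3, 16.9, 5.5, 6, 28))
    stage <- c(rep(NA_integer_, n_td), sample(1:3, n_cln3, TRUE, c(9, 10, 6)))
    d$subject_id <- sprintf("S%03d", d$subject_index)
    d$group <- grp[d$subject_index]
    d$age <- age[d$subject_index]
    d$cln3_stage <- stage[d$subject_index]
    dd <- prepare_measure_table(transform(d, amplitude = 0))
    X <- stats::model.matrix(~ soa * condition * group, dd)
    beta_full <- setNames(numeric(ncol(X)), colnames(X))
    unknown <- setdiff(names(betas), names(beta_full))
    if (length(unknown))
      stopf("invalid argument: unknown coefficient(s) %s",
            paste(unknown, collapse = ", "))
    beta_full[names(betas)] <- betas
    b_subj <- rnorm(n, 0, sd_subject)
    dd$amplitude <- as.vector(X %*% beta_full) + b_subj[d$subject_index] +
      rnorm(nrow(dd), 0, sd_resid)
    out <- dd[, c("subject_id", "group", "age", "cln3_stage", "soa",
                  "condition", "amplitude")]
    attr(out, "betas") <- beta_full
    out
  })
}
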