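test_that("zero-noise balanced tables reproduce the exact least-squares solution", {
  tab <- simulate_measure_table(n_td = 6, n_cln3 = 6, sd_subject = 0,
                                sd_resid = 0, seed = 1)
  fit <- quiet(fit_lme(tab, compute_anova = FALSE))
  d <- prepare_measure_table(tab)
  ls_fit <- coef(lm(amplitude ~ soa * condition * group, data = d))
  expect_equal(fit$coefficients$beta, unname(ls_fit), tolerance = 1e-6)
  expect_equal(fit$coefficients$beta, unname(attr(tab, "betas")),
               tolerance = 1e-6)
  # degenerate fit is reported, never silent
  expect_true(length(fit$warnings) > 0)
})

test_that("the LME recovers known effects and honours the formula variants", {
  truth <- attr(simulate_measure_table(seed = 1), "betas")
  fit <- quiet(fit_lme(simulate_measure_table(seed = 2)))
  cf <- fit$coefficients
  key <- "soa1800:conditionDEV:groupCLN3"
  expect_lt(abs(cf[key, "beta"] - truth[key]), 4 * cf[key, "se"])
  expect_true(all(cf$ci_lo < cf$beta & cf$beta < cf$ci_hi))
  expect_true(is.finite(fit$logLik))
  expect_s3_class(fit$anova, "anova")

  # the (1 + Age | Subject) form is honoured but flagged as degenerate
  fit2 <- quiet(fit_lme(simulate_measure_table(seed = 3), random = "age_slope",
                        compute_anova = FALSE))
  expect_true(length(fit2$warnings) > 0)

  # the score model runs on the CLN3 subset
  fit3 <- quiet(fit_lme(simulate_measure_table(seed = 4), model = "score",
                        compute_anova = FALSE))
  expect_true("score" %in% rownames(fit3$coefficients) ||
                any(grepl("score", rownames(fit3$coefficients))))
})

test_that("likelihood-ratio tests compare nested ML refits", {
  tab <- simulate_measure_table(seed = 5)
  d <- prepare_measure_table(tab)
  full <- quiet(lmerTest::lmer(amplitude ~ soa * condition * group + age +
                                 (1 | subject_id), data = d, REML = TRUE))
  red <- quiet(lmerTest::lmer(amplitude ~ soa * condition * group +
                                (1 | subject_id), data = d, REML = TRUE))
  # identical models: chi2 = 0, p = 1
  same <- likelihood_ratio_test(red, red)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  lrt <- likelihood_ratio_test(full, red)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$df, 1)
  expect_true(lrt$p >= 0 && lrt$p <= 1)

  # a strong injected covariate is detected
  d2 <- d
  d2$amplitude <- d2$amplitude + 0.4 * d2$age
  f2 <- quiet(lmerTest::lmer(amplitude ~ soa * condition * group + age +
                               (1 | subject_id), data = d2, REML = TRUE))
  r2 <- quiet(lmerTest::lmer(amplitude ~ soa * condition * group +
                               (1 | subject_id), data = d2, REML = TRUE))
  expect_lt(likelihood_ratio_test(f2, r2)$p, 0.01)

  expect_error(likelihood_ratio_test(red, full), "not nested")
})

test_that("planned paired comparisons match their contracts and a permutation oracle", {
  # identical vectors: t = 0, two-sided p = 1
  same <- planned_paired_comparison(rep(1, 10), rep(1, 10))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # constant nonzero difference: p = 0, CI excludes 0
  shift <- planned_paired_comparison(rep(2, 10), rep(1, 10))
  expect_equal(shift$p, 0)
  expect_true(all(shift$ci > 0))

  set.seed(8)
  std <- rnorm(21)
  dev <- std - 0.8 + rnorm(21, 0, 0.9)
  res <- planned_paired_comparison(dev, std)
  tt <- t.test(dev - std)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)

  # one-sided variant gives a one-sided CI
  one <- planned_paired_comparison(dev, std, tail = "less")
  expect_equal(one$ci[1], -Inf)

  # sign-flip permutation oracle agrees within 0.02
  d <- dev - std
  t_obs <- res$t
  set.seed(9)
  perm_t <- replicate(4000, {
    s <- sample(c(-1, 1), 21, replace = TRUE)
    mean(s * d) / (sd(s * d) / sqrt(21))
  })
  p_perm <- mean(abs(perm_t) >= abs(t_obs))
  expect_lt(abs(p_perm - res$p), 0.02)

  expect_error(planned_paired_comparison(1:2, 2:3), "n >= 3")
})
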