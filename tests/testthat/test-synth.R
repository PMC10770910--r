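test_that("block schedules have exact deviant counts, spacing and constraints", {
  b <- build_block_schedule(900, 250, 0.15, seed = 1)
  expect_equal(nrow(b), 250)
  expect_equal(sum(b$role == "DEV"), 38)          # round(0.15 * 250)
  expect_equal(diff(b$onset), rep(900, 249))

  # conventional placement constraints: no block-initial or adjacent deviants
  for (s in 1:5) {
    bb <- build_block_schedule(450, 500, 0.15, seed = s)
    dev_pos <- which(bb$role == "DEV")
    expect_equal(length(dev_pos), 75)
    expect_gt(min(dev_pos), 3)
    expect_true(all(diff(dev_pos) > 1))
  }

  expect_true(all(build_block_schedule(450, 10, 0, seed = 1)$role == "STD"))

  b1 <- build_block_schedule(450, 500, 0.15, seed = 1)
  b2 <- build_block_schedule(450, 500, 0.15, seed = 2)
  expect_equal(sort(b1$role), sort(b2$role))      # same multiset
  expect_false(identical(b1$role, b2$role))       # different order

  expect_error(build_block_schedule(-450, 10, 0.1), "invalid")
  expect_error(build_block_schedule(450, 0, 0.1), "invalid")
})

test_that("session schedules honour the 14-block design with 1000 trials per SOA", {
  sch <- build_session_schedule(oddball_config(), seed = 7)
  expect_equal(nrow(sch$block_order), 14)
  expect_equal(as.vector(table(sch$block_order$soa)), c(2, 4, 8))
  expect_equal(unname(table(sch$events$soa)), array(c(1000, 1000, 1000)),
               ignore_attr = TRUE)
  expect_true(all(diff(sch$events$onset) > 0))

  # determinism and seed sensitivity
  expect_identical(sch, build_session_schedule(oddball_config(), seed = 7))
  expect_false(identical(sch$block_order,
                         build_session_schedule(oddball_config(), seed = 8)$block_order))

  # degenerate config: one SOA, one block
  one <- build_session_schedule(small_oddball(900, 25), seed = 3)
  expect_equal(nrow(one$block_order), 1)
  expect_equal(nrow(one$events), 25)
  expect_equal(diff(one$events$onset), rep(900, 24))

  bad <- oddball_config()
  bad$blocks_per_soa <- c("450" = 2)
  expect_error(build_session_schedule(bad, seed = 1), "invalid")
})

test_that("synthesized tones have the configured envelope lengths and ramps", {
  cfg <- oddball_config()
  for (fs in c(8000, 48000)) {
    cfg$sample_rate_audio <- fs
    expect_equal(length(synthesize_tone("DEV", cfg)) / fs * 1000, 180)
    expect_equal(length(synthesize_tone("STD", cfg)) / fs * 1000, 100)
  }
  # rectangular envelope: exact unit peak
  cfg$rise_fall <- 0
  w <- synthesize_tone("STD", cfg)
  expect_equal(max(abs(w)), 1)
  # ramped envelope attenuates the edges
  w2 <- synthesize_tone("STD", oddball_config())
  nr <- round(0.010 * 48000)
  expect_lt(max(abs(w2[seq_len(nr %/% 2)])), 0.6)
  expect_equal(max(abs(w2)), 1, tolerance = 1e-6)

  cfg2 <- oddball_config()
  cfg2$rise_fall <- 60
  expect_error(synthesize_tone("STD", cfg2), "invalid")
})

test_that("cohort sampling reproduces the study structure and effect model", {
  coh <- sample_cohort(cohort_spec(), seed = 1)
  expect_length(coh, 62)
  grp <- vapply(coh, `[[`, character(1), "group")
  expect_equal(sum(grp == "TD"), 41)
  expect_equal(sum(grp == "CLN3"), 21)
  stages <- vapply(coh, `[[`, integer(1), "cln3_stage")
  expect_true(all(is.na(stages[grp == "TD"])))
  expect_true(all(stages[grp == "CLN3"] %in% 1:3))
  ages <- vapply(coh, `[[`, numeric(1), "age")
  expect_true(all(ages >= 6 & ages <= 28))
  gains <- t(vapply(coh, `[[`, numeric(3), "mmn_gain"))
  expect_true(all(is.finite(gains)) && all(gains >= 0))

  # deterministic under seed
  expect_identical(coh, sample_cohort(cohort_spec(), seed = 1))

  # null cohort: no MMN anywhere
  null <- sample_cohort(cohort_spec(effect = null_effect_model()), seed = 2)
  expect_true(all(vapply(null, function(p) all(p$mmn_gain == 0), logical(1))))

  expect_error(sample_cohort(cohort_spec(n_td = 0, n_cln3 = 0)), "empty")
})

test_that("ERP templates inject the MMN with the right amplitude and polarity", {
  mon <- default_montage()
  p <- clean_profile()
  std <- erp_template("STD", p, 900, mon)
  dev <- erp_template("DEV", p, 900, mon)
  d <- dev - std
  tms <- attr(dev, "times")
  fz <- which(mon$name == "Fz")

  expect_equal(min(d[fz, ]), -1.5, tolerance = 1e-3)
  expect_equal(tms[which.min(d[fz, ])], 220, tolerance = 4)

  # polarity inversion at the mastoids
  peak <- which.min(d[fz, ])
  expect_gt(d[mon$name == "M1", peak], 0)
  expect_gt(d[mon$name == "M2", peak], 0)

  # zero gain: deviant identical to standard
  p0 <- clean_profile(gain = c("450" = 0, "900" = 0, "1800" = 0))
  expect_equal(erp_template("DEV", p0, 900, mon), erp_template("STD", p0, 900, mon))

  # effect monotonicity in the gain
  win <- tms >= 200 & tms <= 240
  wmean <- function(g) {
    pg <- clean_profile(gain = c("450" = g, "900" = g, "1800" = g))
    mean((erp_template("DEV", pg, 900, mon) - erp_template("STD", pg, 900, mon))[fz, win])
  }
  vals <- vapply(c(0.25, 0.5, 1, 2), wmean, numeric(1))
  expect_true(all(diff(abs(vals)) > 0))
  # and linear in the gain
  expect_equal(wmean(2) / wmean(1), 2, tolerance = 1e-9)

  expect_error(erp_template("DEV", p, 600, mon), "invalid")
})

test_that("rendered recordings conserve annotations and recover templates noiselessly", {
  p <- clean_profile()
  sch <- build_session_schedule(small_oddball(1800, 30), seed = 5)
  rec <- render_continuous_eeg(p, sch, default_montage(), rate = 128)
  expect_equal(nrow(rec$events), nrow(sch$events))
  expect_equal(rec$rate, 128)
  expect_equal(nrow(rec$data), 34)

  # bit-identical under the same profile seed
  rec2 <- render_continuous_eeg(p, sch, default_montage(), rate = 128)
  expect_identical(rec$data, rec2$data)

  # noiseless round-trip: every epoch equals the injected template
  ep <- epoch_recording(rec)
  tmpl_dev <- erp_template("DEV", p, 1800, default_montage(), rate = 128)
  tmpl_std <- erp_template("STD", p, 1800, default_montage(), rate = 128)
  for (i in seq_len(nrow(ep$labels))) {
    tmpl <- if (ep$labels$role[i] == "DEV") tmpl_dev else tmpl_std
    expect_equal(ep$data[i, , ], unclass(tmpl), ignore_attr = TRUE,
                 tolerance = 1e-6)
  }
})

test_that("blink transients appear at the configured rate and only then", {
  quietpf <- clean_profile(noise_sd = 0.5, blink_rate = 0)
  blinky <- clean_profile(noise_sd = 0.5, blink_rate = 30)
  r0 <- render_small(quietpf, 1800, 25)
  r1 <- render_small(blinky, 1800, 25)
  fp1 <- which(r0$channel_names == "Fp1")
  expect_lt(max(abs(r0$data[fp1, ])), 60)
  expect_gt(max(r1$data[fp1, ]), 80)
  expect_gt(attr(r1, "n_blinks"), 0)
})
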