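test_that("evoked averaging respects labels and the accepted mask", {
  nt <- 117
  d <- array(0, c(4, 3, nt))
  d[1, , ] <- 1; d[2, , ] <- 1; d[3, , ] <- -1; d[4, , ] <- 9
  ep <- make_epochs(d, roles = c("DEV", "DEV", "DEV", "DEV"))

  # two identical epochs -> evoked equals either
  ep2 <- ep; ep2$accepted <- c(TRUE, TRUE, FALSE, FALSE)
  ev <- average_evoked(ep2, "DEV", 900)
  expect_equal(unique(as.vector(ev$data)), 1)
  expect_equal(ev$n_trials, 2L)

  # +v and -v cancel
  ep3 <- ep; ep3$accepted <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(max(abs(average_evoked(ep3, "DEV", 900)$data)), 0)

  # rejected trials do not contribute
  ep4 <- ep; ep4$accepted <- c(TRUE, TRUE, TRUE, FALSE)
  ep5 <- ep; ep5$data <- ep$data[1:3, , , drop = FALSE]
  ep5$labels <- ep$labels[1:3, ]; ep5$accepted <- rep(TRUE, 3)
  expect_equal(average_evoked(ep4, "DEV", 900)$data,
               average_evoked(ep5, "DEV", 900)$data)

  expect_error(average_evoked(ep, "STD", 900), "empty condition")
})

test_that("inclusion logic applies the 50-trial rule with the 3-SD exception", {
  nt <- 117
  times <- (seq_len(nt) - 14) / 128 * 1000
  gm <- rep(0, nt)
  gs <- rep(1, nt)

  ok <- decide_inclusion(c(60, 70, 55), rep(0.5, nt), gm, gs, times)
  expect_true(ok$included)
  expect_equal(ok$reason, "enough_trials")

  exc <- decide_inclusion(c(42, 70, 55), rep(2.5, nt), gm, gs, times)
  expect_true(exc$included)
  expect_equal(exc$reason, "snr_exception")

  bad_wave <- rep(0.5, nt)
  bad_wave[60] <- 10                       # a 10-SD excursion after t = 0
  out <- decide_inclusion(c(42, 70, 55), bad_wave, gm, gs, times)
  expect_false(out$included)
  expect_equal(out$reason, "excluded_low_trials")

  # cohort bookkeeping: 25 candidates, 4 excluded, 1 exception -> 21 analyzed
  set.seed(10)
  waves <- lapply(1:25, function(i) rnorm(nt, 0, 0.2))
  counts <- rep(list(c(60, 60, 60)), 25)
  for (i in 21:25) counts[[i]] <- c(42, 60, 60)     # five low-trial subjects
  for (i in 22:25)                                  # four of them deviant,
    waves[[i]][20 + 2 * i] <- 40                    # each at its own latency
  wm <- colMeans(do.call(rbind, waves))
  ws <- apply(do.call(rbind, waves), 2, sd)
  dec <- lapply(1:25, function(i)
    decide_inclusion(counts[[i]], waves[[i]], wm, ws, times))
  expect_equal(sum(vapply(dec, `[[`, logical(1), "included")), 21)
  expect_equal(sum(vapply(dec, `[[`, character(1), "reason") == "snr_exception"), 1)
})

test_that("difference waves and MMN amplitudes follow their definitions", {
  mon <- default_montage()
  p <- clean_profile()
  dev <- make_evoked(erp_template("DEV", p, 900, mon, rate = 128), "DEV")
  std <- make_evoked(erp_template("STD", p, 900, mon, rate = 128), "STD")

  expect_equal(max(abs(difference_wave(dev, dev))), 0)

  d <- difference_wave(dev, std)
  fz <- which(mon$name == "Fz")
  # 128 Hz grid: the nearest sample sits 1.25 ms off the 220 ms peak
  expect_equal(min(d[fz, ]), -1.5, tolerance = 5e-3)
  expect_gt(d[mon$name == "M1", which.min(d[fz, ])], 0)

  # indicator construction: exactly -2 uV on the window at the composite
  nt <- ncol(dev$data)
  z <- matrix(0, 34, nt)
  dev2 <- make_evoked(z, "DEV")
  sel <- dev2$times >= 200 & dev2$times <= 240
  z2 <- z
  z2[match(c("F3", "Fz", "F4"), mon$name), sel] <- -2
  dev3 <- make_evoked(z2, "DEV")
  expect_equal(mmn_amplitude(dev3, dev2), -2)
  expect_equal(mmn_amplitude(dev2, dev2), 0)

  # composite/mean commutation
  by_electrode <- vapply(c("F3", "Fz", "F4"), function(e)
    mmn_amplitude(dev, std, electrodes = e), numeric(1))
  expect_equal(mmn_amplitude(dev, std), mean(by_electrode))

  # linearity in the injected effect
  p2 <- clean_profile(gain = c("450" = 2, "900" = 2, "1800" = 2))
  dev_x2 <- make_evoked(erp_template("DEV", p2, 900, mon, rate = 128), "DEV")
  expect_equal(mmn_amplitude(dev_x2, std), 2 * mmn_amplitude(dev, std),
               tolerance = 1e-9)

  bad <- std
  bad$times <- bad$times + 1
  expect_error(difference_wave(dev, bad), "common axis")
  expect_error(mmn_amplitude(dev, std, electrodes = "FCz"), "missing electrode")
})

test_that("grand averages are subject-weighted with pointwise SEM", {
  mon <- default_montage()
  nt <- 117
  a <- make_evoked(matrix(1, 34, nt))
  b <- make_evoked(matrix(-1, 34, nt))

  g1 <- grand_average(list(a))
  expect_equal(g1$data, a$data)

  g2 <- grand_average(list(a, b))
  expect_equal(max(abs(g2$data)), 0)

  g3 <- grand_average(list(a, a, a))
  expect_equal(g3$data, a$data)
  expect_equal(max(g3$sem), 0)
  expect_equal(g3$n_trials, 3L)

  expect_error(grand_average(list()), "empty")
})
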