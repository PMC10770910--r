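test_that("decimation preserves the passband and rejects aliased frequencies", {
  r50 <- resample_recording(sine_recording(50, rate = 512, dur = 6), 128)
  expect_equal(r50$rate, 128)
  mid <- 200:500
  expect_equal(max(abs(r50$data[1, mid])), 1, tolerance = 0.02)

  # 100 Hz is above the new Nyquist (64 Hz): attenuated by > 20 dB
  r100 <- resample_recording(sine_recording(100, rate = 512, dur = 6), 128)
  atten_db <- 20 * log10(sd(r100$data[1, mid]) / (1 / sqrt(2)))
  expect_lt(atten_db, -20)

  # DC passes (within the anti-alias filter's passband ripple)
  dc <- sine_recording(0, rate = 512, dur = 6)
  dc$data[] <- 7.5
  rdc <- resample_recording(dc, 128)
  expect_equal(rdc$data[1, mid], rep(7.5, length(mid)), tolerance = 0.02)

  # event indices move to the nearest new-grid sample
  ev <- sine_recording(10, rate = 512, dur = 6)
  ev$events <- data.frame(sample = c(1L, 513L, 1025L), role = "STD", soa = 900)
  rev_ <- resample_recording(ev, 128)
  expect_equal(rev_$events$sample, c(1L, 129L, 257L))

  expect_error(resample_recording(sine_recording(10), 100), "invalid")
})

test_that("the zero-phase Chebyshev II band-pass has the specified response", {
  # DC offset removed
  dc <- sine_recording(0, rate = 128, dur = 8)
  dc$data[] <- 100
  out <- bandpass_filter(dc)
  expect_lt(abs(mean(out$data[1, ])), 0.5)

  # 10 Hz (passband centre) preserved within 5%
  r10 <- bandpass_filter(sine_recording(10, rate = 128, dur = 8))
  mid <- 300:700
  expect_equal(max(abs(r10$data[1, mid])), 1, tolerance = 0.05)

  # 60 Hz (stopband) attenuated by at least the design attenuation
  r60 <- bandpass_filter(sine_recording(60, rate = 128, dur = 8))
  atten_db <- 20 * log10(sd(r60$data[1, mid]) / (1 / sqrt(2)))
  expect_lt(atten_db, -40)

  # events pass through untouched
  rec <- sine_recording(10, rate = 128, dur = 8)
  rec$events <- data.frame(sample = 5L, role = "DEV", soa = 450)
  expect_identical(bandpass_filter(rec)$events, rec$events)

  expect_error(bandpass_filter(sine_recording(10, rate = 64), filter_spec(c(1, 40))),
               "invalid")
})

test_that("bad-channel detection flags corrupted and flat channels, and only those", {
  p <- clean_profile(noise_sd = 5, blink_rate = 4, artifact_rate = 0)
  rec <- render_small(p, 900, 60)
  expect_identical(detect_bad_channels(rec), character(0))

  j <- which(rec$channel_names == "CP5")
  rec_bad <- rec
  set.seed(9)
  rec_bad$data[j, ] <- rnorm(ncol(rec$data), 0, 10 * sd(rec$data[j, ]))
  expect_identical(detect_bad_channels(rec_bad), "CP5")

  rec_flat <- rec
  rec_flat$data[j, ] <- 0
  expect_true("CP5" %in% detect_bad_channels(rec_flat))

  expect_error(detect_bad_channels(rec, n_neighbors = 2), "invalid")
  short <- rec
  short$data <- short$data[, 1:100]
  expect_error(detect_bad_channels(short), "insufficient")
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  mon <- default_montage()
  pos <- mmnpipe:::montage_positions(mon)
  ev0 <- data.frame(sample = integer(0), role = character(0), soa = numeric(0))

  # constant scalp field is reproduced exactly
  rec_c <- mmnpipe:::new_recording(matrix(3.3, 34, 10), 128, mon$name, ev0, mon)
  out_c <- interpolate_channels(rec_c, "Fz", mon)
  expect_equal(out_c$data[mon$name == "Fz", ], rep(3.3, 10), tolerance = 1e-6)

  # a field drawn from the spline basis is recovered in leave-one-out
  src <- c(0.3, 0.5, 0.81)
  src <- src / sqrt(sum(src^2))
  z <- mmnpipe:::spline_g(pos %*% src)
  rec_f <- mmnpipe:::new_recording(matrix(rep(z, 3), 34, 3), 128, mon$name,
                                   ev0, mon)
  for (ch in c("Fz", "C3", "Oz", "M1")) {
    got <- interpolate_channels(rec_f, ch, mon)$data[mon$name == ch, 1]
    expect_equal(got, z[mon$name == ch], tolerance = 0.01)   # 1% relative
  }

  # good channels untouched; empty bad set is the identity
  out1 <- interpolate_channels(rec_f, "Fz", mon)
  expect_identical(out1$data[mon$name != "Fz", ], rec_f$data[mon$name != "Fz", ])
  expect_identical(interpolate_channels(rec_f, character(0), mon), rec_f)

  expect_error(interpolate_channels(rec_f, mon$name[1:31], mon), "insufficient")
})

test_that("epoching uses the -100..800 ms grid and drops boundary trials", {
  p <- clean_profile(noise_sd = 1)
  rec <- render_small(p, 1800, 20)
  ep <- epoch_recording(rec)
  expect_true(0 %in% ep$times)
  expect_lte(ep$times[1], -100)
  expect_gte(ep$times[length(ep$times)], 800)
  expect_equal(diff(ep$times)[1], 1000 / 128, tolerance = 1e-9)
  expect_equal(dim(ep$data)[1], 20)
  expect_equal(ep$log$dropped_boundary, 0L)

  # an event too close to the recording edge is dropped and logged
  rec2 <- rec
  rec2$events <- rbind(data.frame(sample = 5L, role = "STD", soa = 1800,
                                  block = 1L), rec$events)
  ep2 <- epoch_recording(rec2)
  expect_equal(dim(ep2$data)[1], 20)
  expect_equal(ep2$log$dropped_boundary, 1L)

  rec3 <- rec
  rec3$events <- rec$events[0, ]
  expect_error(epoch_recording(rec3), "empty")
})

test_that("two-stage rejection removes amplitude violators and inflated epochs", {
  nt <- 117
  set.seed(3)
  base <- array(rnorm(105 * 4 * nt, 0, 5), c(105, 4, nt))
  # 5 epochs with an inflated post-stimulus maximum (x5)
  inflated <- 101:105
  base[inflated, , ] <- base[inflated, , ] * 5
  ep <- make_epochs(base)
  out <- reject_artifacts(ep)
  expect_true(all(!out$accepted[inflated]))
  expect_true(all(out$accepted[1:100]))

  # stage 1: a single 200 uV excursion rejects the trial
  ep2 <- make_epochs(array(rnorm(10 * 4 * nt, 0, 5), c(10, 4, nt)))
  ep2$data[3, 2, 50] <- 200
  out2 <- reject_artifacts(ep2)
  expect_false(out2$accepted[3])
  expect_equal(out2$log$rejected_stage1, 1L)

  # degenerate: identical epochs, SD = 0, nothing rejected at stage 2
  same <- array(1, c(8, 4, nt))
  out3 <- reject_artifacts(make_epochs(same))
  expect_true(all(out3$accepted))

  # monotone: never un-rejects
  ep4 <- make_epochs(array(rnorm(20 * 4 * nt, 0, 5), c(20, 4, nt)))
  ep4$accepted[1] <- FALSE
  expect_false(reject_artifacts(ep4)$accepted[1])
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  nt <- 117
  set.seed(4)
  ep <- make_epochs(array(rnorm(6 * 4 * nt, 10, 3), c(6, 4, nt)))
  out <- baseline_correct(ep)
  sel <- out$times >= -100 & out$times < 0
  bl <- apply(out$data[, , sel, drop = FALSE], c(1, 2), mean)
  expect_equal(max(abs(bl)), 0, tolerance = 1e-9)

  # constant-offset epoch becomes all-zero
  epc <- make_epochs(array(5, c(2, 4, nt)))
  expect_equal(max(abs(baseline_correct(epc)$data)), 0)

  # idempotent
  expect_equal(baseline_correct(out)$data, out$data, tolerance = 1e-12)
})

test_that("re-referencing zeroes the reference, rejects common mode, and falls back", {
  nt <- 117
  set.seed(5)
  ep <- make_epochs(array(rnorm(5 * 34 * nt), c(5, 34, nt)))
  out <- rereference(ep)
  expect_equal(out$reference, "T7")
  expect_equal(max(abs(out$data[, which(ep$channel_names == "T7"), ])), 0)

  # adding a common constant to all channels changes nothing
  ep_shift <- ep
  ep_shift$data <- ep$data + 12
  expect_equal(rereference(ep_shift)$data, out$data, tolerance = 1e-12)

  # T7 bad -> T8
  out2 <- rereference(ep, bad = "T7")
  expect_equal(out2$reference, "T8")
  expect_error(rereference(ep, bad = c("T7", "T8")), "unusable")

  # re-referencing commutes with baseline correction
  a <- baseline_correct(rereference(ep))
  b <- rereference(baseline_correct(ep))
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("ocular removal cleans blink activity and spares blink-free data", {
  # blink-free: pass-through (no component removed)
  p0 <- clean_profile(noise_sd = 1, blink_rate = 0)
  ep0 <- baseline_correct(epoch_recording(render_small(p0, 900, 40)))
  out0 <- remove_ocular_components(ep0, method = "template")
  expect_equal(out0$log$ocular$removed, 0L)
  expect_equal(out0$data, ep0$data)
  d0 <- mmn_amplitude(average_evoked(out0, "DEV", 900),
                      average_evoked(out0, "STD", 900))
  d0_raw <- mmn_amplitude(average_evoked(ep0, "DEV", 900),
                          average_evoked(ep0, "STD", 900))
  expect_lt(abs(d0 - d0_raw), 0.2)

  # with blinks: frontal variance drops by at least half
  p1 <- clean_profile(noise_sd = 1, blink_rate = 30)
  ep1 <- baseline_correct(epoch_recording(render_small(p1, 900, 120)))
  out1 <- remove_ocular_components(ep1, method = "template")
  fp <- match(c("Fp1", "Fp2"), ep1$channel_names)
  v_before <- var(as.vector(ep1$data[, fp, ]))
  v_after <- var(as.vector(out1$data[, fp, ]))
  expect_lt(v_after, 0.5 * v_before)
  # and the MMN measurement survives (18 deviant trials of measurement noise)
  d1 <- mmn_amplitude(average_evoked(out1, "DEV", 900),
                      average_evoked(out1, "STD", 900))
  expect_lt(abs(d1 - (-1.09)), 1)

  # ICA mode: bounded removal, finite output, frontal variance reduced
  out2 <- remove_ocular_components(ep1, method = "ica", seed = 2)
  expect_lte(out2$log$ocular$removed, 2)
  expect_true(all(is.finite(out2$data)))

  ep_small <- ep1
  ep_small$accepted[-(1:10)] <- FALSE
  expect_error(remove_ocular_components(ep_small), "20 accepted")
})
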