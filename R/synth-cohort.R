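#' Effect model for synthetic cohorts
#'
#' Encodes how the MMN generator gain depends on group, SOA and age.
#' `mmn_gain` is a dimensionless multiplier on the base MMN amplitude
#' (-1.5 uV at Fz by default, see [erp_template()]).
#'
#' Defaults encode the qualitative pattern the pipeline is designed to
#' detect: typically developing (TD) listeners produce an MMN of similar
#' size at all three SOAs, growing with age; the clinical (CLN3) group has
#' its largest MMN at the 900 ms SOA, a reduced MMN at 450 ms, essentially
#' none at 1800 ms, and an MMN that shrinks with age.
#'
#' @param td_gain named gain per SOA for an average-aged TD subject
#' @param cln3_gain named gain per SOA for an average-aged CLN3 subject
#' @param td_age_slope,cln3_age_slope relative gain change per decade of age
#'   (positive = stronger with age); applied around the group mean age
#' @param gain_jitter_sd lognormal SD of between-subject gain variability
#' @return list of class `effect_model`
#' @export
effect_model <- function(td_gain = c("450" = 1, "900" = 1, "1800" = 1),
                         cln3_gain = c("450" = 0.55, "900" = 1.0, "1800" = 0.05),
                         td_age_slope = 0.35,
                         cln3_age_slope = -0.45,
                         gain_jitter_sd = 0.25) {
  out <- list(td_gain = td_gain, cln3_gain = cln3_gain,
              td_age_slope = td_age_slope, cln3_age_slope = cln3_age_slope,
              gain_jitter_sd = gain_jitter_sd)
  class(out) <- "effect_model"
  out
}

#' Null effect model (no MMN anywhere)
#' @return an [effect_model()] with all gains, slopes and jitter set to zero
#' @export
null_effect_model <- function() {
  effect_model(td_gain = c("450" = 0, "900" = 0, "1800" = 0),
               cln3_gain = c("450" = 0, "900" = 0, "1800" = 0),
               td_age_slope = 0, cln3_age_slope = 0, gain_jitter_sd = 0)
}

#' Cohort specification for the synthetic study
#'
#' Group sizes, age distributions and disease-stage mix default to the
#' emulated study: 41 TD participants (ages 13.9 +/- 5.2 y, range 6-26) and
#' 21 CLN3 participants (16.9 +/- 5.5 y, range 6-28) with stages 1:2:3 mixed
#' 9:10:6. Noise and artifact rates are plausible resting-EEG values.
#'
#' @param n_td,n_cln3 group sizes (each >= 1 unless the other is > 0)
#' @param td_age,cln3_age c(mean, sd, min, max) in years; ages are drawn from
#'   a truncated normal
#' @param stage_weights relative frequency of CLN3 stages 1..3
#' @param effect an [effect_model()]
#' @param noise_sd background-EEG amplitude per channel, uV (1/f process)
#' @param blink_rate ocular blinks per minute
#' @param artifact_rate movement artifacts per minute
#' @param bad_channel_prob probability a subject has one corrupted channel
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_td = 41, n_cln3 = 21,
                        td_age = c(13.9, 5.2, 6, 26),
                        cln3_age = c(16.9, 5.5, 6, 28),
                        stage_weights = c(9, 10, 6),
                        effect = effect_model(),
                        noise_sd = 6,
                        blink_rate = 6,
                        artifact_rate = 0.5,
                        bad_channel_prob = 0.15) {
  if (n_td + n_cln3 < 1) stopf("invalid argument: empty cohort")
  out <- list(n_td = n_td, n_cln3 = n_cln3, td_age = td_age,
              cln3_age = cln3_age, stage_weights = stage_weights,
              effect = effect, noise_sd = noise_sd, blink_rate = blink_rate,
              artifact_rate = artifact_rate,
              bad_channel_prob = bad_channel_prob)
  class(out) <- "cohort_spec"
  out
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Sample a cohort of subject profiles
#'
#' Draws ages, CLN3 stages, per-SOA MMN generator gains (group- and
#' age-dependent, with between-subject lognormal jitter, floored at zero)
#' and per-subject nuisance parameters. Reproducible under `seed`.
#'
#' @param spec a [cohort_spec()]
#' @param seed integer master seed
#' @param montage montage used to pick candidate bad channels
#' @return list of `subject_profile` lists with fields `subject_id`, `group`,
#'   `age`, `cln3_stage` (NA for TD), `mmn_gain` (named per SOA), `noise_sd`,
#'   `blink_rate`, `artifact_rate`, `bad_channels`, `seed`
#' @examples
#' cohort <- sample_cohort(cohort_spec(), seed = 1)
#' length(cohort)   # 62
#' @export
sample_cohort <- function(spec = cohort_spec(), seed = 1L,
                          montage = default_montage()) {
  n <- spec$n_td + spec$n_cln3
  if (n < 1) stopf("invalid argument: empty cohort")
  seeds <- derive_seeds(seed, n)
  # reference/measurement channels are never simulated as subject-specific
  # bad channels so the frontal composite and T7/T8 reference always exist
  candidates <- setdiff(montage$name, c("F3", "Fz", "F4", "T7", "T8"))
  eff <- spec$effect
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      td <- i <= spec$n_td
      ar <- if (td) spec$td_age else spec$cln3_age
      age <- rtruncnorm1(1, ar[1], ar[2], ar[3], ar[4])
      stage <- if (td) NA_integer_ else
        sample(1:3, 1, prob = spec$stage_weights)
      base <- if (td) eff$td_gain else eff$cln3_gain
      slope <- if (td) eff$td_age_slope else eff$cln3_age_slope
      agef <- 1 + slope * (age - ar[1]) / 10
      jit <- if (eff$gain_jitter_sd > 0)
        exp(rnorm(1, 0, eff$gain_jitter_sd)) else 1
      gain <- setNames(pmax(0, base * agef * jit), names(base))
      bad <- if (runif(1) < spec$bad_channel_prob)
        sample(candidates, 1) else character(0)
      structure(list(
        subject_id = sprintf("%s%02d", if (td) "TD" else "CLN3",
                             if (td) i else i - spec$n_td),
        group = if (td) "TD" else "CLN3",
        age = age, cln3_stage = stage, mmn_gain = gain,
        noise_sd = spec$noise_sd, blink_rate = spec$blink_rate,
        artifact_rate = spec$artifact_rate,
        bad_channels = bad, seed = seeds[i]), class = "subject_profile")
    })
  })
}

# Smooth dipolar scalp maps. `mmn_map` is normalized so Fz = 1 (frontal
# positive weights, mastoids negative -> a negative MMN source appears
# negative frontally and positive at the mastoids).
mmn_scalp_map <- function(montage) {
  w <- montage$y + 0.6 * montage$z
  w / w[montage$name == "Fz"]
}

aud_scalp_map <- function(montage) {
  w <- 0.5 * montage$y + 0.9 * montage$z
  w / w[montage$name == "Cz"]
}

blink_scalp_map <- function(montage) {
  w <- pmax(0, montage$y)^4
  w / max(w)
}

#' Event-related potential template for one subject and condition
#'
#' The standard-tone template is a generic auditory response: an N1-like
#' negativity (100 ms) and P2-like positivity (190 ms) with a fronto-central
#' scalp distribution. The deviant template adds the mismatch response: a
#' Gaussian-in-time negativity centred at 220 ms (FWHM 40 ms) whose peak at
#' Fz is `-(base_amplitude * mmn_gain[soa])`, spatially distributed as a
#' fixed dipolar map (frontal negative, mastoid positive).
#'
#' @param role `"STD"` or `"DEV"`
#' @param profile a `subject_profile` (only `mmn_gain` is used)
#' @param soa SOA in ms (selects the gain)
#' @param montage an `mmn_montage`
#' @param rate sampling rate, Hz
#' @param window epoch support in ms, default `c(-100, 800)`
#' @param base_amplitude MMN magnitude at Fz for gain 1, uV (default 1.5)
#' @return channels x time matrix (uV) with attribute `"times"` (ms)
#' @export
erp_template <- function(role, profile, soa, montage = default_montage(),
                         rate = 512, window = c(-100, 800),
                         base_amplitude = 1.5) {
  soa_key <- as.character(soa)
  if (role == "DEV" && !soa_key %in% names(profile$mmn_gain))
    stopf("invalid argument: no mmn_gain entry for SOA %s", soa_key)
  pre <- ceiling(-window[1] * rate / 1000)
  post <- ceiling(window[2] * rate / 1000)
  t_ms <- (seq(-pre, post)) / rate * 1000
  gauss <- function(mu, sdv) exp(-(t_ms - mu)^2 / (2 * sdv^2))
  aud <- aud_scalp_map(montage)
  x <- outer(aud, -3.0 * gauss(100, 18) + 2.2 * gauss(190, 30))
  if (role == "DEV") {
    g <- profile$mmn_gain[soa_key]
    x <- x + outer(mmn_scalp_map(montage),
                   -base_amplitude * g * gauss(220, 40 / 2.355))
  }
  rownames(x) <- montage$name
  attr(x, "times") <- t_ms
  x
}

new_recording <- function(data, rate, channel_names, events, montage = NULL) {
  stopifnot(nrow(data) == length(channel_names))
  if (nrow(events) && (min(events$sample) < 1 || max(events$sample) > ncol(data)))
    stopf("invalid argument: event sample indices out of bounds")
  structure(list(data = data, rate = rate, channel_names = channel_names,
                 events = events, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  invisible(x)
}

# 1/f background noise, spatially smoothed over the scalp. Synthesized
# directly in the frequency domain (complex-Gaussian spectrum with 1/sqrt(f)
# amplitude, one inverse FFT) at an FFT-friendly length.
pink_noise <- function(n, nch, rate, positions, smooth_sigma = 0.7) {
  N <- nextn(n, c(2, 3, 5))
  f <- c(0, seq_len(N - 1)) * rate / N
  f <- pmin(f, rate - f)              # two-sided spectrum
  amp <- 1 / sqrt(pmax(f, 0.5))
  spec <- matrix(complex(real = rnorm(N * nch), imaginary = rnorm(N * nch)),
                 N, nch) * amp
  x <- Re(mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
  d2 <- as.matrix(stats::dist(positions))^2
  K <- exp(-d2 / (2 * smooth_sigma^2))
  K <- K / rowSums(K)
  x <- x %*% t(K)
  sc <- apply(x, 2, sd)
  sweep(x, 2, ifelse(sc > 0, sc, 1), "/")
}

#' Render a continuous synthetic EEG recording
#'
#' Superimposes event-locked ERP templates on spatially smoothed 1/f
#' background noise, a posterior alpha-band oscillation, frontally dominant
#' blink transients, sporadic broad-band movement artifacts, and (optionally)
#' corrupted high-variance channels. Annotations carry role, SOA and block
#' for every scheduled trial.
#'
#' @param profile a `subject_profile`
#' @param schedule a `session_schedule`
#' @param montage an `mmn_montage`
#' @param rate acquisition sampling rate, Hz (512 by default)
#' @param base_amplitude MMN base amplitude passed to [erp_template()]
#' @return an `eeg_recording` (channels x samples, uV)
#' @export
render_continuous_eeg <- function(profile, schedule,
                                  montage = default_montage(), rate = 512,
                                  base_amplitude = 1.5) {
  ev <- schedule$events
  if (!nrow(ev)) stopf("invalid argument: empty schedule")
  n <- ceiling((max(ev$onset) + 1000) / 1000 * rate)
  nch <- nrow(montage)
  pos <- montage_positions(montage)
  with_seed(profile$seed, {
    x <- if (profile$noise_sd > 0)
      pink_noise(n, nch, rate, pos) * profile$noise_sd
    else matrix(0, n, nch)

    if (profile$noise_sd > 0) {       # posterior-dominant alpha rhythm
      tt <- (seq_len(n) - 1) / rate
      pw <- pmax(0, -montage$y) + 0.2
      x <- x + outer(0.4 * profile$noise_sd * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)),
                     pw / max(pw))
    }

    # event-locked templates (post-stimulus part only)
    samp <- round(ev$onset / 1000 * rate) + 1L
    tmpl <- list()
    for (soa in unique(ev$soa)) for (role in c("STD", "DEV")) {
      tm <- erp_template(role, profile, soa, montage, rate,
                         window = c(0, 800), base_amplitude = base_amplitude)
      tmpl[[paste(role, soa)]] <- t(tm)
    }
    for (i in seq_len(nrow(ev))) {
      tm <- tmpl[[paste(ev$role[i], ev$soa[i])]]
      idx <- samp[i]:min(n, samp[i] + nrow(tm) - 1L)
      x[idx, ] <- x[idx, ] + tm[seq_along(idx), ]
    }

    dur_min <- n / rate / 60
    if (profile$blink_rate > 0) {     # blink transients
      nb <- rpois(1, profile$blink_rate * dur_min)
      bmap <- blink_scalp_map(montage)
      half <- round(0.15 * rate)
      kern <- exp(-(seq(-half, half) / (0.05 * rate))^2 / 2)
      for (b in seq_len(nb)) {
        c0 <- sample.int(n - 2 * half, 1) + half
        amp <- runif(1, 100, 200)
        idx <- (c0 - half):(c0 + half)
        x[idx, ] <- x[idx, ] + outer(amp * kern, bmap)
      }
      attr(x, "n_blinks") <- nb
    }

    if (!is.null(profile$artifact_rate) && profile$artifact_rate > 0) {
      na <- rpois(1, profile$artifact_rate * dur_min)
      for (a in seq_len(na)) {
        len <- round(runif(1, 0.2, 0.4) * rate)
        s0 <- sample.int(n - len, 1)
        wmap <- runif(nch, 0.4, 1)
        x[s0:(s0 + len - 1), ] <- x[s0:(s0 + len - 1), ] +
          outer(rnorm(len, 0, runif(1, 60, 90)), wmap)
      }
    }

    for (bc in profile$bad_channels) {
      j <- match(bc, montage$name)
      x[, j] <- rnorm(n, 0, 10 * max(profile$noise_sd, 1))
    }

    events <- data.frame(sample = samp, role = ev$role, soa = ev$soa,
                         block = ev$block_index, stringsAsFactors = FALSE)
    rec <- new_recording(t(x), rate, montage$name, events, montage)
    attr(rec, "n_blinks") <- attr(x, "n_blinks")
    rec
  })
}
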