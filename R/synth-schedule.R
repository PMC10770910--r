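#' Oddball paradigm configuration
#'
#' Parameters of the duration-oddball stimulation protocol. Defaults describe
#' the standard protocol: 1000 Hz tones with 10 ms rise/fall ramps, 100 ms
#' standards (85%) and 180 ms duration deviants (15%), presented at stimulus
#' onset asynchronies (SOA) of 450, 900 or 1800 ms in separate blocks --
#' 2 blocks of 500 trials at 450 ms, 4 of 250 at 900 ms and 8 of 125 at
#' 1800 ms, i.e. 14 blocks and 1000 trials per SOA condition.
#'
#' @param tone_freq carrier frequency, Hz
#' @param std_duration,dev_duration tone durations, ms (deviant must be longer)
#' @param rise_fall ramp duration, ms (applied at onset and offset)
#' @param deviant_prop proportion of deviant trials, strictly in (0, 1)
#'   (0 is additionally allowed in [build_block_schedule()] for null blocks)
#' @param soas SOA values, ms
#' @param blocks_per_soa named integer vector, blocks per SOA
#' @param trials_per_block named integer vector, trials per block per SOA
#' @param sample_rate_audio audio synthesis rate, Hz
#' @param inter_block_gap silence between blocks, ms
#' @return an object of class `oddball_config` (validated list)
#' @examples
#' cfg <- oddball_config()
#' cfg$soas
#' @export
oddball_config <- function(tone_freq = 1000,
                           std_duration = 100,
                           dev_duration = 180,
                           rise_fall = 10,
                           deviant_prop = 0.15,
                           soas = c(450, 900, 1800),
                           blocks_per_soa = c("450" = 2, "900" = 4, "1800" = 8),
                           trials_per_block = c("450" = 500, "900" = 250, "1800" = 125),
                           sample_rate_audio = 48000,
                           inter_block_gap = 2000) {
  cfg <- list(tone_freq = tone_freq, std_duration = std_duration,
              dev_duration = dev_duration, rise_fall = rise_fall,
              deviant_prop = deviant_prop, soas = soas,
              blocks_per_soa = blocks_per_soa,
              trials_per_block = trials_per_block,
              sample_rate_audio = sample_rate_audio,
              inter_block_gap = inter_block_gap)
  validate_oddball_config(cfg)
  class(cfg) <- "oddball_config"
  cfg
}

validate_oddball_config <- function(cfg) {
  if (cfg$deviant_prop <= 0 || cfg$deviant_prop >= 1)
    stopf("invalid argument: deviant_prop must be in (0, 1)")
  if (cfg$dev_duration <= cfg$std_duration)
    stopf("invalid argument: dev_duration must exceed std_duration")
  if (any(cfg$soas <= cfg$dev_duration))
    stopf("invalid argument: every SOA must exceed the deviant duration")
  if (2 * cfg$rise_fall > cfg$std_duration)
    stopf("invalid argument: rise/fall ramps exceed the standard tone duration")
  key <- as.character(cfg$soas)
  if (!all(key %in% names(cfg$blocks_per_soa)) ||
      !all(key %in% names(cfg$trials_per_block)))
    stopf("invalid argument: blocks_per_soa / trials_per_block must name every SOA")
  invisible(cfg)
}

#' Build the trial schedule for one stimulation block
#'
#' Trials are placed at exact multiples of the SOA. Deviant placement uses
#' exact-count randomization: exactly `round(deviant_prop * n_trials)` trials
#' are deviants, the first three trials of a block are always standards, and
#' two deviants never occur back to back (conventional constraints for MMN
#' designs; proportions are therefore exactly testable).
#'
#' @param soa stimulus onset asynchrony, ms
#' @param n_trials number of trials in the block
#' @param deviant_prop deviant proportion in `[0, 1)`
#' @param seed integer seed for the placement randomization
#' @return data.frame with columns `onset` (ms from block start), `role`
#'   (`"STD"`/`"DEV"`), `soa`, `block_index`
#' @examples
#' b <- build_block_schedule(900, 250, 0.15, seed = 1)
#' sum(b$role == "DEV")   # 38
#' @export
build_block_schedule <- function(soa, n_trials, deviant_prop, seed = 1L,
                                 block_index = 1L) {
  assert_scalar_pos(soa, "soa")
  assert_scalar_pos(n_trials, "n_trials")
  if (deviant_prop < 0 || deviant_prop >= 1)
    stopf("invalid argument: deviant_prop must be in [0, 1)")
  n_trials <- as.integer(n_trials)
  n_dev <- as.integer(round(deviant_prop * n_trials))
  role <- rep("STD", n_trials)
  if (n_dev > 0) {
    role[place_deviants(n_trials, n_dev, seed)] <- "DEV"
  }
  data.frame(onset = (seq_len(n_trials) - 1) * soa,
             role = role, soa = soa, block_index = as.integer(block_index),
             stringsAsFactors = FALSE)
}

# Random deviant positions: none in the first `lead_in` trials, no two
# adjacent. Sampled uniformly over the valid sets by the gap bijection:
# strictly non-adjacent k-subsets of 1..m correspond one-to-one to plain
# k-subsets of 1..(m-k+1) via y_i = x_(i) + (i-1).
place_deviants <- function(n_trials, n_dev, seed, lead_in = 3L) {
  m <- n_trials - lead_in
  if (n_dev > ceiling(m / 2))
    stopf("invalid argument: cannot place %d non-adjacent deviants in %d trials",
          n_dev, n_trials)
  with_seed(seed, {
    x <- sort(sample.int(m - n_dev + 1L, n_dev))
    lead_in + x + seq_len(n_dev) - 1L
  })
}

#' Build a full session schedule
#'
#' Concatenates all configured blocks in randomized order with a silent
#' inter-block gap. Under the default configuration this yields 14 blocks and
#' 1000 trials per SOA condition.
#'
#' @param config an [oddball_config()]
#' @param seed integer seed (block order and deviant placements)
#' @return object of class `session_schedule`: a list with `events`
#'   (data.frame `onset`, `role`, `soa`, `block_index`; onsets are ms from
#'   session start) and `block_order` (data.frame `soa`, `block_index`)
#' @examples
#' sch <- build_session_schedule(oddball_config(), seed = 7)
#' nrow(sch$block_order)     # 14
#' table(sch$events$soa)     # 1000 trials each
#' @export
build_session_schedule <- function(config = oddball_config(), seed = 1L) {
  validate_oddball_config(config)
  key <- as.character(config$soas)
  blocks <- rep(config$soas, times = config$blocks_per_soa[key])
  seeds <- derive_seeds(seed, length(blocks) + 1L)
  order_idx <- with_seed(seeds[length(seeds)], sample(seq_along(blocks)))
  blocks <- blocks[order_idx]

  events <- vector("list", length(blocks))
  t0 <- max(1000, config$inter_block_gap)   # session lead-in: full pre-stimulus
                                            # support for the first trial
  per_soa_counter <- setNames(integer(length(config$soas)), key)
  for (b in seq_along(blocks)) {
    soa <- blocks[b]
    k <- as.character(soa)
    per_soa_counter[k] <- per_soa_counter[k] + 1L
    blk <- build_block_schedule(soa, config$trials_per_block[k],
                                config$deviant_prop, seed = seeds[b],
                                block_index = b)
    blk$onset <- blk$onset + t0
    events[[b]] <- blk
    t0 <- max(blk$onset) + soa + config$inter_block_gap
  }
  out <- list(events = do.call(rbind, events),
              block_order = data.frame(soa = blocks,
                                       block_index = seq_along(blocks)))
  class(out) <- "session_schedule"
  out
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %d blocks, %d trials (%s)\n",
              nrow(x$block_order), nrow(x$events),
              paste(sprintf("%s ms: %d", names(table(x$events$soa)),
                            as.integer(table(x$events$soa))), collapse = ", ")))
  invisible(x)
}

#' Synthesize a standard or deviant tone
#'
#' A unit-amplitude sinusoid at the configured carrier frequency with
#' cosine-squared onset/offset ramps of `rise_fall` ms. The total envelope
#' length equals the standard duration for `"STD"` and the deviant duration
#' for `"DEV"`.
#'
#' @param role `"STD"` or `"DEV"`
#' @param config an [oddball_config()]
#' @return numeric waveform sampled at `config$sample_rate_audio`
#' @examples
#' w <- synthesize_tone("DEV", oddball_config())
#' length(w) / oddball_config()$sample_rate_audio * 1000   # 180 ms
#' @export
synthesize_tone <- function(role = c("STD", "DEV"), config = oddball_config()) {
  role <- match.arg(role)
  dur_ms <- if (role == "DEV") config$dev_duration else config$std_duration
  if (2 * config$rise_fall > dur_ms)
    stopf("invalid argument: rise/fall ramps exceed the tone duration")
  fs <- config$sample_rate_audio
  n <- round(dur_ms / 1000 * fs)
  t <- (seq_len(n) - 1) / fs
  w <- sin(2 * pi * config$tone_freq * t)
  nr <- round(config$rise_fall / 1000 * fs)
  if (nr > 0) {
    ramp <- sin(seq(0, pi / 2, length.out = nr))^2
    w[seq_len(nr)] <- w[seq_len(nr)] * ramp
    w[(n - nr + 1):n] <- w[(n - nr + 1):n] * rev(ramp)
  }
  w
}

#' Export a schedule as a tab-separated table
#'
#' @param schedule a `session_schedule`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_schedule_tsv <- function(schedule, path) {
  ev <- schedule$events
  names(ev) <- c("onset_ms", "role", "soa", "block")
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
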