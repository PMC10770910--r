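# Shared fixtures, built in code.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Reproducible child-seed streams for simulation loops.
derive_acc_seeds <- function(master, n) mmnpipe:::derive_seeds(master, n)

# A profile with unit MMN gain everywhere and no nuisance processes.
clean_profile <- function(noise_sd = 0, blink_rate = 0, artifact_rate = 0,
                          gain = c("450" = 1, "900" = 1, "1800" = 1),
                          seed = 101L) {
  structure(list(subject_id = "T01", group = "TD", age = 14,
                 cln3_stage = NA_integer_, mmn_gain = gain,
                 noise_sd = noise_sd, blink_rate = blink_rate,
                 artifact_rate = artifact_rate,
                 bad_channels = character(0), seed = seed),
            class = "subject_profile")
}

# Small single-SOA oddball configuration for fast renders.
small_oddball <- function(soa = 1800, n_trials = 30) {
  cfg_args <- list(soas = soa,
                   blocks_per_soa = setNames(1, as.character(soa)),
                   trials_per_block = setNames(n_trials, as.character(soa)))
  do.call(oddball_config, cfg_args)
}

render_small <- function(profile = clean_profile(), soa = 1800,
                         n_trials = 30, rate = 128, seed = 5L) {
  sch <- build_session_schedule(small_oddball(soa, n_trials), seed = seed)
  render_continuous_eeg(profile, sch, default_montage(), rate = rate)
}

# Hand-built epoch set (trials x channels x time) on a 128 Hz grid.
make_epochs <- function(data, roles = rep("STD", dim(data)[1]),
                        soas = rep(900, dim(data)[1]),
                        montage = default_montage(),
                        rate = 128, pre = 13) {
  nt <- dim(data)[3]
  structure(list(
    data = data,
    times = (seq_len(nt) - 1 - pre) / rate * 1000,
    labels = data.frame(role = roles, soa = soas, block = 1L,
                        stringsAsFactors = FALSE),
    accepted = rep(TRUE, dim(data)[1]),
    reference = "native",
    channel_names = montage$name[seq_len(dim(data)[2])],
    montage = montage,
    log = list(dropped_boundary = 0L)), class = "epoch_set")
}

make_evoked <- function(data, role = "DEV", soa = 900,
                        montage = default_montage(), rate = 128, pre = 13) {
  rownames(data) <- montage$name[seq_len(nrow(data))]
  structure(list(data = data, times = (seq_len(ncol(data)) - 1 - pre) / rate * 1000,
                 n_trials = 10L, role = role, soa = soa, subject_id = "S",
                 channel_names = rownames(data), montage = montage),
            class = "evoked")
}

sine_recording <- function(freq, rate = 512, dur = 4, amp = 1, nch = 4,
                           montage = default_montage()) {
  n <- rate * dur
  tt <- (seq_len(n) - 1) / rate
  x <- matrix(rep(amp * sin(2 * pi * freq * tt), each = nch), nch, n)
  mmnpipe:::new_recording(x, rate, montage$name[seq_len(nch)],
                          data.frame(sample = integer(0), role = character(0),
                                     soa = numeric(0)), montage)
}
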