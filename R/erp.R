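#' Average accepted epochs into an evoked response
#'
#' Arithmetic mean over the accepted trials carrying the requested
#' (role, SOA) label.
#'
#' @param ep an `epoch_set`
#' @param role `"STD"` or `"DEV"`
#' @param soa SOA in ms
#' @param subject_id optional identifier carried in the result
#' @return an `evoked`: list with `data` (channels x time, uV), `times`,
#'   `n_trials`, `role`, `soa`, `subject_id`, `channel_names`, `montage`
#' @export
average_evoked <- function(ep, role, soa, subject_id = NA_character_) {
  i <- which(ep$accepted & ep$labels$role == role & ep$labels$soa == soa)
  if (!length(i)) stopf("empty condition: no accepted %s trials at SOA %s",
                        role, soa)
  m <- apply(ep$data[i, , , drop = FALSE], c(2, 3), mean)
  rownames(m) <- ep$channel_names
  structure(list(data = m, times = ep$times, n_trials = length(i),
                 role = role, soa = soa, subject_id = subject_id,
                 channel_names = ep$channel_names, montage = ep$montage),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %s @ SOA %s ms, %d trials, %d ch x %d samples\n",
              x$role, x$soa, x$n_trials, nrow(x$data), ncol(x$data)))
  invisible(x)
}

# Frontal composite (mean of F3, Fz, F4) of an evoked, as a time vector.
frontal_composite <- function(evoked, electrodes = c("F3", "Fz", "F4")) {
  i <- match(electrodes, evoked$channel_names)
  if (anyNA(i)) stopf("invalid argument: missing electrode(s)")
  colMeans(evoked$data[i, , drop = FALSE])
}

#' Decide subject inclusion from trial counts and waveform quality
#'
#' A subject is included outright when every condition retains at least
#' `min_trials` accepted trials. A subject below that count is still
#' retained when their frontal-composite waveform stays within the group
#' mean +/- 3 SD pointwise over 0-800 ms (the signal-to-noise exception);
#' otherwise the subject is excluded.
#'
#' @param counts named integer vector of accepted trials per condition
#' @param subject_composite the subject's frontal-composite waveform
#' @param group_mean,group_sd pointwise group statistics on the same support
#' @param times time axis (ms) matching the waveforms
#' @param min_trials inclusion threshold (default 50)
#' @param sd_limit the exception band width in SDs (default 3)
#' @return list of class `inclusion_decision`: `included`, `reason`
#'   (`"enough_trials"`, `"snr_exception"` or `"excluded_low_trials"`)
#' @export
decide_inclusion <- function(counts, subject_composite, group_mean, group_sd,
                             times, min_trials = 50, sd_limit = 3) {
  if (length(group_mean) != length(subject_composite) ||
      length(group_sd) != length(subject_composite))
    stopf("invalid argument: group statistics do not match the waveform")
  if (min(counts) >= min_trials)
    return(structure(list(included = TRUE, reason = "enough_trials"),
                     class = "inclusion_decision"))
  sel <- times >= 0 & times <= 800
  within <- abs(subject_composite[sel] - group_mean[sel]) <=
    sd_limit * group_sd[sel]
  if (all(within))
    structure(list(included = TRUE, reason = "snr_exception"),
              class = "inclusion_decision")
  else
    structure(list(included = FALSE, reason = "excluded_low_trials"),
              class = "inclusion_decision")
}

#' Deviant-minus-standard difference wave
#'
#' @param dev,std `evoked` objects for the same subject and SOA on a common
#'   time axis
#' @return channels x time matrix (uV) with attribute `"times"`; with this
#'   sign convention the mismatch response is negative at frontal channels
#' @export
difference_wave <- function(dev, std) {
  if (!isTRUE(all.equal(dev$times, std$times)) ||
      !identical(dev$channel_names, std$channel_names))
    stopf("invalid argument: evoked responses are not on a common axis")
  d <- dev$data - std$data
  attr(d, "times") <- dev$times
  d
}

#' MMN amplitude: windowed frontal-composite mean of DEV - STD
#'
#' Mean over the electrode composite and over all samples whose centres lie
#' in the closed `window` (200-240 ms by default) of the deviant-minus-
#' standard difference.
#'
#' @param dev,std `evoked` objects on a common axis
#' @param window measurement window, ms
#' @param electrodes electrode composite (default F3, Fz, F4)
#' @return scalar amplitude in uV
#' @export
mmn_amplitude <- function(dev, std, window = c(200, 240),
                          electrodes = c("F3", "Fz", "F4")) {
  d <- difference_wave(dev, std)
  i <- match(electrodes, dev$channel_names)
  if (anyNA(i)) stopf("invalid argument: missing electrode(s)")
  sel <- dev$times >= window[1] & dev$times <= window[2]
  if (!any(sel)) stopf("invalid argument: window outside epoch support")
  mean(d[i, sel])
}

#' Grand average of per-subject evoked responses
#'
#' Unweighted mean across subjects (each subject counts once, regardless of
#' trial counts), with the pointwise standard error of the mean.
#'
#' @param evokeds list of `evoked` objects on a common time axis
#' @return an `evoked` with `n_trials` = number of subjects and an extra
#'   `sem` matrix (channels x time)
#' @export
grand_average <- function(evokeds) {
  if (!length(evokeds)) stopf("empty input: no evoked responses")
  tpl <- evokeds[[1]]
  for (e in evokeds[-1])
    if (!isTRUE(all.equal(e$times, tpl$times)))
      stopf("invalid argument: time axes differ")
  arr <- simplify2array(lapply(evokeds, `[[`, "data"))  # ch x time x subj
  m <- apply(arr, c(1, 2), mean)
  sem <- if (length(evokeds) > 1)
    apply(arr, c(1, 2), sd) / sqrt(length(evokeds))
  else m * 0
  rownames(m) <- tpl$channel_names
  structure(list(data = m, sem = sem, times = tpl$times,
                 n_trials = length(evokeds), role = tpl$role, soa = tpl$soa,
                 subject_id = "grand", channel_names = tpl$channel_names,
                 montage = tpl$montage),
            class = "evoked")
}

#' Write a per-subject MMN measure table as TSV
#'
#' @param measures data.frame with one row per subject x SOA (columns
#'   `subject_id`, `group`, `age`, `cln3_stage`, `soa`, `amplitude_uV`,
#'   `n_dev`, `n_std`)
#' @param path output path
#' @return the path, invisibly
#' @export
write_measure_tsv <- function(measures, path) {
  utils::write.table(measures, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
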