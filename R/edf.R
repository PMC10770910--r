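# Minimal EDF+C I/O for continuous recordings with trial annotations.
# Data are stored as 16-bit integers with per-channel physical scaling; one
# "EDF Annotations" signal carries the trial markers as time-stamped
# annotation lists (TALs). Covers exactly what this pipeline needs: one
# continuous segment, uniform rate, microvolt channels.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording as EDF+ (continuous)
#'
#' Channels are scaled to the 16-bit digital range with symmetric
#' per-channel physical limits (physical dimension uV). Every event is
#' written as an annotation `"<role> soa=<soa> block=<block>"` at its onset.
#'
#' @param rec an `eeg_recording`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_edf <- function(rec, path) {
  x <- rec$data
  nch <- nrow(x)
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9)
    stopf("invalid argument: EDF writer requires an integer sampling rate")
  rate <- round(rate)
  n_rec <- ceiling(ncol(x) / rate)
  if (ncol(x) < n_rec * rate)
    x <- cbind(x, matrix(0, nch, n_rec * rate - ncol(x)))

  phys_max <- pmax(apply(abs(x), 1, max), 1)
  scale <- 32767 / phys_max
  dig <- round(x * scale)

  ev <- rec$events
  tals <- if (nrow(ev)) {
    onset <- (ev$sample - 1) / rate
    text <- sprintf("%s soa=%s block=%s", ev$role, ev$soa,
                    if ("block" %in% names(ev)) ev$block else 0)
    sprintf("+%.6f\x15%.6f\x14%s\x14", onset, 0, text)
  } else character(0)
  tal_rec <- if (nrow(ev)) floor((ev$sample - 1) / rate) else integer(0)

  # annotation signal size: timestamp TAL + this record's event TALs
  ann_bytes <- vapply(seq_len(n_rec) - 1L, function(r) {
    nchar(sprintf("+%d\x14\x14", r), type = "bytes") + 1L +
      sum(nchar(tals[tal_rec == r], type = "bytes")) + 1L
  }, numeric(1))
  ann_ns <- ceiling(max(ann_bytes) / 2) + 2L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("synthetic oddball EEG", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field((nch + 1 + 1) * 256, 8),
    pad_field("EDF+C", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(nch + 1, 4))
  writeChar(hdr, con, eos = NULL)
  labels <- c(rec$channel_names, "EDF Annotations")
  fields <- list(
    lapply(labels, pad_field, width = 16),
    lapply(rep("", nch + 1), pad_field, width = 80),
    lapply(c(rep("uV", nch), ""), pad_field, width = 8),
    lapply(c(sprintf("%.4f", -phys_max), "-1"), pad_field, width = 8),
    lapply(c(sprintf("%.4f", phys_max), "1"), pad_field, width = 8),
    lapply(c(rep("-32768", nch), "-32768"), pad_field, width = 8),
    lapply(c(rep("32767", nch), "32767"), pad_field, width = 8),
    lapply(rep("", nch + 1), pad_field, width = 80),
    lapply(c(rep(rate, nch), ann_ns), pad_field, width = 8),
    lapply(rep("", nch + 1), pad_field, width = 32))
  for (f in fields) writeChar(paste(unlist(f), collapse = ""), con, eos = NULL)

  for (r in seq_len(n_rec) - 1L) {
    idx <- r * rate + seq_len(rate)
    # EDF record layout: all samples of signal 1, then signal 2, ...
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
    raw_ann <- c(charToRaw(sprintf("+%d\x14\x14", r)), as.raw(0))
    if (any(tal_rec == r))
      raw_ann <- c(raw_ann,
                   charToRaw(paste(tals[tal_rec == r], collapse = "")),
                   as.raw(0))
    raw_ann <- c(raw_ann, raw(2 * ann_ns - length(raw_ann)))
    writeBin(raw_ann, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file written by [write_edf()]
#'
#' Parses the header, rescales the 16-bit samples to physical units, and
#' recovers trial events from the annotation channel (annotations of the
#' form `"<role> soa=<soa> block=<block>"`).
#'
#' @param path path to the EDF file
#' @param montage optional montage attached to the result (labels must match
#'   case-insensitively)
#' @return an `eeg_recording`
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  gf <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- gf(16); gf(80); gf(8)
  pmin_ <- as.numeric(gf(8)); pmax_ <- as.numeric(gf(8))
  dmin <- as.numeric(gf(8)); dmax <- as.numeric(gf(8))
  gf(80)
  nsamp <- as.integer(gf(8))
  gf(32)

  ann_i <- which(labels == "EDF Annotations")
  ch_i <- setdiff(seq_len(ns), ann_i)
  rate <- nsamp[ch_i[1]] / rec_dur
  data <- matrix(0, length(ch_i), n_rec * nsamp[ch_i[1]])
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (s %in% ann_i) {
        raw_ann <- readBin(con, "raw", 2 * nsamp[s])
        ann_text <- c(ann_text, rawToChar(raw_ann[raw_ann != as.raw(0)],
                                          multiple = FALSE))
      } else {
        v <- readBin(con, "integer", nsamp[s], size = 2, endian = "little")
        j <- match(s, ch_i)
        sc <- (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
        data[j, (r - 1) * nsamp[s] + seq_len(nsamp[s])] <-
          pmin_[s] + (v - dmin[s]) * sc
      }
    }
  }
  tals <- unlist(strsplit(paste(ann_text, collapse = ""), "\x14\\+",
                          fixed = FALSE))
  events <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) next
    onset <- as.numeric(sub("^\\+?([-0-9.]+).*", "\\1", parts[1]))
    m <- regmatches(parts[2],
                    regexec("(STD|DEV) soa=([0-9.]+) block=([0-9]+)", parts[2]))[[1]]
    if (length(m) == 4)
      events[[length(events) + 1]] <- data.frame(
        sample = round(onset * rate) + 1L, role = m[2],
        soa = as.numeric(m[3]), block = as.integer(m[4]),
        stringsAsFactors = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(sample = integer(0), role = character(0),
                            soa = numeric(0), block = integer(0))
  ch_names <- labels[ch_i]
  if (!is.null(montage)) {
    m <- match(tolower(ch_names), tolower(montage$name))
    if (anyNA(m)) stopf("invalid argument: channel labels do not match the montage")
    ch_names <- montage$name[m]
  }
  new_recording(data, rate, ch_names, events, montage)
}
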