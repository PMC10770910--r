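#' Band-pass filter specification
#'
#' @param band passband `c(low, high)` in Hz
#' @param family `"chebyshev2"` (stopband-ripple) or `"chebyshev1"`
#' @param order filter order (6 by default)
#' @param stopband_attenuation stopband attenuation in dB (Chebyshev II)
#' @return list of class `filter_spec`
#' @export
filter_spec <- function(band = c(1, 40), family = c("chebyshev2", "chebyshev1"),
                        order = 6, stopband_attenuation = 40) {
  family <- match.arg(family)
  if (band[1] <= 0 || band[2] <= band[1])
    stopf("invalid argument: need 0 < low < high")
  structure(list(band = band, family = family, order = order,
                 stopband_attenuation = stopband_attenuation),
            class = "filter_spec")
}

# Squared magnitude response of an IIR filter (b, a) on the N-point FFT grid.
iir_mag2 <- function(b, a, N) {
  z <- exp(-1i * 2 * pi * (0:(N - 1)) / N)
  num <- rep(b[1] + 0i, N)
  for (k in seq_along(b)[-1]) num <- num * z + b[k]
  den <- rep(a[1] + 0i, N)
  for (k in seq_along(a)[-1]) den <- den * z + a[k]
  Mod(num / den)^2
}

# Zero-phase filtering: apply |H|^2 in the frequency domain with reflection
# padding. Identical in response to forward-backward application of the IIR
# filter, without its startup transients.
zerophase_filter <- function(x, b, a, npad = 1024) {
  n <- nrow(x)
  npad <- min(npad, n)
  N <- nextn(n + 2 * npad, c(2, 3, 5))
  xp <- matrix(0, N, ncol(x))
  xp[seq_len(npad), ] <- x[npad:1, , drop = FALSE]
  xp[npad + seq_len(n), ] <- x
  xp[npad + n + seq_len(npad), ] <- x[n:(n - npad + 1), , drop = FALSE]
  H2 <- iir_mag2(b, a, N)
  out <- Re(mvfft(mvfft(xp) * H2, inverse = TRUE)) / N
  out[npad + seq_len(n), , drop = FALSE]
}

design_is_stable <- function(flt) {
  all(Mod(polyroot(rev(flt$a))) < 1)
}

#' Resample a continuous recording by integer decimation
#'
#' An 8th-order Chebyshev Type I low-pass anti-aliasing filter with cutoff
#' at 0.8 x the new Nyquist frequency is applied (zero phase), then every
#' k-th sample is kept. Event sample indices are rescaled to the nearest
#' sample on the new grid.
#'
#' @param rec an `eeg_recording`
#' @param target_rate new sampling rate, Hz; must divide `rec$rate`
#' @return the decimated `eeg_recording`
#' @export
resample_recording <- function(rec, target_rate = 128) {
  q <- rec$rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stopf("invalid argument: decimation factor %.3f is not an integer", q)
  q <- round(q)
  if (q == 1) return(rec)
  flt <- signal::cheby1(8, 0.05, 0.8 / q)
  y <- zerophase_filter(t(rec$data), flt$b, flt$a)
  keep <- seq(1, nrow(y), by = q)
  ev <- rec$events
  if (nrow(ev)) ev$sample <- pmax(1L, round((ev$sample - 1L) / q) + 1L)
  new_recording(t(y[keep, , drop = FALSE]), target_rate, rec$channel_names,
                ev, rec$montage)
}

#' Band-pass filter a continuous recording
#'
#' Designs the requested Chebyshev band-pass and applies it with zero phase
#' to every channel. For the Chebyshev Type II family (specified by its
#' stopband), the stopband edges are placed with a margin outside the
#' requested band -- at half the low edge and 1.2 x the high edge -- so the
#' quoted band is a true passband and slow ERP components are not eroded by
#' the transition region. If the design is numerically unstable at the
#' requested order, the order is reduced until a stable design is found
#' (with a warning); events are unchanged.
#'
#' @param rec an `eeg_recording`
#' @param spec a [filter_spec()]
#' @return the filtered `eeg_recording`
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  nyq <- rec$rate / 2
  if (spec$band[2] >= nyq)
    stopf("invalid argument: band edge %g Hz >= Nyquist (%g Hz)",
          spec$band[2], nyq)
  design <- function(ord) {
    if (spec$family == "chebyshev2") {
      Ws <- c(0.5 * spec$band[1], min(1.2 * spec$band[2], 0.98 * nyq)) / nyq
      signal::cheby2(ord, spec$stopband_attenuation, Ws, type = "pass")
    } else {
      signal::cheby1(ord, 0.5, spec$band / nyq, type = "pass")
    }
  }
  ord <- spec$order
  flt <- design(ord)
  while (!design_is_stable(flt) && ord > 2) {
    ord <- ord - 1
    warning(sprintf("unstable band-pass design; falling back to order %d", ord))
    flt <- design(ord)
  }
  y <- zerophase_filter(t(rec$data), flt$b, flt$a)
  new_recording(t(y), rec$rate, rec$channel_names, rec$events, rec$montage)
}

#' Detect bad channels
#'
#' Flags channels whose robust z-score of log standard deviation exceeds
#' +/- 3 (flat channels are outliers under this rule), or whose mean
#' correlation with their `n_neighbors` spatially nearest channels falls
#' below 0.4. The per-channel spread is estimated robustly (1.4826 x MAD,
#' a consistent SD estimate) so that sparse transients such as blinks do
#' not masquerade as continuously noisy channels, and the between-channel
#' scale is floored so a channel must deviate from the median spread by at
#' least a factor of 2 before the SD rule can fire.
#'
#' @param rec an `eeg_recording`
#' @param montage an `mmn_montage` matching the channel labels
#' @param n_neighbors number of nearest neighbours, 3-7
#' @param z_thresh robust-z threshold on log SD
#' @param corr_thresh neighbour-correlation threshold
#' @param max_fraction if more than this fraction of channels is flagged the
#'   detection is considered unreliable and nothing is flagged (with a
#'   warning)
#' @return character vector of flagged channel names
#' @export
detect_bad_channels <- function(rec, montage = rec$montage, n_neighbors = 5,
                                z_thresh = 3, corr_thresh = 0.4,
                                max_fraction = 0.25) {
  if (n_neighbors < 3 || n_neighbors > 7)
    stopf("invalid argument: n_neighbors must be within 3-7")
  if (ncol(rec$data) / rec$rate < 10)
    stopf("insufficient data: recording shorter than 10 s")
  x <- t(rec$data)
  if (nrow(x) > 30000)       # statistics stabilize well below this length
    x <- x[seq(1, nrow(x), length.out = 30000), , drop = FALSE]
  sds <- apply(x, 2, mad)
  lg <- log(pmax(sds, .Machine$double.xmin))
  med <- median(lg)
  # scale floor: a channel must deviate from the median spread by at least
  # a factor of 2 to count as an SD outlier, however homogeneous the rest
  # of the array is (otherwise signal-bearing channels of very clean
  # recordings become "outliers")
  sc <- max(mad(lg), log(2) / z_thresh)
  z <- (lg - med) / sc
  bad_sd <- abs(z) > z_thresh | sds == 0

  pos <- montage_positions(montage, rec$channel_names)
  d <- as.matrix(stats::dist(pos))
  cc <- suppressWarnings(cor(x))
  cc[!is.finite(cc)] <- 0
  bad_corr <- vapply(seq_len(ncol(x)), function(j) {
    nb <- order(d[j, ])[2:(n_neighbors + 1)]
    mean(cc[j, nb]) < corr_thresh
  }, logical(1))
  bad <- rec$channel_names[bad_sd | bad_corr]
  # mass flagging means the recording itself is degenerate (e.g. no
  # background activity at all), not that most channels are broken
  if (length(bad) > max_fraction * length(rec$channel_names)) {
    warning(sprintf("%d of %d channels flagged; treating detection as unreliable",
                    length(bad), length(rec$channel_names)))
    return(character(0))
  }
  bad
}

# Perrin-style spherical-spline kernel: g(cos angle) as a truncated Legendre
# series, order m, nterms terms.
spline_g <- function(x, m = 4, nterms = 50) {
  dm <- dim(x)
  x <- pmin(1, pmax(-1, x))
  dim(x) <- dm
  p_prev <- array(1, dim = if (is.null(dm)) length(x) else dm)   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:nterms) {
    p_new <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_new
    p_prev <- p_cur
    p_cur <- p_new
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each flagged channel's time series with the Perrin-style
#' spherical-spline estimate computed from the remaining good channels
#' (Legendre series of order `m = 4`, 50 terms, ridge regularization 1e-5).
#' Good channels are untouched.
#'
#' @param rec an `eeg_recording`
#' @param bad character vector of channel names to replace
#' @param montage an `mmn_montage`
#' @param m,nterms,lambda spline stiffness, series length, regularization
#' @return the repaired `eeg_recording`
#' @export
interpolate_channels <- function(rec, bad, montage = rec$montage,
                                 m = 4, nterms = 50, lambda = 1e-5) {
  if (!length(bad)) return(rec)
  if (!all(bad %in% rec$channel_names))
    stopf("invalid argument: bad channels not in the recording")
  good <- setdiff(rec$channel_names, bad)
  if (length(good) < 4) stopf("insufficient data: fewer than 4 good channels")
  pg <- montage_positions(montage, good)
  pb <- montage_positions(montage, bad)
  G <- spline_g(tcrossprod(pg), m, nterms) + diag(lambda, length(good))
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  Z <- rbind(rec$data[match(good, rec$channel_names), , drop = FALSE], 0)
  C <- solve(A, Z)
  Gb <- spline_g(tcrossprod(pb, pg), m, nterms)
  est <- cbind(Gb, 1) %*% C
  rec$data[match(bad, rec$channel_names), ] <- est
  rec
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Epochs span the requested window around every annotated event on the
#' recording's sample grid (t = 0 is the event sample; the grid covers at
#' least the full window). Events without full window support are dropped
#' and counted in the returned object's `log`.
#'
#' @param rec an `eeg_recording`
#' @param window epoch window in ms, default `c(-100, 800)`
#' @return an `epoch_set`: list with `data` (trials x channels x time array),
#'   `times` (ms), `labels` (role, soa, block), `accepted` (logical),
#'   `reference`, `channel_names`, `montage`, `log`
#' @export
epoch_recording <- function(rec, window = c(-100, 800)) {
  ev <- rec$events
  if (!nrow(ev)) stopf("empty input: recording has no events")
  pre <- ceiling(-window[1] * rec$rate / 1000)
  post <- ceiling(window[2] * rec$rate / 1000)
  ok <- ev$sample - pre >= 1 & ev$sample + post <= ncol(rec$data)
  dropped <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) stopf("empty input: no event has full window support")
  nt <- pre + post + 1L
  # gather all epochs with one indexing operation: time x trial sample grid
  idx <- outer(seq(-pre, post), ev$sample, "+")
  data <- aperm(array(t(rec$data)[as.vector(idx), ],
                      c(nt, nrow(ev), nrow(rec$data))), c(2, 3, 1))
  structure(list(
    data = data,
    times = seq(-pre, post) / rec$rate * 1000,
    labels = data.frame(role = ev$role, soa = ev$soa,
                        block = if ("block" %in% names(ev)) ev$block else NA,
                        stringsAsFactors = FALSE),
    accepted = rep(TRUE, nrow(ev)),
    reference = "native",
    channel_names = rec$channel_names,
    montage = rec$montage,
    log = list(dropped_boundary = dropped)), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d accepted) x %d ch x %d samples, ref=%s\n",
              dim(x$data)[1], sum(x$accepted), dim(x$data)[2], dim(x$data)[3],
              x$reference))
  invisible(x)
}

#' Two-stage amplitude-based artifact rejection
#'
#' Stage 1 rejects any trial containing a sample exceeding +/- `threshold_uv`
#' in any channel. Stage 2 operates per condition (role x SOA) on the
#' surviving trials: for each epoch the largest absolute value over all
#' channels within the first 500 ms post-stimulus is taken, and epochs whose
#' maximum exceeds the condition mean by more than two standard deviations
#' are rejected. Trials are never un-rejected.
#'
#' @param ep an `epoch_set`
#' @param threshold_uv absolute-amplitude threshold (default 150 uV)
#' @param sd_mult stage-2 multiplier (default 2)
#' @return the `epoch_set` with an updated `accepted` mask; per-stage counts
#'   are appended to `log`
#' @export
reject_artifacts <- function(ep, threshold_uv = 150, sd_mult = 2) {
  if (!dim(ep$data)[1]) stopf("empty input: no epochs")
  acc0 <- ep$accepted
  peak <- apply(abs(ep$data), 1, max)
  stage1 <- acc0 & peak <= threshold_uv

  tsel <- ep$times >= 0 & ep$times < 500
  m <- apply(abs(ep$data[, , tsel, drop = FALSE]), 1, max)
  stage2 <- stage1
  cond <- interaction(ep$labels$role, ep$labels$soa, drop = TRUE)
  empty_conditions <- character(0)
  for (cl in levels(cond)) {
    i <- which(cond == cl & stage1)
    if (!length(i)) { empty_conditions <- c(empty_conditions, cl); next }
    mu <- mean(m[i]); s <- sd(m[i])
    if (is.na(s) || s == 0) next
    stage2[i[m[i] > mu + sd_mult * s]] <- FALSE
  }
  ep$accepted <- stage2
  ep$log$rejected_stage1 <- sum(acc0) - sum(stage1)
  ep$log$rejected_stage2 <- sum(stage1) - sum(stage2)
  ep$log$empty_conditions <- empty_conditions
  ep
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval
#' (closed on the left, open on the right; `[-100, 0)` ms by default).
#'
#' @param ep an `epoch_set`
#' @param interval baseline interval in ms
#' @return the corrected `epoch_set`
#' @export
baseline_correct <- function(ep, interval = c(-100, 0)) {
  sel <- ep$times >= interval[1] & ep$times < interval[2]
  if (!any(sel)) stopf("invalid argument: baseline interval outside epoch support")
  bl <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(bl, dim(ep$data))
  ep
}

#' Re-reference epochs to T7 (or T8)
#'
#' Subtracts the chosen reference channel's time series from every channel.
#' T7 is used unless it is listed as bad, in which case T8 is used; if both
#' are bad the operation fails.
#'
#' @param ep an `epoch_set`
#' @param primary,fallback reference channel names
#' @param bad character vector of bad-channel names
#' @return the re-referenced `epoch_set` (`reference` records the choice)
#' @export
rereference <- function(ep, primary = "T7", fallback = "T8", bad = character(0)) {
  ref <- if (!primary %in% bad) primary
         else if (!fallback %in% bad) fallback
         else stopf("unusable reference: both %s and %s are bad", primary, fallback)
  j <- match(ref, ep$channel_names)
  if (is.na(j)) stopf("invalid argument: reference channel %s absent", ref)
  refsig <- ep$data[, j, , drop = FALSE]
  ep$data <- ep$data - refsig[, rep(1, dim(ep$data)[2]), , drop = FALSE]
  ep$reference <- ref
  ep
}

# Concatenate accepted epochs into a channels x samples matrix.
concat_epochs <- function(ep) {
  idx <- which(ep$accepted)
  d <- ep$data[idx, , , drop = FALSE]
  nt <- dim(d)[3]
  out <- matrix(aperm(d, c(2, 3, 1)), dim(d)[2], nt * length(idx))
  list(x = out, idx = idx, nt = nt)
}

detect_blink_regressor <- function(x, channel_names, montage, rate) {
  fr <- intersect(c("Fp1", "Fp2", "AF3", "AF4"), channel_names)
  f <- colMeans(x[match(fr, channel_names), , drop = FALSE])
  thr <- max(50, median(f) + 5 * mad(f))
  above <- f > thr
  if (!any(above)) return(NULL)
  half <- round(0.15 * rate)
  mask <- rep(FALSE, length(f))
  for (i in which(above)) mask[max(1, i - half):min(length(f), i + half)] <- TRUE
  u <- f * mask
  list(u = u, mask = mask)
}

#' Remove ocular (blink) activity from epochs
#'
#' Two modes. `"ica"` decomposes the concatenated accepted epochs with a
#' FastICA-style algorithm (tanh contrast, symmetric decorrelation) and
#' removes at most `max_components` components that are both frontally
#' dominant (frontal:posterior weight ratio > 3) and correlated (> 0.7) with
#' the detected blink time course. `"template"` is a deterministic
#' regression: the blink time course measured at the prefrontal channels,
#' restricted to detected blink windows, is projected out of every channel.
#' If no blink activity is detected the data pass through unchanged.
#'
#' @param ep an `epoch_set` with >= 20 accepted trials
#' @param max_components maximum number of components to remove (ICA mode)
#' @param method `"template"` (deterministic) or `"ica"`
#' @param seed seed for the ICA initialization
#' @return the cleaned `epoch_set`; `log$ocular` records what was removed
#' @export
remove_ocular_components <- function(ep, max_components = 2,
                                     method = c("template", "ica"),
                                     seed = 1L) {
  method <- match.arg(method)
  if (sum(ep$accepted) < 20)
    stopf("invalid argument: need at least 20 accepted trials")
  rate <- 1000 / diff(ep$times[1:2])
  cc <- concat_epochs(ep)
  blink <- detect_blink_regressor(cc$x, ep$channel_names, ep$montage, rate)
  if (is.null(blink)) {
    ep$log$ocular <- list(method = method, removed = 0L)
    return(ep)
  }
  if (method == "template") {
    u <- blink$u
    b <- as.vector(cc$x %*% u) / sum(u * u)
    clean <- cc$x - outer(b, u)
    removed <- 1L
  } else {
    dec <- tryCatch(fastica_decompose(cc$x, n_comp = min(15, nrow(cc$x)),
                                      seed = seed),
                    error = function(e) NULL)
    if (is.null(dec)) {
      warning("ICA decomposition failed; data passed through unchanged")
      ep$log$ocular <- list(method = method, removed = 0L, failed = TRUE)
      return(ep)
    }
    fr <- match(frontal_channels(ep$montage), ep$channel_names)
    po <- match(posterior_channels(ep$montage), ep$channel_names)
    ratio <- apply(dec$A, 2, function(a)
      mean(abs(a[fr])) / max(mean(abs(a[po])), 1e-12))
    r_blink <- abs(apply(dec$S, 1, function(s) cor(s, blink$u)))
    cand <- which(ratio > 3 & r_blink > 0.7)
    cand <- cand[order(-r_blink[cand])]
    cand <- utils::head(cand, max_components)
    if (!length(cand)) {
      ep$log$ocular <- list(method = method, removed = 0L)
      return(ep)
    }
    Skeep <- dec$S
    Skeep[cand, ] <- 0
    clean <- dec$A %*% Skeep + dec$mean
    removed <- length(cand)
  }
  d <- array(clean, c(dim(ep$data)[2], cc$nt, length(cc$idx)))
  ep$data[cc$idx, , ] <- aperm(d, c(3, 1, 2))
  ep$log$ocular <- list(method = method, removed = removed)
  ep
}

# Compact FastICA (symmetric orthogonalization, tanh contrast).
# x: channels x samples. Returns mixing A, sources S, channel means.
fastica_decompose <- function(x, n_comp, seed = 1L, max_iter = 200,
                              tol = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > 1e-10)[seq_len(min(n_comp, sum(eg$values > 1e-10)))]
  Wh <- diag(1 / sqrt(eg$values[keep])) %*% t(eg$vectors[, keep, drop = FALSE])
  z <- Wh %*% xc
  p <- nrow(z)
  W <- with_seed(seed, matrix(rnorm(p * p), p, p))
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- g %*% t(z) / ncol(z) - diag(rowMeans(gp)) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% z
  A <- MASS_ginv(Wh) %*% t(W)
  list(A = A, S = S, mean = mu)
}

# Moore-Penrose pseudoinverse via SVD (avoids a MASS dependency for one call).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
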