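#' Standard figures from a run report
#'
#' Writes three figure families as PNG files: frontal-composite waveform
#' panels per group and SOA (standard and deviant traces with +/- SEM
#' ribbons, the difference trace, and the shaded 200-240 ms measurement
#' window), deviant-minus-standard topographic maps at the window (color
#' limits symmetric about zero), and per-group/SOA MMN amplitude scatter
#' with group means. Panels whose data are missing are skipped with a note.
#'
#' @param report a `run_report`
#' @param dir output directory (created if needed)
#' @param window the measurement window to shade, ms
#' @return character vector of written file paths, invisibly
#' @export
make_figures <- function(report, dir, window = c(200, 240)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ga <- report$grand_averages
  if (!length(ga)) {
    message("no grand averages available; figures skipped")
    return(invisible(character(0)))
  }
  written <- character(0)

  rows <- list()
  for (key in names(ga)) {
    parts <- strsplit(key, "_")[[1]]
    e <- ga[[key]]
    comp <- frontal_composite(e)
    sem <- colMeans(e$sem[match(c("F3", "Fz", "F4"), e$channel_names), ,
                          drop = FALSE])
    rows[[key]] <- data.frame(group = parts[1], soa = parts[2],
                              role = parts[3], time = e$times,
                              amp = comp, sem = sem)
  }
  wf <- do.call(rbind, rows)
  diffs <- do.call(rbind, lapply(split(wf, list(wf$group, wf$soa)), function(d) {
    if (length(unique(d$role)) < 2) return(NULL)
    dv <- d[d$role == "DEV", ]
    st <- d[d$role == "STD", ]
    data.frame(group = dv$group, soa = dv$soa, time = dv$time,
               amp = dv$amp - st$amp)
  }))
  p1 <- ggplot2::ggplot(wf, ggplot2::aes(x = .data$time, y = .data$amp,
                                         color = .data$role)) +
    ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$amp - .data$sem,
                                      ymax = .data$amp + .data$sem,
                                      fill = .data$role),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = diffs, ggplot2::aes(x = .data$time, y = .data$amp),
                       color = "goldenrod3", inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_grid(soa ~ group) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)",
                  title = "Frontal composite (F3/Fz/F4): standard, deviant, difference") +
    ggplot2::theme_minimal()
  f1 <- file.path(dir, "waveforms.png")
  ggplot2::ggsave(f1, p1, width = 8, height = 8, dpi = 120)
  written <- c(written, f1)

  topo <- list()
  for (key in names(ga)) {
    parts <- strsplit(key, "_")[[1]]
    if (parts[3] != "DEV") next
    std_key <- paste(parts[1], parts[2], "STD", sep = "_")
    if (is.null(ga[[std_key]])) next
    e <- ga[[key]]
    d <- e$data - ga[[std_key]]$data
    sel <- e$times >= window[1] & e$times <= window[2]
    amp <- rowMeans(d[, sel, drop = FALSE])
    mon <- e$montage
    theta <- acos(pmin(1, pmax(-1, mon$z)))
    rho <- sqrt(mon$x^2 + mon$y^2)
    topo[[key]] <- data.frame(group = parts[1], soa = parts[2],
                              px = ifelse(rho > 0, theta * mon$x / rho, 0),
                              py = ifelse(rho > 0, theta * mon$y / rho, 0),
                              amp = amp)
  }
  if (length(topo)) {
    td <- do.call(rbind, topo)
    lim <- max(abs(td$amp))
    p2 <- ggplot2::ggplot(td, ggplot2::aes(x = .data$px, y = .data$py,
                                           color = .data$amp)) +
      ggplot2::geom_point(size = 5) +
      ggplot2::scale_color_gradient2(low = "blue", mid = "white",
                                     high = "red", limits = c(-lim, lim)) +
      ggplot2::coord_equal() +
      ggplot2::facet_grid(soa ~ group) +
      ggplot2::labs(title = "Deviant - standard, 200-240 ms window",
                    color = "uV") +
      ggplot2::theme_void()
    f2 <- file.path(dir, "topography.png")
    ggplot2::ggsave(f2, p2, width = 7, height = 8, dpi = 120)
    written <- c(written, f2)
  }

  if (!is.null(report$measures) && nrow(report$measures)) {
    m <- report$measures
    m$soa <- factor(m$soa)
    p3 <- ggplot2::ggplot(m, ggplot2::aes(x = .data$soa, y = .data$amplitude,
                                          color = .data$group)) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(x = "SOA (ms)", y = "MMN amplitude (uV)",
                    title = "Per-subject MMN amplitudes") +
      ggplot2::theme_minimal()
    f3 <- file.path(dir, "amplitudes.png")
    ggplot2::ggsave(f3, p3, width = 7, height = 4, dpi = 120)
    written <- c(written, f3)
  }
  invisible(written)
}

#' @importFrom ggplot2 .data
NULL
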