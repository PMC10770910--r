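#' Electrode montage for a 32-channel cap with mastoids
#'
#' An idealized unit-sphere layout for the standard 32-channel Biosemi-style
#' cap plus the two mastoid electrodes (M1, M2). Positions are generated from
#' 10-20-style inclination/azimuth angles; the exact manufacturer coordinates
#' are not required by any downstream operation, which only consume relative
#' geometry (neighbourhoods, interpolation kernels, topographies).
#'
#' Coordinate convention: +x towards the right ear (T8), +y towards the nose,
#' +z towards the vertex (Cz). All vectors have unit norm.
#'
#' @param include_mastoids logical; keep the M1/M2 rows (default `TRUE`).
#' @return An object of class `mmn_montage`: a data.frame with columns
#'   `name`, `x`, `y`, `z` (unit 3-D position per electrode).
#' @examples
#' mon <- default_montage()
#' nrow(mon)            # 34
#' range(sqrt(mon$x^2 + mon$y^2 + mon$z^2))
#' @export
default_montage <- function(include_mastoids = TRUE) {
  # (inclination from vertex, azimuth from +x counterclockwise), degrees
  ang <- rbind(
    Fp1 = c(90, 108), AF3 = c(74, 113), F7 = c(90, 144), F3 = c(62, 129),
    FC1 = c(32, 118), FC5 = c(62, 158), T7 = c(90, 180), C3 = c(45, 180),
    CP1 = c(32, 242), CP5 = c(62, 202), P7 = c(90, 216), P3 = c(62, 231),
    Pz  = c(45, 270), PO3 = c(74, 247), O1 = c(90, 252), Oz = c(90, 270),
    O2  = c(90, 288), PO4 = c(74, 293), P4 = c(62, 309), P8 = c(90, 324),
    CP6 = c(62, 338), CP2 = c(32, 298), C4 = c(45, 0),   T8 = c(90, 0),
    FC6 = c(62, 22),  FC2 = c(32, 62),  F4 = c(62, 51),  F8 = c(90, 36),
    AF4 = c(74, 67),  Fp2 = c(90, 72),  Fz = c(45, 90),  Cz = c(0, 0),
    M1  = c(115, 195), M2 = c(115, 345)
  )
  if (!include_mastoids) ang <- ang[!rownames(ang) %in% c("M1", "M2"), ]
  th <- ang[, 1] * pi / 180
  ph <- ang[, 2] * pi / 180
  mon <- data.frame(
    name = rownames(ang),
    x = sin(th) * cos(ph),
    y = sin(th) * sin(ph),
    z = cos(th),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(mon) <- c("mmn_montage", "data.frame")
  mon
}

#' @export
print.mmn_montage <- function(x, ...) {
  cat(sprintf("<mmn_montage> %d electrodes: %s ...\n", nrow(x),
              paste(utils::head(x$name, 8), collapse = ", ")))
  invisible(x)
}

montage_positions <- function(montage, names = montage$name) {
  i <- match(names, montage$name)
  if (anyNA(i)) stop("unknown channel(s): ", paste(names[is.na(i)], collapse = ", "))
  m <- as.matrix(montage[i, c("x", "y", "z")])
  rownames(m) <- names
  m
}

#' Frontal / posterior channel helpers
#'
#' Channel groups used throughout the pipeline: the frontal measurement
#' composite (F3, Fz, F4), the broader frontal pool used for blink detection,
#' and the posterior pool used for frontal-dominance ratios.
#' @param montage an `mmn_montage`
#' @return character vector of channel names present in the montage
#' @keywords internal
frontal_channels <- function(montage) {
  intersect(c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8"),
            montage$name)
}

posterior_channels <- function(montage) {
  intersect(c("P7", "P3", "Pz", "P4", "P8", "PO3", "PO4", "O1", "Oz", "O2"),
            montage$name)
}
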