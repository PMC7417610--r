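#' Define a line probe across leaf segments
#'
#' @param from,to Probe endpoints as `c(row, col)` pixel coordinates
#'   (1-based matrix indices); must be distinct.
#' @param n_segments Number of leaf segments the probe crosses (>= 1; at
#'   least 6 is recommended for a stable average).
#' @return A `line_probe` object.
#' @export
line_probe <- function(from, to, n_segments) {
  stopifnot(length(from) == 2, length(to) == 2, n_segments >= 1)
  if (all(from == to)) stop("probe endpoints must be distinct")
  structure(list(from = as.numeric(from), to = as.numeric(to),
                 n_segments = as.integer(n_segments)),
            class = "line_probe")
}

# Bresenham traversal between two pixels; returns an n x 2 matrix of
# (row, col) indices, one sample per pixel step along the dominant axis.
bresenham_line <- function(from, to) {
  x0 <- from[2]; y0 <- from[1]; x1 <- to[2]; y1 <- to[1]
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1 else -1
  sy <- if (y0 < y1) 1 else -1
  n <- max(dx, dy) + 1
  out <- matrix(0L, nrow = n, ncol = 2)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    out[i, ] <- c(y, x)
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  out
}

#' Estimate background and tissue intensity levels
#'
#' The noise level is the mean intensity over a user-designated background
#' region; the signal level is the mean over seed pixels placed in the
#' middle of leaf segments.
#'
#' @param image A [leaf_image()] (or plain matrix).
#' @param background,foreground Regions given either as a logical mask of
#'   the image size or as an n x 2 matrix of (row, col) indices; must be
#'   non-empty and disjoint.
#' @return List with `noise_level` and `signal_level`.
#' @export
estimate_levels <- function(image, background, foreground) {
  pix <- function(region, what) {
    if (is.logical(region)) {
      if (!any(region)) stop("empty ", what, " region")
      idx <- which(region)
    } else {
      region <- as.matrix(region)
      if (nrow(region) == 0) stop("empty ", what, " region")
      idx <- (region[, 2] - 1) * nrow(image) + region[, 1]
    }
    idx
  }
  bg <- pix(background, "background")
  fg <- pix(foreground, "foreground")
  if (length(intersect(bg, fg)) > 0)
    stop("background and foreground regions overlap")
  list(noise_level = mean(image[bg]), signal_level = mean(image[fg]))
}

#' Intensity cut-off separating tissue from background
#'
#' Half the sum of the noise and signal levels. Binarising at this midpoint
#' compensates partial-volume effects: boundary pixels filled less than
#' half count as empty, those filled more than half as full.
#'
#' @param noise_level,signal_level Mean background / tissue intensities;
#'   `signal_level` must exceed `noise_level`.
#' @return The cut-off intensity.
#' @export
signal_cutoff <- function(noise_level, signal_level) {
  if (signal_level <= noise_level)
    stop("signal level must exceed noise level")
  (noise_level + signal_level) / 2
}

#' Mean blade thickness along a line probe
#'
#' Samples the image along the probe (Bresenham traversal, one sample per
#' pixel step), classifies each sample as filled (>= cut-off) or empty,
#' and converts the filled count to physical length: the probe's physical
#' length is the Euclidean endpoint distance times `pixel_size`, each
#' sample represents an equal share of it, and the filled length divided
#' by the number of crossed segments is the mean thickness.
#'
#' @param image A [leaf_image()] or matrix.
#' @param probe A [line_probe()].
#' @param cutoff Intensity cut-off (see [signal_cutoff()]).
#' @param pixel_size Pixel size, um/pixel; defaults to the image attribute.
#' @return Mean segment thickness, um.
#' @export
thickness_from_line <- function(image, probe, cutoff,
                                pixel_size = attr(image, "pixel_size")) {
  stopifnot(inherits(probe, "line_probe"))
  if (is.null(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be supplied (um/pixel)")
  if (any(c(probe$from, probe$to) < 1) ||
      any(probe$from > dim(image)) || any(probe$to > dim(image)))
    stop("probe endpoints outside the image")

  path <- bresenham_line(probe$from, probe$to)
  vals <- image[cbind(path[, 1], path[, 2])]
  filled <- sum(vals >= cutoff)
  if (filled == 0) stop("no tissue crossed: all samples below cut-off")

  n <- nrow(path)
  dist_px <- sqrt(sum((probe$to - probe$from)^2))
  step_um <- pixel_size * if (n > 1) dist_px / (n - 1) else 1
  filled * step_um / probe$n_segments
}

#' Combine thickness measurements across images and slices
#'
#' @param measurements Thickness values, um (>= 1 value).
#' @return List with `mean`, `sd` (0 for a single value) and `n`.
#' @export
average_slices <- function(measurements) {
  if (length(measurements) < 1) stop("need at least one measurement")
  s <- if (length(measurements) == 1) 0 else stats::sd(measurements)
  list(mean = mean(measurements), sd = s, n = length(measurements))
}

#' One-call blade thickness measurement
#'
#' Convenience wrapper: estimates the noise and signal levels, forms the
#' midpoint cut-off, and measures the mean thickness along the probe.
#'
#' @inheritParams estimate_levels
#' @inheritParams thickness_from_line
#' @return List with `thickness_um`, `cutoff`, `noise_level`,
#'   `signal_level`.
#' @export
measure_leaf_thickness <- function(image, probe, background, foreground,
                                   pixel_size = attr(image, "pixel_size")) {
  lv <- estimate_levels(image, background, foreground)
  cut <- signal_cutoff(lv$noise_level, lv$signal_level)
  th <- thickness_from_line(image, probe, cut, pixel_size)
  list(thickness_um = th, cutoff = cut,
       noise_level = lv$noise_level, signal_level = lv$signal_level)
}
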