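#' Generate a synthetic cross-section image with known band geometry
#'
#' Builds a grayscale phantom for the line-probe thickness procedure:
#' `n_segments` parallel horizontal bright bands (leaf blade segments seen
#' in cross-section), each exactly `thickness_px` pixels thick, evenly
#' spaced on a darker background. Gaussian noise of standard deviation
#' `noise_sd` is added to every pixel, so the contrast-to-noise ratio is
#' `(signal_mean - noise_mean) / noise_sd`. A vertical probe crossing all
#' bands is returned together with the true geometry.
#'
#' @param thickness_px Band thickness in pixels (>= 1).
#' @param n_segments Number of bands.
#' @param signal_mean,noise_mean Mean intensity of band and background
#'   pixels; `signal_mean > noise_mean`.
#' @param noise_sd Gaussian noise standard deviation (0 for a noiseless
#'   phantom).
#' @param image_size Image side length in pixels (square image).
#' @param pixel_size Physical pixel size, um/pixel (stored on the image).
#' @param seed Optional RNG seed; a fixed seed gives a byte-identical image.
#'
#' @return A list with `image` (a `leaf_image`: numeric matrix with a
#'   `pixel_size` attribute), `probe` (a [line_probe()] crossing all bands),
#'   and `truth` (band start rows, `thickness_px`, `n_segments`, and the
#'   true thickness in um).
#' @export
generate_section_image <- function(thickness_px, n_segments,
                                   signal_mean = 90, noise_mean = 10,
                                   noise_sd = 0, image_size = 256,
                                   pixel_size = 39.0625, seed = NULL) {
  stopifnot(thickness_px >= 1, n_segments >= 1,
            signal_mean > noise_mean, noise_sd >= 0, image_size >= 4)
  gap <- (image_size - n_segments * thickness_px) / (n_segments + 1)
  if (gap < 1)
    stop("bands do not fit: ", n_segments, " segments of ", thickness_px,
         " px need more than ", image_size, " rows")
  if (!is.null(seed)) set.seed(seed)

  img <- matrix(noise_mean, nrow = image_size, ncol = image_size)
  starts <- round(gap * seq_len(n_segments) +
                    thickness_px * (seq_len(n_segments) - 1)) + 1L
  for (s in starts) img[s:(s + thickness_px - 1L), ] <- signal_mean
  if (noise_sd > 0)  # clip at zero as in magnitude images
    img <- pmax(img + matrix(stats::rnorm(image_size^2, 0, noise_sd),
                             nrow = image_size), 0)

  col <- as.integer(ceiling(image_size / 2))
  probe <- line_probe(from = c(1, col), to = c(image_size, col),
                      n_segments = n_segments)

  list(
    image = leaf_image(img, pixel_size = pixel_size),
    probe = probe,
    truth = list(band_start_rows = starts, thickness_px = thickness_px,
                 n_segments = n_segments,
                 thickness_um = thickness_px * pixel_size,
                 signal_mean = signal_mean, noise_mean = noise_mean,
                 noise_sd = noise_sd)
  )
}

#' Construct a leaf_image from an intensity matrix
#'
#' @param x Numeric matrix of finite, non-negative intensities
#'   (rows = image rows, 0-based pixel (row, col) coordinates are not used;
#'   all coordinates in this package are 1-based R matrix indices).
#' @param pixel_size Physical pixel size, um/pixel.
#' @return The matrix with class `leaf_image` and a `pixel_size` attribute.
#' @export
leaf_image <- function(x, pixel_size) {
  stopifnot(is.matrix(x), all(is.finite(x)), all(x >= 0), pixel_size > 0)
  structure(x, pixel_size = pixel_size, class = c("leaf_image", "matrix", "array"))
}

#' Read / write a leaf_image as 16-bit grayscale TIFF
#'
#' Intensities are scaled by `max_intensity` into the TIFF 0..1 range on
#' write and rescaled back on read.
#'
#' @param image A [leaf_image()].
#' @param path TIFF file path.
#' @param pixel_size Pixel size (um/pixel) to attach on read.
#' @param max_intensity Full-scale intensity corresponding to white.
#' @return `write_leaf_image()` returns `path` invisibly;
#'   `read_leaf_image()` returns a [leaf_image()].
#' @export
write_leaf_image <- function(image, path, max_intensity = 2^16 - 1) {
  stopifnot(inherits(image, "leaf_image"))
  m <- pmin(pmax(unclass(image) / max_intensity, 0), 1)
  tiff::writeTIFF(m, where = path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_leaf_image
#' @export
read_leaf_image <- function(path, pixel_size, max_intensity = 2^16 - 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  leaf_image(m * max_intensity, pixel_size = pixel_size)
}
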