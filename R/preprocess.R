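#' Thermal image container
#'
#' A minimal container for a grayscale thermogram: a numeric matrix of
#' intensities (gray levels or raw temperature readings) plus the bit depth
#' used when reading/writing files.
#'
#' @param pixels numeric matrix, finite values.
#' @param bit_depth 8, 16, or `"float"`.
#' @param id character identifier.
#' @return object of class `thermal_image`.
#' @export
thermal_image <- function(pixels, bit_depth = 8L, id = "") {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stopf("thermal image contains non-finite values")
  structure(list(pixels = pixels, bit_depth = bit_depth, id = id),
            class = "thermal_image")
}

#' @export
print.thermal_image <- function(x, ...) {
  cat(sprintf("<thermal_image '%s' %dx%d, bit depth %s, range [%g, %g]>\n",
              x$id, nrow(x$pixels), ncol(x$pixels), as.character(x$bit_depth),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a thermogram from PNG, TIFF or a plain-text matrix
#'
#' PNG/TIFF intensities are rescaled to the nominal gray-level range of the
#' file's bit depth (0..255 or 0..65535). CSV/TXT files are read as a bare
#' numeric matrix of temperature values, as distributed in thermal-matrix
#' datasets.
#'
#' @param path file path; format chosen by extension.
#' @return a [thermal_image()].
#' @export
read_thermal_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  id <- basename(path)
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    thermal_image(round(a * 255), bit_depth = 8L, id = id)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    thermal_image(round(a * 65535), bit_depth = 16L, id = id)
  } else if (ext %in% c("csv", "txt")) {
    a <- as.matrix(utils::read.table(path, sep = if (ext == "csv") "," else "",
                                     header = FALSE))
    dimnames(a) <- NULL
    thermal_image(a, bit_depth = "float", id = id)
  } else stopf("unsupported image format: '%s'", ext)
}

#' Write a thermal image to PNG
#' @param img a `thermal_image`.
#' @param path output path.
#' @export
write_thermal_image <- function(img, path) {
  maxval <- if (identical(img$bit_depth, 16L)) 65535 else 255
  p <- img$pixels
  if (identical(img$bit_depth, "float")) {
    rng <- range(p)
    p <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0
  } else p <- p / maxval
  png::writePNG(pmin(pmax(p, 0), 1), path)
  invisible(path)
}

#' Otsu foreground threshold
#'
#' Selects the gray level that maximises the between-class variance of the
#' intensity histogram (equivalently minimises the pooled within-class
#' variance), the classic automatic split of a thermogram into warm body
#' foreground and cold background. Pixels strictly above the returned
#' threshold are foreground. Ties are broken toward the smallest threshold.
#'
#' @param img a `thermal_image` or numeric matrix.
#' @param bins histogram resolution for non-8-bit input; 8-bit images use
#'   their native 256 levels.
#' @return the threshold, on the image's own gray-level scale.
#' @examples
#' m <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
#' otsu_threshold(m) >= 10 && otsu_threshold(m) < 200
#' @export
otsu_threshold <- function(img, bins = 1024L) {
  p <- if (inherits(img, "thermal_image")) img$pixels else as.matrix(img)
  v <- as.numeric(p)
  if (max(v) == min(v)) stopf("degenerate histogram: constant image")
  eight_bit <- (inherits(img, "thermal_image") &&
                identical(img$bit_depth, 8L)) ||
               (all(v == round(v)) && min(v) >= 0 && max(v) <= 255)
  if (eight_bit) {
    levels <- 0:255
    counts <- tabulate(v + 1L, nbins = 256L)
  } else {
    levels <- seq(min(v), max(v), length.out = bins)
    counts <- tabulate(findInterval(v, levels, rightmost.closed = TRUE),
                       nbins = bins)
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n                  # background weight at t = level i
  mu <- cumsum(counts * levels) / n
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(levels))
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  levels[which.max(sigma_b)]               # which.max takes the first maximum
}

#' Foreground mask from Otsu's threshold
#' @param img a `thermal_image` or matrix.
#' @param ... passed to [otsu_threshold()].
#' @return logical matrix, TRUE on foreground (pixels above the threshold).
#' @export
otsu_mask <- function(img, ...) {
  p <- if (inherits(img, "thermal_image")) img$pixels else as.matrix(img)
  p > otsu_threshold(img, ...)
}

#' HSI pseudo-coloring of a grayscale thermogram
#'
#' Maps gray level to hue linearly from blue (240 degrees, coldest) to red
#' (0 degrees, hottest) with full saturation, and to the intensity channel by
#' min-max normalisation over the foreground, reproducing the familiar
#' iron/rainbow look of clinical thermograms where warm tissue appears red
#' and yellow and the cold background blue. Background pixels receive a
#' reserved hue (270 degrees) and zero saturation so no foreground gray level
#' collides with them. The per-pixel (hue, saturation, intensity) triple is
#' also the feature vector handed to the fuzzy clustering stage.
#'
#' @param img a `thermal_image` or matrix.
#' @param mask logical foreground mask, same shape; default all-foreground.
#' @return object of class `pseudo_color`: list of matrices `h`, `s`, `i`
#'   in `[0, 1]` plus the `mask`.
#' @export
pseudo_color_hsi <- function(img, mask = NULL) {
  p <- if (inherits(img, "thermal_image")) img$pixels else as.matrix(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(p), ncol(p))
  if (!all(dim(mask) == dim(p))) stopf("mask shape does not match image")
  h <- matrix(270 / 360, nrow(p), ncol(p))   # reserved background hue
  s <- matrix(0, nrow(p), ncol(p))
  i <- matrix(0, nrow(p), ncol(p))
  if (any(mask)) {
    v <- p[mask]
    rng <- range(v)
    g <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
    i[mask] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0, length(v))
    h[mask] <- (240 * (1 - g)) / 360         # blue (cold) -> red (hot)
    s[mask] <- 1
  }
  structure(list(h = h, s = s, i = i, mask = mask), class = "pseudo_color")
}

#' Render a pseudo-colored image as RGB for display or file output
#' @param pc a `pseudo_color`.
#' @return h x w x 3 array in `[0,1]`.
#' @export
pseudo_color_rgb <- function(pc) {
  hsv_col <- grDevices::hsv(pmin(pmax(pc$h, 0), 1), pc$s,
                            pmin(pmax(0.25 + 0.75 * pc$i, 0), 1))
  rgb <- grDevices::col2rgb(hsv_col) / 255
  arr <- array(0, c(nrow(pc$h), ncol(pc$h), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow(pc$h))
  arr[, , 2] <- matrix(rgb[2, ], nrow(pc$h))
  arr[, , 3] <- matrix(rgb[3, ], nrow(pc$h))
  arr
}
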