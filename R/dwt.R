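# Separable 2-D discrete wavelet transform with the 4-tap Daubechies (D4)
# filter pair and periodic boundary handling. Only what the texture stage
# needs: one analysis/synthesis level and a multi-level approximation
# cascade; perfect reconstruction is exercised in the tests.

d4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # low-pass
  g <- rev(h) * c(1, -1, 1, -1)                           # high-pass (QMF)
  list(h = h, g = g)
}

# one-level analysis of the columns of x (periodic); returns low and high
# halves, each with nrow(x)/2 rows
#' @noRd
dwt_cols <- function(x, h, g) {
  n <- nrow(x)
  L <- length(h)
  # downsampled circular convolution: a_k = sum_m h[m] x[(2k-2+m-1) mod n + 1]
  idx <- outer(seq(1, n, by = 2), 0:(L - 1), function(s, m) ((s + m - 1) %% n) + 1)
  lo <- matrix(0, n / 2, ncol(x))
  hi <- matrix(0, n / 2, ncol(x))
  for (m in seq_len(L)) {
    rows <- idx[, m]
    lo <- lo + h[m] * x[rows, , drop = FALSE]
    hi <- hi + g[m] * x[rows, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# inverse of dwt_cols (periodic synthesis)
#' @noRd
idwt_cols <- function(lo, hi, h, g) {
  n2 <- nrow(lo); n <- 2L * n2
  L <- length(h)
  x <- matrix(0, n, ncol(lo))
  for (k in seq_len(n2)) {
    s <- 2L * k - 1L
    for (m in seq_len(L)) {
      pos <- ((s + m - 2L) %% n) + 1L
      x[pos, ] <- x[pos, ] + h[m] * lo[k, ] + g[m] * hi[k, ]
    }
  }
  x
}

#' One-level 2-D discrete wavelet transform (Daubechies-4, periodic)
#'
#' @param x numeric matrix with even dimensions.
#' @return list of sub-bands `ll`, `lh`, `hl`, `hh`, each half-size.
#' @export
dwt2 <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) %% 2L || ncol(x) %% 2L) stopf("dimensions must be even")
  f <- d4_filters()
  cols <- dwt_cols(x, f$h, f$g)
  rl <- dwt_cols(t(cols$lo), f$h, f$g)
  rh <- dwt_cols(t(cols$hi), f$h, f$g)
  list(ll = t(rl$lo), lh = t(rl$hi), hl = t(rh$lo), hh = t(rh$hi))
}

#' Inverse of [dwt2()]
#' @param bands list with `ll`, `lh`, `hl`, `hh`.
#' @return reconstructed matrix.
#' @export
idwt2 <- function(bands) {
  f <- d4_filters()
  lo <- t(idwt_cols(t(bands$ll), t(bands$lh), f$h, f$g))
  hi <- t(idwt_cols(t(bands$hl), t(bands$hh), f$h, f$g))
  idwt_cols(lo, hi, f$h, f$g)
}

#' Texture descriptors on wavelet sub-bands of a roi
#'
#' Crops the roi bounding box (background filled with the roi mean so the
#' transform sees no artificial step edge), applies `level` cascaded D4
#' decompositions, and computes the 21 co-occurrence descriptors on the
#' approximation band (optionally also on the three level-1 detail bands).
#' `level = 0` reduces to plain [texture_features()] on the roi.
#'
#' @param img_roi numeric matrix with `NA` outside the roi.
#' @param level decomposition depth (>= 0).
#' @param cfg a [glcm_config()].
#' @param include_details also return descriptors for `lh`, `hl`, `hh`.
#' @return named list of descriptor vectors, one per sub-band (`approx`
#'   always present).
#' @export
dwt_texture <- function(img_roi, level = 1L, cfg = glcm_config(),
                        include_details = FALSE) {
  m <- as.matrix(img_roi)
  roi <- is.finite(m)
  if (!any(roi)) stopf("roi is empty")
  if (level == 0L) return(list(approx = texture_features(m, cfg)))
  bb <- mask_bbox(roi)
  crop <- m[bb["rmin"]:bb["rmax"], bb["cmin"]:bb["cmax"], drop = FALSE]
  fill <- mean(crop[is.finite(crop)])
  crop[!is.finite(crop)] <- fill
  if (min(dim(crop)) < 2^level)
    stopf("roi bounding box smaller than 2^level in one dimension")
  # pad to even size by edge replication
  a <- crop
  out <- NULL
  for (l in seq_len(level)) {
    if (nrow(a) %% 2L) a <- rbind(a, a[nrow(a), ])
    if (ncol(a) %% 2L) a <- cbind(a, a[, ncol(a)])
    bands <- dwt2(a)
    if (l == 1L && include_details) out <- bands
    a <- bands$ll
  }
  res <- list(approx = texture_features(a, cfg))
  if (include_details)
    res <- c(res, lapply(out[c("lh", "hl", "hh")],
                         function(b) texture_features(b, cfg)))
  res
}
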