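#' GLCM configuration
#'
#' @param levels gray quantization count (>= 2), default 16: small enough to
#'   keep the co-occurrence matrix well populated on a focal roi.
#' @param distances pixel offsets, default 1.
#' @param angles directions in degrees among 0, 45, 90, 135; descriptors are
#'   averaged over angles.
#' @param symmetric count each pair in both orders, default TRUE.
#' @param normalize divide counts so entries sum to 1, default TRUE.
#' @export
glcm_config <- function(levels = 16L, distances = 1L,
                        angles = c(0, 45, 90, 135),
                        symmetric = TRUE, normalize = TRUE) {
  if (levels < 2) stopf("levels must be >= 2")
  if (any(distances < 1)) stopf("distances must be >= 1")
  if (!all(angles %in% c(0, 45, 90, 135)))
    stopf("angles must be among 0, 45, 90, 135")
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances), angles = angles,
                 symmetric = symmetric, normalize = normalize),
            class = "glcm_config")
}

# quantize roi values to 1..levels by equal-width binning over the roi range
#' @noRd
quantize_levels <- function(v, levels) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(1L, length(v)))
  q <- floor((v - rng[1]) / diff(rng) * levels) + 1L
  pmin(q, levels)
}

# (row, col) step for a glcm angle at unit distance; angles measured so 0
# degrees pairs a pixel with its right neighbour, 90 with the one above
#' @noRd
angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d))
}

#' Gray-level co-occurrence matrix
#'
#' Joint histogram of quantized gray levels of pixel pairs separated by a
#' given offset, restricted to pairs with both pixels inside the roi.
#' Background pixels never contribute. With `symmetric = TRUE` both pair
#' orders are counted so the matrix is symmetric; with `normalize = TRUE`
#' entries sum to 1 and can be read as pair probabilities.
#'
#' @param img_roi numeric matrix with `NA` outside the roi, or a plain
#'   matrix (all pixels in the roi).
#' @param cfg a [glcm_config()].
#' @param angle single direction in degrees; default the first configured.
#' @param distance single offset; default the first configured.
#' @return levels x levels matrix.
#' @examples
#' compute_glcm(matrix(c(0, 1, 0, 1), 2, 2), glcm_config(levels = 2), 0)
#' @export
compute_glcm <- function(img_roi, cfg = glcm_config(),
                         angle = cfg$angles[1], distance = cfg$distances[1]) {
  m <- as.matrix(img_roi)
  roi <- is.finite(m)
  if (sum(roi) < 2) stopf("roi must contain at least 2 pixels")
  q <- matrix(NA_integer_, nrow(m), ncol(m))
  q[roi] <- quantize_levels(m[roi], cfg$levels)
  off <- angle_offset(angle, distance)
  nr <- nrow(m); nc <- ncol(m)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  r2 <- r1 + off[1]; c2 <- c1 + off[2]
  vr <- r1[r2 >= 1 & r2 <= nr]; vc <- c1[c2 >= 1 & c2 <= nc]
  if (length(vr) == 0 || length(vc) == 0)
    stopf("roi thinner than the requested offset")
  a <- q[vr, vc, drop = FALSE]
  b <- q[vr + off[1], vc + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stopf("roi thinner than the requested offset")
  P <- matrix(0, cfg$levels, cfg$levels)
  tab <- table(factor(a[ok], levels = seq_len(cfg$levels)),
               factor(b[ok], levels = seq_len(cfg$levels)))
  P <- P + as.matrix(tab)
  if (cfg$symmetric) P <- P + t(P)
  if (cfg$normalize) P <- P / sum(P)
  unname(P)
}

#' Haralick-style texture descriptors of a co-occurrence matrix
#'
#' Computes the 21 descriptors used throughout the package from one
#' normalized GLCM, with the standard Haralick / Soh / Clausi definitions
#' (natural logarithms; gray levels indexed 1..N). `homogeneity` is the
#' inverse difference `sum p/(1+|i-j|)`, `idm` the inverse difference moment
#' `sum p/(1+(i-j)^2)`, `inn` and `idn` their range-normalized forms with
#' `|i-j|/N` and `(i-j)^2/N^2`. Sum variance is centred on the sum average.
#'
#' @param P normalized co-occurrence matrix (entries sum to 1).
#' @return named numeric vector of 21 descriptors.
#' @export
texture_descriptors <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stopf("P must be normalized (sum to 1)")
  N <- nrow(P)
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(N) * px); muy <- sum(seq_len(N) * py)
  sdx <- sqrt(sum((seq_len(N) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(N) - muy)^2 * py))

  # diagonal-band (difference) and anti-diagonal (sum) distributions
  k_sum <- 2:(2 * N)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_dif <- 0:(N - 1)
  p_dif <- vapply(k_dif, function(k) sum(P[abs(i - j) == k]), numeric(1))

  hxy <- -sum(xlogx(P))
  pxy <- px %o% py
  hxy1 <- -sum(P[pxy > 0] * log(pxy[pxy > 0]))
  hxy2 <- -sum(xlogx(pxy))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))

  sum_avg <- sum(k_sum * p_sum)
  corr <- if (sdx > 0 && sdy > 0)
    sum((i - mux) * (j - muy) * P) / (sdx * sdy) else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  c(autocorrelation     = sum(i * j * P),
    contrast            = sum((i - j)^2 * P),
    correlation         = corr,
    cluster_prominence  = sum((i + j - mux - muy)^4 * P),
    cluster_shade       = sum((i + j - mux - muy)^3 * P),
    dissimilarity       = sum(abs(i - j) * P),
    energy              = sum(P^2),
    entropy             = hxy,
    homogeneity         = sum(P / (1 + abs(i - j))),
    maximum_probability = max(P),
    variance            = sum((i - mux)^2 * P),
    sum_average         = sum_avg,
    sum_variance        = sum((k_sum - sum_avg)^2 * p_sum),
    sum_entropy         = -sum(xlogx(p_sum)),
    difference_variance = sum((k_dif - sum(k_dif * p_dif))^2 * p_dif),
    difference_entropy  = -sum(xlogx(p_dif)),
    imc1                = imc1,
    imc2                = imc2,
    inn                 = sum(P / (1 + abs(i - j) / N)),
    idn                 = sum(P / (1 + (i - j)^2 / N^2)),
    idm                 = sum(P / (1 + (i - j)^2)))
}

#' Texture features of a roi, averaged over directions
#'
#' Computes one GLCM per configured angle/distance and averages the 21
#' descriptors, the usual way of making the texture signature approximately
#' rotation-insensitive.
#'
#' @param img_roi numeric matrix with `NA` outside the roi.
#' @param cfg a [glcm_config()].
#' @return named numeric vector of 21 descriptors.
#' @export
texture_features <- function(img_roi, cfg = glcm_config()) {
  acc <- NULL
  count <- 0L
  for (d in cfg$distances) for (a in cfg$angles) {
    f <- texture_descriptors(compute_glcm(img_roi, cfg, a, d))
    acc <- if (is.null(acc)) f else acc + f
    count <- count + 1L
  }
  acc / count
}
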