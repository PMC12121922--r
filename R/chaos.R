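#' Serialize roi pixels into a scalar sequence
#'
#' The nonlinear indices (Lyapunov exponent, Kolmogorov-Sinai entropy,
#' correlation dimension) operate on a scalar sequence; the roi is unrolled
#' in a deterministic scan order. `hilbert` follows a Hilbert space-filling
#' curve over the roi bounding box, preserving 2-D locality better than
#' raster orders.
#'
#' @param img numeric matrix or [thermal_image()].
#' @param roi_mask logical mask; default all pixels.
#' @param order `"row_major"`, `"column_major"` or `"hilbert"`.
#' @return numeric vector, one value per roi pixel.
#' @export
image_to_series <- function(img, roi_mask = NULL,
                            order = c("row_major", "column_major", "hilbert")) {
  order <- match.arg(order)
  p <- if (inherits(img, "thermal_image")) img$pixels else as.matrix(img)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(p), ncol(p))
  if (!any(roi_mask)) stopf("roi is empty")
  switch(order,
    row_major = as.numeric(t(p))[as.logical(t(roi_mask))],
    column_major = p[roi_mask],
    hilbert = {
      bb <- mask_bbox(roi_mask)
      side <- 2^ceiling(log2(max(bb["rmax"] - bb["rmin"],
                                 bb["cmax"] - bb["cmin"]) + 1))
      path <- hilbert_path(side)
      rr <- path[, 1] + bb["rmin"] - 1L
      cc <- path[, 2] + bb["cmin"] - 1L
      ok <- rr <= nrow(p) & cc <= ncol(p)
      idx <- cbind(rr[ok], cc[ok])
      inroi <- roi_mask[idx]
      p[idx][inroi]
    })
}

# boundary pixels of a mask: roi cells 4-adjacent to background or the edge
#' @noRd
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
              pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !interior
}

# visiting order (row, col), 1-based, of the Hilbert curve on a side x side
# grid (side a power of 2); classic d2xy bit manipulation
#' @noRd
hilbert_path <- function(side) {
  n <- side * side
  d <- 0:(n - 1)
  x <- integer(n); y <- integer(n)
  t <- d
  s <- 1L
  while (s < side) {
    rx <- bitwAnd(1L, t %/% 2L)
    ry <- bitwAnd(1L, bitwXor(t, rx))
    # rotate quadrant: flip if rx == 1, then swap x/y (only when ry == 0)
    swap <- ry == 0L
    flip <- swap & rx == 1L
    x[flip] <- s - 1L - x[flip]; y[flip] <- s - 1L - y[flip]
    xs <- x[swap]
    x[swap] <- y[swap]; y[swap] <- xs
    x <- x + s * rx
    y <- y + s * ry
    t <- t %/% 4L
    s <- s * 2L
  }
  cbind(y + 1L, x + 1L)
}

#' Box-counting fractal dimension of a binary set
#'
#' Covers the set with grids of square boxes of side s (grid anchored at the
#' set's bounding-box corner), counts occupied boxes N(s) for a ladder of
#' dyadic sizes, and returns the slope of the least-squares line of log N(s)
#' against log(1/s). A smooth curve gives ~1, a filled region ~2, and an
#' irregular margin pushes the estimate upward; this is the shape-complexity
#' index extracted from the segmented hot region.
#'
#' @param binary_image 0/1 or logical matrix (or an `attractor_series`
#'   carrying an image).
#' @param box_sizes box sides in pixels; default powers of 2 from 2 to
#'   min(image height, width)/4. At least 3 sizes are required.
#' @return the dimension estimate, with attribute `counts` (N(s) table).
#' @export
box_counting_fd <- function(binary_image, box_sizes = NULL) {
  if (inherits(binary_image, "attractor_series"))
    binary_image <- binary_image$image
  b <- as.matrix(binary_image) != 0
  if (!any(b)) stopf("binary set is empty")
  if (is.null(box_sizes)) {
    smax <- min(dim(b)) / 4
    if (smax < 2) stopf("image too small for box counting")
    box_sizes <- 2^(1:floor(log2(smax)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3) stopf("need at least 3 box sizes")
  idx <- which(b, arr.ind = TRUE)
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  counts <- vapply(box_sizes, function(s) {
    br <- (idx[, 1] - r0) %/% s
    bc <- (idx[, 2] - c0) %/% s
    length(unique(br * (max(bc) + 1L + 1L) + bc))
  }, numeric(1))
  if (all(counts == 1)) stopf("scale range too narrow: one occupied box at every scale")
  fit <- stats::lm(log(counts) ~ log(1 / box_sizes))
  structure(unname(stats::coef(fit)[2]),
            counts = data.frame(size = box_sizes, n = counts))
}

#' Time-delay embedding configuration
#'
#' @param dim embedding dimension m (`NULL` = choose by false nearest
#'   neighbours, capped at `max_dim`).
#' @param delay lag in samples (`NULL` = first minimum of the auto mutual
#'   information).
#' @param theiler temporal exclusion window for neighbour searches
#'   (`NULL` = `dim * delay`).
#' @param max_dim cap for the automatic dimension search.
#' @export
embedding_config <- function(dim = NULL, delay = NULL, theiler = NULL,
                             max_dim = 10L) {
  structure(list(dim = dim, delay = delay, theiler = theiler,
                 max_dim = as.integer(max_dim)), class = "embedding_config")
}

#' Delay from the first minimum of the auto mutual information
#' @param series numeric vector.
#' @param max_lag largest lag examined.
#' @param bins histogram resolution.
#' @return lag in samples (>= 1).
#' @export
delay_ami <- function(series, max_lag = 50L, bins = 16L) {
  n <- length(series)
  max_lag <- min(max_lag, n %/% 4L)
  q <- quantize_levels(series, bins)
  mutual <- function(a, b) {
    pj <- table(a, b) / length(a)
    pa <- rowSums(pj); pb <- colSums(pj)
    sum(pj[pj > 0] * log(pj[pj > 0] / (pa %o% pb)[pj > 0]))
  }
  ami0 <- mutual(q, q)                  # self-information reference
  ami <- vapply(seq_len(max_lag), function(lag)
    mutual(q[1:(n - lag)], q[(1 + lag):n]), numeric(1))
  # first local minimum, or the first 1/e drop below the lag-0 information
  # (map-like series whose information collapses immediately get lag 1)
  for (lag in seq_len(max_lag)) {
    if (ami[lag] < ami0 / exp(1)) return(lag)
    if (lag < max_lag && ami[lag + 1L] > ami[lag]) return(lag)
  }
  max_lag
}

#' Embedding dimension by false nearest neighbours
#'
#' Standard Kennel criterion: the smallest dimension at which fewer than
#' `frac` of nearest neighbours are "false" (their distance grows by more
#' than `rtol` when the next delay coordinate is appended).
#'
#' @param series numeric vector.
#' @param delay lag in samples.
#' @param max_dim cap on the search.
#' @param rtol growth-ratio threshold.
#' @param frac acceptable false-neighbour fraction.
#' @param max_points subsample cap for the O(n^2) neighbour search.
#' @return embedding dimension.
#' @export
fnn_dim <- function(series, delay, max_dim = 10L, rtol = 10, frac = 0.05,
                    max_points = 400L) {
  sdev <- stats::sd(series)
  if (sdev == 0) return(1L)
  for (m in seq_len(max_dim)) {
    e1 <- embed_series(series, m, delay)
    e2 <- embed_series(series, m + 1L, delay)
    n <- nrow(e2)
    if (n < 20L) return(max(1L, m - 1L))
    keep <- if (n > max_points)
      round(seq(1L, n, length.out = max_points)) else seq_len(n)
    a <- e1[keep, , drop = FALSE]
    d2 <- pair_sqdist(a, e1[seq_len(n), , drop = FALSE])
    for (ii in seq_along(keep)) d2[ii, keep[ii]] <- Inf
    nn <- max.col(-d2, ties.method = "first")
    dn <- sqrt(d2[cbind(seq_along(keep), nn)])
    extra <- abs(e2[keep, m + 1L] - e2[nn, m + 1L])
    false_nn <- extra / pmax(dn, 1e-12) > rtol | dn / sdev > 2
    if (mean(false_nn) < frac) return(m)
  }
  max_dim
}

#' Delay embedding of a scalar series
#' @param series numeric vector.
#' @param m embedding dimension.
#' @param delay lag in samples.
#' @return (n - (m-1) delay) x m matrix; row t is
#'   (x_t, x_{t+delay}, ..., x_{t+(m-1) delay}).
#' @export
embed_series <- function(series, m, delay) {
  n <- length(series) - (m - 1L) * delay
  if (n < 2L) stopf("series too short for this embedding")
  sapply(0:(m - 1L), function(k) series[(1L + k * delay):(n + k * delay)])
}

# resolve an embedding_config against a concrete series
#' @noRd
resolve_embedding <- function(series, emb) {
  if (is.null(emb)) emb <- embedding_config()
  delay <- emb$delay %||% delay_ami(series)
  dim <- emb$dim %||% fnn_dim(series, delay, emb$max_dim)
  theiler <- emb$theiler %||% (dim * delay)
  list(dim = dim, delay = delay, theiler = theiler)
}

#' Largest Lyapunov exponent by the Jacobian (local-map) method
#'
#' Reconstructs the orbit by time-delay embedding, fits a local affine map
#' at each orbit point by least squares over its nearest neighbours
#' (excluding temporally adjacent points by a Theiler window), and
#' accumulates the fitted Jacobians along the orbit with QR
#' re-orthonormalisation. The largest exponent is the mean log growth of the
#' leading direction, in nats per sample. Positive values indicate sensitive
#' dependence on initial conditions; regular motion gives ~0.
#'
#' Defaults differ from the other series indices: the Jacobian method is
#' classically run at unit delay, and the regression needs more room than
#' the minimal unfolding, so the automatic dimension is the Takens-style
#' `2 m_fnn + 1` (capped at `max_dim`) rather than the bare
#' false-nearest-neighbour estimate.
#'
#' @param series numeric vector. At least ~500 samples are recommended for a
#'   stable estimate; the hard floor is 120 (short roi series still yield a
#'   usable comparative index).
#' @param emb an [embedding_config()] or `NULL` for automatic choices.
#' @param n_neighbors neighbours per local fit; default `2 * m + 4`.
#' @param ridge Tikhonov regularisation for near-degenerate local fits.
#' @return the exponent (nats/step), with attribute `embedding`.
#' @examples
#' \donttest{
#' s <- generate_series("logistic", list(r = 4), n = 2000, seed = 1)
#' lle_jacobian(s$values)  # close to log(2)
#' }
#' @export
lle_jacobian <- function(series, emb = NULL, n_neighbors = NULL,
                         ridge = 1e-8) {
  if (length(series) < 120) stopf("series must have length >= 120")
  if (stats::sd(series) == 0) {
    warnf("degenerate constant series; exponent reported as 0")
    return(structure(0, embedding = list(dim = 1L, delay = 1L)))
  }
  if (is.null(emb)) emb <- embedding_config()
  tau <- emb$delay %||% 1L
  m <- emb$dim %||% min(2L * fnn_dim(series, tau, emb$max_dim) + 1L,
                        emb$max_dim)
  w <- emb$theiler %||% (m * tau)
  e <- list(dim = m, delay = tau, theiler = w)
  x <- embed_series(series, m, tau)
  n <- nrow(x) - 1L                      # transitions t -> t+1
  if (n <= m * 10L) stopf("too few embedded points for the Jacobian fits")
  k <- n_neighbors %||% (2L * m + 4L)
  k <- min(k, n - 2L * w - 2L)           # shrink for short series
  if (k < m + 2L) stopf("too few neighbours for the local fits")

  Q <- diag(1, m)
  logsum <- 0
  steps <- 0L
  xt <- x[seq_len(n), , drop = FALSE]
  for (t in seq_len(n)) {
    d2 <- rowSums((xt - matrix(x[t, ], n, m, byrow = TRUE))^2)
    excl <- max(1L, t - w):min(n, t + w)
    d2[excl] <- Inf
    nb <- order(d2)[seq_len(k)]
    X <- cbind(1, xt[nb, , drop = FALSE] -
                    matrix(x[t, ], k, m, byrow = TRUE))
    Y <- x[nb + 1L, , drop = FALSE] - matrix(x[t + 1L, ], k, m, byrow = TRUE)
    XtX <- crossprod(X) + diag(ridge, m + 1L)
    A <- solve(XtX, crossprod(X, Y))     # (m+1) x m; rows 2.. are Jacobian^T
    J <- t(A[-1, , drop = FALSE])
    qrz <- qr(J %*% Q)
    Q <- qr.Q(qrz)
    rdiag <- abs(diag(qr.R(qrz)))
    logsum <- logsum + log(max(rdiag[1], 1e-300))
    steps <- steps + 1L
  }
  structure(logsum / steps, embedding = e)
}

#' Kolmogorov-Sinai entropy estimate (sample-entropy form)
#'
#' Rate of information production estimated as
#' `-ln(C_{m+1}(r) / C_m(r))`: the negative log conditional probability that
#' two sequences matching within tolerance `r` over `m` points (Chebyshev
#' distance) still match at the next point. Self-matches are excluded.
#' Regular series score near 0; irregular ones score higher. With `r`
#' proportional to the series SD the index is invariant under affine
#' rescaling of the series.
#'
#' @param series numeric vector; around 100 samples or more are needed for a
#'   stable estimate (the hard floor is `4 * (m + 1)`).
#' @param m template length, default 2.
#' @param r tolerance; default `0.2 * sd(series)`.
#' @return entropy estimate (nats).
#' @export
ks_entropy <- function(series, m = 2L, r = NULL) {
  n <- length(series)
  if (n < 4L * (m + 1L)) stopf("series too short for template length m = %d", m)
  sdev <- stats::sd(series)
  if (sdev == 0) return(0)
  r <- r %||% (0.2 * sdev)
  if (r <= 0) stopf("tolerance r must be positive")
  ntempl <- n - m                       # same template count for both lengths
  xm <- embed_series(series, m, 1L)[seq_len(ntempl), , drop = FALSE]
  xm1 <- embed_series(series, m + 1L, 1L)
  a <- template_matches(xm, r)
  b <- template_matches(xm1, r)
  if (b == 0) stopf("no template matches at length m+1; increase r")
  -log(b / a)
}

# number of unordered template pairs (i < j) matching within r (Chebyshev)
#' @noRd
template_matches <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  cnt <- 0
  for (i in seq_len(n - 1L)) {
    rows <- (i + 1L):n
    cheb <- abs(x[rows, 1L] - x[i, 1L])
    for (j in seq_len(m - 1L) + 1L)
      cheb <- pmax(cheb, abs(x[rows, j] - x[i, j]))
    cnt <- cnt + sum(cheb <= r)
  }
  cnt
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Computes the correlation sum
#' `C(r) = (pairs closer than r) / (eligible pairs)` over a ladder of radii
#' (pairs within the Theiler window are ineligible) and returns the slope of
#' `log C(r)` against `log r` over the scaling region. The default radii run
#' from the 1st to the 10th percentile of the pairwise distances: the
#' correlation sum only scales as `r^D` for radii well below the attractor
#' size, and wider windows visibly flatten the slope on sets of known
#' dimension through boundary saturation. If the log-log fit is not linear
#' there (R^2 < 0.98) the largest radii are dropped until it is.
#'
#' @param x numeric series (embedded via `emb`) or an already-embedded
#'   point matrix.
#' @param emb an [embedding_config()] or `NULL` (ignored for matrices).
#' @param radii radii ladder; `NULL` for the percentile default.
#' @param max_points deterministic subsample cap for the O(n^2) pair count.
#' @param r2_min linear-region acceptance threshold.
#' @return dimension estimate with attributes `radii` and `corr_sum`.
#' @export
correlation_dimension <- function(x, emb = NULL, radii = NULL,
                                  max_points = 600L, r2_min = 0.98) {
  if (is.matrix(x)) {
    pts <- x
    theiler <- 0L
  } else {
    e <- resolve_embedding(x, emb)
    pts <- embed_series(x, e$dim, e$delay)
    theiler <- e$theiler
  }
  n <- nrow(pts)
  if (n > max_points) {
    keep <- round(seq(1L, n, length.out = max_points))
    pts <- pts[keep, , drop = FALSE]
    idx <- keep
  } else idx <- seq_len(n)
  n <- nrow(pts)
  if (n < 200L) stopf("need at least 200 embedded points")
  dmat <- as.matrix(stats::dist(pts))
  sep <- abs(outer(idx, idx, "-"))
  eligible <- upper.tri(dmat) & sep > theiler
  dvec <- dmat[eligible]
  if (length(dvec) < 100L) stopf("too few eligible pairs")
  if (is.null(radii)) {
    qs <- stats::quantile(dvec[dvec > 0], c(0.01, 0.10))
    if (qs[1] <= 0 || qs[2] <= qs[1]) stopf("empty scaling region")
    radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = 12))
  } else if (max(radii) / min(radii) < 10) {
    warnf("supplied radii span less than one decade")
  }
  radii <- sort(radii)
  cs <- vapply(radii, function(r) mean(dvec <= r), numeric(1))
  ok <- cs > 0
  if (sum(ok) < 3) stopf("empty scaling region")
  lr <- log(radii[ok]); lc <- log(cs[ok])
  repeat {
    fit <- stats::lm(lc ~ lr)
    r2 <- summary(fit)$r.squared
    if (r2 >= r2_min || length(lr) <= 4L) break
    lr <- lr[-length(lr)]; lc <- lc[-length(lc)]   # trim the largest radius
  }
  structure(unname(stats::coef(fit)[2]),
            radii = radii, corr_sum = cs)
}

#' The four chaotic indices of a segmented thermogram
#'
#' Fractal dimension is computed on the binary roi (boundary + interior
#' set); the Lyapunov exponent, Kolmogorov-Sinai entropy and correlation
#' dimension on the scalar series of roi gray levels in the configured scan
#' order (decimated to at most `max_series` samples to bound the quadratic
#' neighbour searches). `fd_on_series = TRUE` switches the fractal dimension
#' to the gray-level series route as well (delay-embedded point set).
#'
#' A common fixed embedding (dimension 3, unit delay) is used for every
#' image rather than a per-image automatic choice: the indices feed a
#' classifier, so comparability across images outweighs per-image embedding
#' optimality.
#'
#' The fractal dimension is taken on the roi *boundary* by default: the
#' interior of a solid region has dimension 2 regardless of the lesion, so
#' the margin irregularity that distinguishes infiltrative growth lives in
#' the boundary set. `fd_input = "region"` uses the filled roi,
#' `fd_input = "series"` a delay-embedded point-set dimension of the
#' gray-level series.
#'
#' @param img [thermal_image()] or matrix.
#' @param roi_mask logical roi.
#' @param order scan order for [image_to_series()].
#' @param emb an [embedding_config()]; `NULL` falls back to the fixed
#'   (dim 3, delay 1) embedding.
#' @param max_series decimation cap for the series-based indices.
#' @param fd_input `"boundary"` (default), `"region"` or `"series"`.
#' @return named numeric vector `fd`, `lle`, `kse`, `cd`.
#' @export
chaotic_features <- function(img, roi_mask, order = "row_major", emb = NULL,
                             max_series = 900L,
                             fd_input = c("boundary", "region", "series")) {
  fd_input <- match.arg(fd_input)
  p <- if (inherits(img, "thermal_image")) img$pixels else as.matrix(img)
  fd_set <- if (fd_input == "boundary") mask_boundary(roi_mask) else roi_mask
  series <- image_to_series(p, roi_mask, order)
  if (length(series) > max_series)
    series <- series[round(seq(1L, length(series), length.out = max_series))]
  if (stats::sd(series) == 0)
    return(c(fd = box_counting_fd(fd_set), lle = 0, kse = 0, cd = 0))
  e <- if (is.null(emb)) list(dim = 3L, delay = 1L, theiler = 3L)
       else resolve_embedding(series, emb)
  fd <- if (fd_input == "series") {
    pts <- embed_series(series, max(2L, e$dim), e$delay)
    correlation_dimension(pts)
  } else box_counting_fd(fd_set)
  lle <- tryCatch(as.numeric(lle_jacobian(series, embedding_config(
    dim = e$dim, delay = e$delay, theiler = e$theiler))),
    error = function(err) NA_real_)
  kse <- tryCatch(ks_entropy(series), error = function(err) NA_real_)
  cd <- tryCatch(as.numeric(correlation_dimension(series, embedding_config(
    dim = e$dim, delay = e$delay, theiler = e$theiler))),
    error = function(err) NA_real_)
  c(fd = as.numeric(fd), lle = lle, kse = kse, cd = cd)
}
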