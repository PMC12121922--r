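#' Fuzzy c-means configuration
#'
#' @param k number of clusters (>= 2), default 4.
#' @param m fuzziness exponent (> 1), default 2.
#' @param max_iter iteration cap, default 300.
#' @param tol convergence tolerance on the maximum centre shift, default 1e-5.
#' @param seed integer seed for the centre initialisation.
#' @return an `fcm_config` list.
#' @export
fcm_config <- function(k = 4L, m = 2, max_iter = 300L, tol = 1e-5, seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  if (m <= 1) stopf("fuzziness exponent m must be > 1")
  if (tol <= 0) stopf("tol must be positive")
  structure(list(k = as.integer(k), m = m, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)), class = "fcm_config")
}

#' Fuzzy c-means clustering
#'
#' Canonical fuzzy c-means on a set of feature vectors: memberships
#' `u_ij = 1 / sum_l (d_ij / d_lj)^(2/(m-1))` from Euclidean distances to the
#' centres, centres updated as membership^m-weighted means, alternated until
#' the maximum centre shift drops below `tol`. Unlike hard k-means every
#' point belongs to every cluster with a graded membership (rows sum to 1),
#' which suits thermograms where temperature transitions are gradual.
#' Centres are initialised with a seeded k-means++-style spread so runs are
#' reproducible.
#'
#' @param x n x d numeric matrix of feature vectors (one row per pixel).
#' @param cfg an [fcm_config()].
#' @return an `fcm_fit`: `memberships` (n x k), `centers` (k x d),
#'   `cluster` (hard argmax labels), `objective_trace` (objective after each
#'   full iteration; non-increasing), `converged` flag, `iterations`.
#' @export
fcm_cluster <- function(x, cfg = fcm_config()) {
  x <- as.matrix(x)
  n <- nrow(x); k <- cfg$k
  n_distinct <- nrow(unique(x))
  if (n_distinct < k)
    stopf("k = %d exceeds the number of distinct points (%d)", k, n_distinct)

  centers <- with_seed(cfg$seed, kmeanspp_init(x, k))
  expo <- 2 / (cfg$m - 1)
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  u <- NULL
  for (it in seq_len(cfg$max_iter)) {
    d2 <- pmax(pair_sqdist(x, centers), 1e-300)        # n x k
    # membership update: u_ij = 1 / sum_l (d_ij/d_lj)^(2/(m-1))
    dd <- d2^(expo / 2)
    u <- (1 / dd) / rowSums(1 / dd)
    um <- u^cfg$m
    new_centers <- t(um) %*% x / colSums(um)
    trace <- c(trace, sum(um * pair_sqdist(x, new_centers)))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    iterations <- it
    if (shift < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("fuzzy c-means did not converge in %d iterations", cfg$max_iter)
  d2 <- pmax(pair_sqdist(x, centers), 1e-300)
  dd <- d2^(expo / 2)
  u <- (1 / dd) / rowSums(1 / dd)
  structure(list(memberships = u, centers = centers,
                 cluster = max.col(u, ties.method = "first"),
                 objective_trace = trace, converged = converged,
                 iterations = iterations, config = cfg), class = "fcm_fit")
}

# squared Euclidean distances between rows of a and rows of b
#' @noRd
pair_sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * a %*% t(b)
  pmax(d, 0)
}

# k-means++ style seeding: first centre uniform, later centres with
# probability proportional to squared distance from the nearest centre
#' @noRd
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  for (j in 2:k) {
    d2 <- apply(pair_sqdist(x, centers[seq_len(j - 1), , drop = FALSE]),
                1, min)
    if (sum(d2) == 0) centers[j, ] <- x[sample.int(n, 1), ]
    else centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
  }
  centers
}

#' Segment a thermogram and extract the hottest region
#'
#' Full segmentation stage: Otsu foreground mask, HSI pseudo-coloring,
#' fuzzy c-means on the per-pixel (hue, saturation, intensity) triples of the
#' foreground, selection of the hottest cluster as region of interest,
#' optional axilla/sternum band exclusion, and the final binary image handed
#' to the nonlinear feature extractors.
#'
#' The image handed to the clustering step is lightly smoothed (two 3x3 box
#' passes): the hot region is a contiguous warm area with internal texture,
#' and clustering raw gray levels would split it into bright and dim grain
#' clusters. Texture and nonlinear features are still computed from the raw
#' pixels inside the resulting roi.
#'
#' @param img a [thermal_image()].
#' @param cfg an [fcm_config()].
#' @param exclusion exclusion config from [exclusion_config()], or `NULL` to
#'   skip band exclusion.
#' @param smooth_passes 3x3 box-blur passes applied to the clustering copy
#'   of the image (0 = cluster raw gray levels).
#' @return a `segmentation_result`: `cluster_map` (0 = background),
#'   `memberships`, `centers`, `roi_mask`, `binary_image`, `fg_mask`,
#'   `pseudo_color`, `fcm` (the raw fit).
#' @export
segment_thermogram <- function(img, cfg = fcm_config(), exclusion = NULL,
                               smooth_passes = 2L) {
  fg <- otsu_mask(img)
  smoothed <- if (smooth_passes > 0L) box_blur(img$pixels, smooth_passes)
              else img$pixels
  pc <- pseudo_color_hsi(smoothed, fg)
  feat <- cbind(h = pc$h[fg], s = pc$s[fg], i = pc$i[fg])
  fit <- fcm_cluster(feat, cfg)
  cluster_map <- matrix(0L, nrow(img$pixels), ncol(img$pixels))
  cluster_map[fg] <- fit$cluster
  res <- structure(list(cluster_map = cluster_map,
                        memberships = fit$memberships,
                        centers = fit$centers, fg_mask = fg,
                        pseudo_color = pc, fcm = fit),
                   class = "segmentation_result")
  # a strongly textured hot region can straddle two intensity clusters (its
  # bright and dim grain populations); the hot *region* is every cluster
  # above the largest gap in cluster mean intensity. Closing + hole filling
  # then solidifies speckle. select_hot_cluster() remains the single-cluster
  # primitive.
  res$roi_mask <- fill_holes(binary_close(binary_close(
    merge_hot_clusters(res, img))))
  if (!is.null(exclusion))
    res$roi_mask <- exclude_regions(res$roi_mask, exclusion, torso_mask = fg)
  res$binary_image <- binarize_roi(img, res$roi_mask)
  res
}

#' Select the hottest cluster as region of interest
#'
#' The hottest cluster is the one whose pixels have the largest mean source
#' intensity; in a breast thermogram this is the suspected hypermetabolic
#' focal region. A tie is resolved toward the larger cluster, with a warning.
#'
#' @param res a `segmentation_result` (or any list with `cluster_map`).
#' @param img the source [thermal_image()].
#' @return logical roi mask.
#' @export
select_hot_cluster <- function(res, img) {
  cm <- res$cluster_map
  ids <- sort(unique(cm[cm > 0L]))
  if (length(ids) == 0L) stopf("no clusters present")
  means <- vapply(ids, function(j) mean(img$pixels[cm == j]), numeric(1))
  sizes <- vapply(ids, function(j) sum(cm == j), numeric(1))
  top <- which(abs(means - max(means)) < 1e-12)
  if (length(top) > 1L) {
    warnf("tie in cluster mean intensity; picking the larger cluster")
    top <- top[which.max(sizes[top])]
  }
  cm == ids[top]
}

#' Hottest-region mask by intensity-gap cluster merging
#'
#' Returns the union of all clusters whose mean source intensity lies above
#' the midpoint between the coldest and hottest cluster means: the "hot
#' side" of the intensity hierarchy. When the hot region is a single
#' cluster this reduces to [select_hot_cluster()]; when internal texture
#' splits it into a bright and a dim cluster, both are kept.
#'
#' @param res a `segmentation_result` (or any list with `cluster_map`).
#' @param img the source [thermal_image()].
#' @return logical roi mask.
#' @export
merge_hot_clusters <- function(res, img) {
  cm <- res$cluster_map
  ids <- sort(unique(cm[cm > 0L]))
  if (length(ids) < 2L) return(cm > 0L)
  means <- vapply(ids, function(j) mean(img$pixels[cm == j]), numeric(1))
  hot <- ids[means > (min(means) + max(means)) / 2]
  if (length(hot) == 0L) hot <- ids[which.max(means)]
  matrix(cm %in% hot, nrow(cm), ncol(cm))
}

#' Exclusion-band configuration for axilla and sternum removal
#'
#' @param axilla_frac fraction of the torso bounding-box height, measured
#'   from the top, removed from the roi (armpit hot folds).
#' @param sternum_frac fraction of the torso bounding-box width, centred,
#'   removed (sternal notch/midline heat).
#' @param keep_largest keep only the largest connected component on each
#'   body side after band removal.
#' @export
exclusion_config <- function(axilla_frac = 0.15, sternum_frac = 0.10,
                             keep_largest = TRUE) {
  structure(list(axilla_frac = axilla_frac, sternum_frac = sternum_frac,
                 keep_largest = keep_largest), class = "exclusion_config")
}

#' Remove axilla and sternal bands from a roi mask
#'
#' Removes the top `axilla_frac` of the torso bounding box and a centred
#' vertical band of width `sternum_frac`, then (optionally) keeps only the
#' largest connected component on each side of the midline.
#'
#' @param roi_mask logical matrix.
#' @param exclusion an [exclusion_config()].
#' @param torso_mask logical foreground mask defining the bounding box;
#'   defaults to the roi itself.
#' @return pruned logical roi mask.
#' @export
exclude_regions <- function(roi_mask, exclusion = exclusion_config(),
                            torso_mask = roi_mask) {
  if (!any(roi_mask)) stopf("roi mask is empty")
  bb <- mask_bbox(torso_mask)
  out <- roi_mask
  if (exclusion$axilla_frac > 0) {
    cut_row <- bb["rmin"] + exclusion$axilla_frac * (bb["rmax"] - bb["rmin"])
    out[seq_len(nrow(out)) < cut_row, ] <- FALSE
  }
  if (exclusion$sternum_frac > 0) {
    mid <- (bb["cmin"] + bb["cmax"]) / 2
    half <- exclusion$sternum_frac * (bb["cmax"] - bb["cmin"]) / 2
    cols <- seq_len(ncol(out))
    out[, cols > mid - half & cols < mid + half] <- FALSE
  }
  if (!any(out)) stopf("exclusion removed the entire roi")
  if (isTRUE(exclusion$keep_largest)) {
    mid <- (bb["cmin"] + bb["cmax"]) / 2
    keep <- matrix(FALSE, nrow(out), ncol(out))
    for (side in c("left", "right")) {
      sel <- out
      if (side == "left") sel[, seq_len(ncol(out)) > mid] <- FALSE
      else sel[, seq_len(ncol(out)) <= mid] <- FALSE
      if (!any(sel)) next
      lab <- label_components(sel)
      sizes <- tabulate(lab[lab > 0L])
      keep <- keep | (lab == which.max(sizes))
    }
    if (any(keep)) out <- keep
  }
  out
}

#' Binary image of the region of interest
#'
#' @param img source image (unused beyond shape checking; kept for a uniform
#'   stage signature).
#' @param roi_mask logical roi.
#' @return integer 0/1 matrix, 1 inside the roi.
#' @export
binarize_roi <- function(img, roi_mask) {
  if (!any(roi_mask)) stopf("roi mask is empty")
  p <- if (inherits(img, "thermal_image")) img$pixels else as.matrix(img)
  if (!all(dim(p) == dim(roi_mask))) stopf("roi shape does not match image")
  matrix(as.integer(roi_mask), nrow(roi_mask), ncol(roi_mask))
}
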