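#' Full 25-feature signature of one thermogram
#'
#' Segments the image ([segment_thermogram()]), computes the 21
#' co-occurrence texture descriptors on the roi gray levels and the four
#' chaotic indices (fractal dimension on the binary roi; Lyapunov exponent,
#' Kolmogorov-Sinai entropy and correlation dimension on the roi gray-level
#' series), and returns them as one named vector.
#'
#' @param img a [thermal_image()].
#' @param fcm an [fcm_config()].
#' @param glcm a [glcm_config()].
#' @param emb an [embedding_config()] or `NULL` for automatic embedding.
#' @param exclusion an [exclusion_config()] or `NULL` (default) to skip the
#'   axilla/sternum bands (phantoms have no axilla).
#' @param order scan order for the pixel series.
#' @param use_dwt compute the texture block on the level-1 wavelet
#'   approximation band instead of the raw roi.
#' @return named numeric vector of length 25.
#' @export
extract_features <- function(img, fcm = fcm_config(), glcm = glcm_config(),
                             emb = NULL, exclusion = NULL,
                             order = "row_major", use_dwt = FALSE) {
  seg <- segment_thermogram(img, fcm, exclusion)
  roi_img <- img$pixels
  roi_img[!seg$roi_mask] <- NA_real_
  tex <- if (use_dwt) dwt_texture(roi_img, level = 1L, cfg = glcm)$approx
         else texture_features(roi_img, glcm)
  chaos <- chaotic_features(img, seg$roi_mask, order = order, emb = emb)
  c(tex, chaos)
}

#' Feature table of an image batch
#'
#' @param imgs list of [thermal_image()]s (e.g. phantoms).
#' @param ... passed to [extract_features()].
#' @param progress print a dot every 25 images.
#' @return data.frame with 25 feature columns plus `id`.
#' @export
feature_table <- function(imgs, ..., progress = FALSE) {
  rows <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    rows[[i]] <- extract_features(imgs[[i]], ...)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- as.data.frame(do.call(rbind, rows))
  # a failed series index (tiny roi) yields NA; impute the column median so
  # the table stays usable by every classifier
  for (j in seq_along(out)) {
    miss <- is.na(out[[j]])
    if (any(miss)) out[[j]][miss] <- stats::median(out[[j]], na.rm = TRUE)
  }
  out$id <- vapply(imgs, function(im) im$id, character(1))
  out
}

#' Generate a labelled phantom cohort
#'
#' Draws `n_per_class` benign and `n_per_class` malignant phantom specs
#' (class-conditional parameter jitter, see [sample_phantom_specs()]) and
#' renders them.
#'
#' @param n_per_class images per class.
#' @param seed integer seed.
#' @param width,height image size.
#' @return list with `images` (list of `thermal_image`) and `labels`
#'   (factor, levels benign < malignant).
#' @export
phantom_cohort <- function(n_per_class, seed = 1L, width = 64L,
                           height = 64L) {
  specs <- c(sample_phantom_specs(n_per_class, "benign", seed = seed,
                                  width = width, height = height),
             sample_phantom_specs(n_per_class, "malignant", seed = seed + 1L,
                                  width = width, height = height))
  imgs <- lapply(specs, generate_phantom)
  for (i in seq_along(imgs)) imgs[[i]]$id <- sprintf("phantom_%03d.png", i)
  labels <- factor(vapply(imgs, function(im) im$label, character(1)),
                   levels = c("benign", "malignant"))
  list(images = imgs, labels = labels, specs = specs)
}
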