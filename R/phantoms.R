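#' Phantom thermogram specification
#'
#' Describes one synthetic frontal breast thermogram: a warm torso ellipse on
#' a cold background carrying two breast mounds and one elliptical hot spot.
#' The hot spot stands in for the hypermetabolic, hypervascular focal region
#' that a tumour produces in an infrared image. Two knobs carry the
#' class-dependent structure: `boundary_roughness` perturbs the hot-spot rim
#' with low-order Fourier modes (irregular margins raise the box-counting
#' dimension of the segmented region), and `texture_contrast` /
#' `texture_corr_len` control a Gaussian random field inside the spot
#' (stronger, shorter-range fluctuations raise co-occurrence contrast,
#' entropy and sample entropy of the pixel series). Malignant defaults are
#' strictly rougher and higher-contrast than benign defaults.
#'
#' @param label `"benign"` or `"malignant"`; selects the default knob values.
#' @param width,height image size in pixels, at least 64.
#' @param hotspot_center (row, col) of the hot-spot centre; default places it
#'   in the left breast mound.
#' @param hotspot_radius mean hot-spot radius in pixels.
#' @param boundary_roughness rim perturbation amplitude in `[0, 1]` (fraction
#'   of the radius carried by the Fourier modes).
#' @param texture_contrast standard deviation, in gray levels, of the random
#'   field inside the hot spot.
#' @param texture_corr_len correlation length of that field, pixels.
#' @param noise_sd additive white measurement noise, gray levels. Kept well
#'   below the texture amplitude: camera noise common to both classes would
#'   otherwise dominate the series irregularity and wash out the configured
#'   class contrast.
#' @param seed integer seed; the phantom is a pure function of the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(label = c("benign", "malignant"),
                         width = 64L, height = 64L,
                         hotspot_center = NULL,
                         hotspot_radius = NULL,
                         boundary_roughness = NULL,
                         texture_contrast = NULL,
                         texture_corr_len = NULL,
                         noise_sd = 3,
                         seed = 1L) {
  label <- match.arg(label)
  def <- phantom_class_defaults(label)
  spec <- list(
    label = label,
    width = as.integer(width), height = as.integer(height),
    hotspot_center = hotspot_center %||%
      c(round(0.62 * height), round(0.32 * width)),
    hotspot_radius = hotspot_radius %||% def$radius,
    boundary_roughness = boundary_roughness %||% def$roughness,
    texture_contrast = texture_contrast %||% def$contrast,
    texture_corr_len = texture_corr_len %||% def$corr_len,
    noise_sd = noise_sd,
    seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

# Class-conditional defaults: the malignant spot has an irregular rim and a
# stronger, rougher internal temperature field than the benign one.
#' @noRd
phantom_class_defaults <- function(label) {
  # contrasts are kept close (malignant still strictly larger): texture
  # irregularity is carried by the correlation length, and near-equal
  # amplitude keeps the camera-noise share comparable across classes
  if (label == "malignant") {
    list(roughness = 0.55, contrast = 16, corr_len = 1.2, radius = 12)
  } else {
    list(roughness = 0.12, contrast = 14, corr_len = 2.8, radius = 11)
  }
}

#' @noRd
validate_phantom_spec <- function(spec) {
  if (spec$width < 64L || spec$height < 64L)
    stopf("phantom must be at least 64x64 pixels")
  if (spec$boundary_roughness < 0 || spec$boundary_roughness > 1)
    stopf("boundary_roughness must lie in [0, 1]")
  # rim factor is bounded by 1 + 0.5 * roughness (L1-normalised modes)
  rmax <- spec$hotspot_radius * (1 + 0.5 * spec$boundary_roughness)
  ctr <- spec$hotspot_center
  if (ctr[1] - rmax < 1 || ctr[1] + rmax > spec$height ||
      ctr[2] - rmax < 1 || ctr[2] + rmax > spec$width)
    stopf("hotspot (centre %d,%d radius %.1f) does not fit inside the image",
          ctr[1], ctr[2], rmax)
  invisible(spec)
}

#' Generate a synthetic breast thermogram
#'
#' Renders the phantom described by a [phantom_spec()]: cold background
#' (gray level ~40), warm torso ellipse (~120), two breast mounds (~140) and
#' an elliptical hot spot (~190) whose rim is a circle perturbed by seeded
#' low-order Fourier modes and whose interior carries a seeded Gaussian
#' random field. Output is an 8-bit [thermal_image()] by default; the planted
#' hot-spot mask is attached as `$truth` for segmentation scoring.
#'
#' @param spec a `phantom_spec`.
#' @param bit_depth 8 or 16.
#' @return a `thermal_image` with extra fields `truth` (logical matrix of the
#'   planted hot spot) and `label`.
#' @examples
#' img <- generate_phantom(phantom_spec("malignant", seed = 3))
#' mean(img$pixels[img$truth]) > mean(img$pixels[!img$truth])
#' @export
generate_phantom <- function(spec, bit_depth = 8L) {
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  maxval <- if (bit_depth == 16L) 65535 else 255
  scale <- maxval / 255
  with_seed(spec$seed, {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    img <- matrix(40, h, w)

    # torso: vertical ellipse filling most of the frame
    torso <- ((rr - h * 0.52) / (h * 0.46))^2 +
             ((cc - w * 0.5) / (w * 0.42))^2 <= 1
    img[torso] <- 120

    # two breast mounds in the lower half with a marked radial temperature
    # gradient (warm centre, cooler periphery)
    for (bc in c(0.32, 0.68)) {
      d2 <- ((rr - h * 0.62) / (h * 0.20))^2 + ((cc - w * bc) / (w * 0.16))^2
      mound <- torso & d2 <= 1
      img[mound] <- 120 + 35 * (1 - d2[mound])
    }

    # hot spot: circle with seeded Fourier rim perturbation
    ctr <- spec$hotspot_center
    theta <- atan2(rr - ctr[1], cc - ctr[2])
    modes <- 2:6
    amp <- rnorm(length(modes))
    phs <- runif(length(modes), 0, 2 * pi)
    amp <- amp / max(sum(abs(amp)), 1e-12)  # L1-normalised: |pert| <= 1
    pert <- matrix(0, h, w)
    for (i in seq_along(modes))
      pert <- pert + amp[i] * cos(modes[i] * theta + phs[i])
    radius <- spec$hotspot_radius *
      (1 + spec$boundary_roughness * 0.5 * pert)
    dist <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    hot <- dist <= radius

    # interior texture: correlated Gaussian random field, clipped at +/- 2 sd
    # (tissue temperature fluctuations are bounded; unbounded tails would
    # push hot-spot pixels below breast-mound level and break the hot-region
    # topology)
    field <- pmin(pmax(gaussian_random_field(h, w, spec$texture_corr_len),
                       -2), 2)
    img[hot] <- 200 + spec$texture_contrast * field[hot]

    if (spec$noise_sd > 0) img <- img + rnorm(h * w, sd = spec$noise_sd)
    img <- round(pmin(pmax(img, 0), 255) * scale)

    out <- thermal_image(img, bit_depth = bit_depth,
                         id = sprintf("phantom_%s_seed%d", spec$label,
                                      spec$seed))
    out$truth <- hot
    out$label <- spec$label
    out
  })
}

# White noise smoothed by a separable Gaussian kernel and re-standardised to
# unit variance; corr_len <= ~0.3 px degenerates gracefully to white noise.
#' @noRd
gaussian_random_field <- function(h, w, corr_len) {
  z <- matrix(rnorm(h * w), h, w)
  if (corr_len < 0.3) return(z)
  half <- max(1L, ceiling(2 * corr_len))
  x <- (-half):half
  k <- exp(-x^2 / (2 * corr_len^2))
  k <- k / sum(k)
  sm <- apply(z, 2, function(col) as.numeric(stats::filter(col, k, sides = 2,
                                                           circular = TRUE)))
  sm <- t(apply(sm, 1, function(row) as.numeric(stats::filter(row, k,
                                                sides = 2, circular = TRUE))))
  sm / stats::sd(sm)
}

#' Draw per-image phantom specs for a class
#'
#' Samples the class-dependent knobs around the class defaults so that the
#' two classes overlap (no single feature separates them perfectly).
#' Malignant specs carry a latent phenotype `u` in `[0, 1]` that trades the
#' two malignancy markers against each other: `u` near 0 gives a
#' texture-dominant lesion (short correlation length, relatively smooth
#' margin), `u` near 1 a margin-dominant one (rough boundary, benign-like
#' internal texture). Real tumours present heterogeneously in exactly this
#' sense, and it is what makes combining texture with shape/complexity
#' features genuinely informative: either feature family alone misses one
#' phenotype.
#'
#' @param n number of specs.
#' @param label class label.
#' @param seed integer seed.
#' @param width,height image size.
#' @return list of `phantom_spec`.
#' @export
sample_phantom_specs <- function(n, label = c("benign", "malignant"),
                                 seed = 1L, width = 64L, height = 64L) {
  label <- match.arg(label)
  def <- phantom_class_defaults(label)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (label == "malignant") {
        u <- stats::runif(1)
        rough <- 0.30 + 0.45 * u + rnorm(1, 0, 0.06)
        clen <- 0.8 + 1.2 * u + rnorm(1, 0, 0.2)
      } else {
        rough <- rnorm(1, def$roughness, 0.08)
        clen <- rnorm(1, def$corr_len, 0.45)
      }
      rough <- min(max(rough, 0.02), 0.8)
      clen <- min(max(clen, 0.7), 4)
      contr <- min(max(rnorm(1, def$contrast, 3), 6), 22)
      rad <- min(max(rnorm(1, def$radius, 1.3), 8), 12.5)
      ctr <- c(round(0.62 * height) + sample(-3:3, 1),
               round(0.32 * width) + sample(0:4, 1))
      phantom_spec(label, width = width, height = height,
                   hotspot_center = ctr, hotspot_radius = rad,
                   boundary_roughness = rough, texture_contrast = contr,
                   texture_corr_len = clen, noise_sd = 3,
                   seed = sample.int(.Machine$integer.max, 1))
    })
  })
}
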