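test_that("image_to_series respects scan order and determinism", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)    # column-major storage
  expect_identical(image_to_series(img, order = "row_major"), c(1, 2, 3, 4))
  expect_identical(image_to_series(img, order = "column_major"), c(1, 3, 2, 4))
  expect_identical(image_to_series(t(img), order = "column_major"),
                   image_to_series(img, order = "row_major"))
  expect_identical(image_to_series(img, order = "row_major"),
                   image_to_series(img, order = "row_major"))
  expect_error(image_to_series(img, matrix(FALSE, 2, 2)), "empty")
})

test_that("hilbert order visits every roi pixel exactly once", {
  set.seed(2)
  roi <- matrix(runif(400) < 0.6, 20, 20)
  img <- matrix(seq_len(400), 20, 20)
  s <- image_to_series(img, roi, order = "hilbert")
  expect_identical(sort(s), sort(img[roi]))
})

test_that("box-counting dimension recovers analytic dimensions", {
  line <- generate_series("line", list(size = 128))$image
  expect_lt(abs(box_counting_fd(line) - 1), 0.1)
  sq <- generate_series("filled_square", list(size = 128))$image
  expect_lt(abs(box_counting_fd(sq) - 2), 0.1)
  si <- generate_series("sierpinski", list(depth = 7))$image
  expect_lt(abs(box_counting_fd(si) - log(3) / log(2)), 0.07)
})

test_that("box counting rejects degenerate inputs", {
  expect_error(box_counting_fd(matrix(0, 16, 16)), "empty")
  m <- matrix(0L, 64, 64); m[30, 30] <- 1L
  expect_error(box_counting_fd(m), "scale range")
  expect_error(box_counting_fd(matrix(1, 8, 8), box_sizes = c(2, 4)),
               "3 box sizes")
})

test_that("box-counting dimension is invariant to translation and rotation", {
  si <- generate_series("sierpinski", list(depth = 6))$image
  base <- box_counting_fd(si)
  shifted <- matrix(0L, 100, 100)
  shifted[20:(19 + 64), 30:(29 + 64)] <- si
  expect_lt(abs(box_counting_fd(shifted) - base), 0.02)
  expect_lt(abs(box_counting_fd(t(si[nrow(si):1, ])) - base), 0.02)
})

test_that("sample-entropy form of KS entropy matches brute-force enumeration", {
  set.seed(3)
  for (i in 1:3) {
    s <- rnorm(50)
    r <- 0.25 * sd(s)
    expect_equal(ks_entropy(s, m = 2, r = r), sampen_brute(s, 2, r),
                 tolerance = 1e-12)
  }
})

test_that("KS entropy limits and ordering by regularity", {
  expect_identical(ks_entropy(rep(4, 200)), 0)
  set.seed(5)
  wins <- 0
  for (i in 1:20) {
    noise <- rnorm(500)
    sine <- sin(2 * pi * 0.031 * seq_len(500) + runif(1, 0, 2 * pi))
    wins <- wins + (ks_entropy(noise) > ks_entropy(sine))
  }
  expect_identical(wins, 20)
  expect_error(ks_entropy(rnorm(8)), "too short")
})

test_that("KS entropy is invariant under affine rescaling with sd-scaled r", {
  set.seed(6)
  s <- rnorm(300)
  expect_equal(ks_entropy(s), ks_entropy(5 * s + 3), tolerance = 1e-12)
})

test_that("correlation sum matches the brute-force pair count exactly", {
  set.seed(7)
  pts <- cbind(runif(300), runif(300))
  radii <- quantile(dist(pts), c(0.02, 0.05, 0.1, 0.2, 0.5))
  cd <- correlation_dimension(pts, radii = radii)
  expect_equal(unname(attr(cd, "corr_sum")),
               unname(corr_sum_brute(pts, radii)), tolerance = 1e-15)
  # C(r) non-decreasing; C(max distance) = 1
  cs <- attr(correlation_dimension(
    pts, radii = c(radii, max(dist(pts)))), "corr_sum")
  expect_true(all(diff(cs) >= 0))
  expect_equal(unname(cs[length(cs)]), 1)
})

test_that("correlation dimension recovers line and square dimensions", {
  set.seed(8)
  u <- sort(runif(600))
  line_pts <- cbind(u, u)
  expect_lt(abs(correlation_dimension(line_pts) - 1), 0.1)
  sq_pts <- cbind(runif(600), runif(600))
  expect_lt(abs(correlation_dimension(sq_pts) - 2), 0.15)
  expect_error(correlation_dimension(cbind(runif(50), runif(50))), "200")
})

test_that("lyapunov exponent flags degenerate and regular series", {
  expect_warning(l <- lle_jacobian(rep(1, 600)), "degenerate")
  expect_lte(as.numeric(l), 0)
  sine <- sin(2 * pi * 0.029 * seq_len(2000))
  expect_lt(abs(as.numeric(lle_jacobian(sine))), 0.05)
})

test_that("chaotic feature vector is finite and named on a phantom roi", {
  co <- tiny_cohort(1, seed = 31)
  img <- co$images[[1]]
  seg <- segment_thermogram(img)
  f <- chaotic_features(img, seg$roi_mask)
  expect_named(f, c("fd", "lle", "kse", "cd"))
  expect_true(all(is.finite(f)))
  expect_true(f[["fd"]] >= 0 && f[["fd"]] <= 2)
  expect_true(f[["kse"]] >= 0)
})
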