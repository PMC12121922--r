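test_that("otsu separates a two-level image exactly", {
  m <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
  t <- otsu_threshold(m)
  expect_true(t >= 10 && t < 200)
  expect_identical(otsu_mask(m), m > t)
  expect_identical(sum(otsu_mask(m)), 8L)
})

test_that("otsu equals the exhaustive between-class-variance argmax", {
  set.seed(42)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 400, replace = TRUE,
                         prob = runif(256)^2), 20, 20)
    expect_identical(as.integer(otsu_threshold(img)), otsu_brute(img))
  }
})

test_that("otsu rejects a constant image", {
  expect_error(otsu_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("otsu commutes with affine intensity rescaling", {
  set.seed(1)
  img <- matrix(runif(900), 30, 30)
  t0 <- otsu_threshold(img)
  t1 <- otsu_threshold(img * 5 + 2)
  expect_equal((t1 - 2) / 5, t0, tolerance = 0.02)
})

test_that("pseudo-coloring maps hotter pixels closer to red", {
  img <- matrix(c(10, 50, 120, 200), 2, 2)
  pc <- pseudo_color_hsi(img)
  ord <- order(img)
  expect_true(all(diff(pc$h[ord]) < 0))   # hue decreases toward red (0)
  # intensity channel is the min-max normalisation of the input
  expect_equal(pc$i, (img - 10) / 190)
  expect_true(all(pc$s == 1))
})

test_that("pseudo-coloring is a pure per-pixel function", {
  set.seed(3)
  img <- matrix(runif(64, 0, 255), 8, 8)
  perm <- sample(64)
  pc <- pseudo_color_hsi(img)
  img_p <- matrix(img[perm], 8, 8)
  pc_p <- pseudo_color_hsi(img_p)
  expect_equal(as.numeric(pc_p$h), as.numeric(pc$h)[perm])
  expect_equal(as.numeric(pc_p$i), as.numeric(pc$i)[perm])
})

test_that("background gets the reserved hue; constant foreground constant hue", {
  img <- matrix(100, 4, 4)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 4)
  pc <- pseudo_color_hsi(img, mask)
  expect_true(length(unique(pc$h[mask])) == 1L)
  expect_true(all(pc$h[!mask] == 270 / 360))
  expect_true(all(pc$s[!mask] == 0))
  expect_error(pseudo_color_hsi(img, matrix(TRUE, 2, 2)), "shape")
})

test_that("image IO round-trips PNG and CSV matrices", {
  img <- generate_phantom(phantom_spec("benign", seed = 8))
  p1 <- withr::local_tempfile(fileext = ".png")
  write_thermal_image(img, p1)
  back <- read_thermal_image(p1)
  expect_equal(back$pixels, img$pixels)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write.table(img$pixels, p2, sep = ",", row.names = FALSE, col.names = FALSE)
  back2 <- read_thermal_image(p2)
  expect_equal(back2$pixels, img$pixels, ignore_attr = TRUE)
  expect_error(read_thermal_image("no_such_file.png"), "not found")
})
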