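test_that("phantom generation is bitwise deterministic for a fixed seed", {
  spec <- phantom_spec("malignant", seed = 17)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth, b$truth)

  s1 <- generate_series("logistic", list(r = 4), n = 600, seed = 5)
  s2 <- generate_series("logistic", list(r = 4), n = 600, seed = 5)
  expect_identical(s1$values, s2$values)
})

test_that("hotspot is hotter than background for both class defaults", {
  for (lab in c("benign", "malignant")) {
    img <- generate_phantom(phantom_spec(lab, seed = 3))
    expect_gt(mean(img$pixels[img$truth]), mean(img$pixels[!img$truth]))
  }
})

test_that("malignant defaults are strictly rougher and higher-contrast", {
  b <- phantom_spec("benign")
  m <- phantom_spec("malignant")
  expect_gt(m$boundary_roughness, b$boundary_roughness)
  expect_gt(m$texture_contrast, b$texture_contrast)
})

test_that("a hotspot that cannot fit in the image is rejected", {
  expect_error(phantom_spec("benign", hotspot_center = c(5, 5),
                            hotspot_radius = 12),
               "does not fit")
  expect_error(phantom_spec("benign", width = 32, height = 32),
               "at least 64x64")
})

test_that("reference series have their defining properties", {
  cs <- generate_series("const", list(value = 2.5), n = 1000, seed = 1)
  expect_true(all(cs$values == 2.5))

  lg <- generate_series("logistic", list(r = 4), n = 1000, seed = 2)
  expect_true(all(lg$values >= 0 & lg$values <= 1))

  expect_error(generate_series("lorenz", n = 1000, seed = 1))
  expect_error(generate_series("logistic", n = 100, seed = 1), ">= 500")
})

test_that("sierpinski render has exactly 3^depth occupied cells", {
  for (d in c(4, 7)) {
    img <- generate_series("sierpinski", list(depth = d))$image
    expect_identical(sum(img), as.integer(3^d))
    expect_identical(dim(img), as.integer(c(2^d, 2^d)))
  }
})

test_that("class-conditional directions hold on extracted features", {
  # >= 50 phantoms per class; configured directions (fd, entropy, contrast)
  # must hold at p < 0.01 by rank test
  co <- phantom_cohort(50, seed = 21)
  ft <- feature_table(co$images)
  X <- as.matrix(ft[, setdiff(names(ft), "id")])
  y <- co$labels
  for (f in c("fd", "entropy", "contrast", "kse")) {
    p <- wilcox.test(X[y == "malignant", f], X[y == "benign", f],
                     alternative = "greater")$p.value
    expect_lt(p, 0.01)
  }
})
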