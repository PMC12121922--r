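test_that("glcm of the 2x2 two-row image puts half the mass on each diagonal cell", {
  img <- matrix(c(0, 1, 0, 1), 2, 2)   # rows (0,0) and (1,1)
  P <- compute_glcm(img, glcm_config(levels = 2), angle = 0)
  expect_equal(P[1, 1], 0.5)
  expect_equal(P[2, 2], 0.5)
  expect_equal(P[1, 2] + P[2, 1], 0)
})

test_that("glcm is normalized and symmetric", {
  set.seed(6)
  img <- matrix(sample(0:255, 300, TRUE), 15, 20)
  cfg <- glcm_config()
  for (a in cfg$angles) {
    P <- compute_glcm(img, cfg, a)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P))
  }
  # constant roi: a single nonzero entry equal to 1
  Pc <- compute_glcm(matrix(5, 4, 4), glcm_config(levels = 8), 0)
  expect_equal(max(Pc), 1)
  expect_equal(sum(Pc > 0), 1L)
})

test_that("offsets larger than the roi are rejected", {
  expect_error(compute_glcm(matrix(1:3, 3, 1), glcm_config(levels = 4),
                            angle = 0),
               "thinner")
})

test_that("constant-image descriptors sit at their analytic limits", {
  P <- compute_glcm(matrix(9, 6, 6), glcm_config(levels = 16), 0)
  f <- texture_descriptors(P)
  expect_identical(f[["energy"]], 1)
  expect_identical(f[["contrast"]], 0)
  expect_identical(f[["dissimilarity"]], 0)
  expect_identical(f[["homogeneity"]], 1)
  expect_identical(f[["entropy"]], 0)
  expect_identical(f[["maximum_probability"]], 1)
})

test_that("alternating horizontal stripes give correlation -1 and contrast 1", {
  img <- outer(1:4, 1:4, function(i, j) (j %% 2))  # horizontal neighbours differ

  P <- compute_glcm(img, glcm_config(levels = 2), angle = 0)
  f <- texture_descriptors(P)
  expect_equal(f[["correlation"]], -1)
  expect_equal(f[["contrast"]], 1)
})

test_that("descriptors match the direct-summation oracle", {
  set.seed(8)
  for (i in 1:20) {
    M <- matrix(rexp(256), 16, 16)
    M <- (M + t(M))          # symmetric like a symmetric glcm
    P <- M / sum(M)
    expect_equal(texture_descriptors(P), glcm_oracle(P), tolerance = 1e-10)
  }
})

test_that("descriptors are invariant to roi translation", {
  set.seed(10)
  patch <- matrix(sample(0:255, 64, TRUE), 8, 8)
  big1 <- matrix(NA_real_, 20, 20); big1[2:9, 2:9] <- patch
  big2 <- matrix(NA_real_, 20, 20); big2[10:17, 11:18] <- patch
  expect_equal(texture_features(big1), texture_features(big2))
})

test_that("angle-averaged symmetric descriptors survive 180-degree rotation", {
  set.seed(12)
  img <- matrix(sample(0:255, 100, TRUE), 10, 10)
  rot <- img[10:1, 10:1]
  expect_equal(texture_features(img), texture_features(rot), tolerance = 1e-12)
})

test_that("entropy zero exactly when energy one", {
  set.seed(13)
  for (i in 1:10) {
    M <- matrix(rexp(16), 4, 4); P <- (M + t(M)) / (2 * sum(M))
    f <- texture_descriptors(P)
    expect_identical(unname(f["entropy"] == 0), unname(f["energy"] == 1))
  }
})

test_that("dwt level 0 equals plain descriptors; reconstruction is exact", {
  set.seed(14)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_equal(dwt_texture(img, level = 0)$approx, texture_features(img))

  bands <- dwt2(img)
  expect_lt(max(abs(idwt2(bands) - img)), 1e-8)

  # constant image: approximation band constant, energy 1
  f <- dwt_texture(matrix(7, 16, 16), level = 1)$approx
  expect_equal(f[["energy"]], 1)
  expect_error(dwt_texture(matrix(1:4 + 0.5, 2, 2), level = 3), "2\\^level")
})
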