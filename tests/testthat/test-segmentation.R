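test_that("fcm recovers two well-separated 1-D blobs", {
  set.seed(4)
  x <- matrix(c(rnorm(100, 10, 1), rnorm(100, 200, 1)), ncol = 1)
  fit <- fcm_cluster(x, fcm_config(k = 2, seed = 2))
  centers <- sort(fit$centers[, 1])
  expect_lt(abs(centers[1] - 10), 2)
  expect_lt(abs(centers[2] - 200), 2)
  hard <- fit$cluster
  expect_true(all(hard[1:100] == hard[1]))
  expect_true(all(hard[101:200] == hard[101]))
  expect_false(hard[1] == hard[101])
})

test_that("fcm memberships are a proper fuzzy partition", {
  set.seed(9)
  x <- matrix(rnorm(300), 100, 3)
  fit <- fcm_cluster(x, fcm_config(k = 3, seed = 1))
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
})

test_that("fcm objective is monotone non-increasing across iterations", {
  set.seed(11)
  for (rep in 1:3) {
    x <- matrix(runif(400, 0, 255), 200, 2)
    fit <- fcm_cluster(x, fcm_config(k = 3, m = 2, seed = rep))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("degenerate clustering inputs are rejected", {
  expect_error(fcm_config(k = 1), "k must be")
  expect_error(fcm_config(m = 1), "m must be")
  expect_error(fcm_cluster(matrix(5, 50, 1), fcm_config(k = 2)),
               "distinct")
})

test_that("hottest cluster selection picks the highest-mean cluster", {
  img <- thermal_image(matrix(c(rep(180, 8), rep(90, 8)), 4, 4))
  res <- list(cluster_map = matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4))
  roi <- select_hot_cluster(res, img)
  expect_identical(roi, res$cluster_map == 1L)

  # tie in means: larger cluster wins, with a warning
  img2 <- thermal_image(matrix(100, 4, 4))
  res2 <- list(cluster_map = matrix(c(rep(1L, 4), rep(2L, 12)), 4, 4))
  expect_warning(roi2 <- select_hot_cluster(res2, img2), "tie")
  expect_identical(roi2, res2$cluster_map == 2L)
})

test_that("cluster relabelling does not change the roi", {
  img <- generate_phantom(phantom_spec("benign", seed = 5))
  seg <- segment_thermogram(img)
  relab <- seg
  cm <- seg$cluster_map
  k <- max(cm)
  perm <- c(seq_len(k)[-1], 1L)          # cyclic relabel
  cm2 <- cm
  cm2[cm > 0L] <- perm[cm[cm > 0L]]
  relab$cluster_map <- cm2
  expect_identical(merge_hot_clusters(relab, img),
                   merge_hot_clusters(seg, img))
})

test_that("exclusion bands behave as configured", {
  mask <- matrix(TRUE, 20, 20)
  # zero fractions: identity
  expect_identical(exclude_regions(mask, exclusion_config(0, 0, FALSE)), mask)
  # central band of 10% on a symmetric mask removes the central columns
  out <- exclude_regions(mask, exclusion_config(0, 0.1, FALSE))
  expect_true(all(!out[, 10:11]))
  expect_identical(out[, 1:9], mask[, 1:9])
  expect_identical(out[, 12:20], mask[, 12:20])
  # symmetric result
  expect_identical(out, out[, 20:1])
  # axilla: top 15% of rows removed
  out2 <- exclude_regions(mask, exclusion_config(0.15, 0, FALSE))
  expect_true(all(!out2[1:3, ]))
  # removing everything is an error: roi entirely inside the axilla band
  top_only <- matrix(FALSE, 20, 20); top_only[1:2, ] <- TRUE
  expect_error(exclude_regions(top_only, exclusion_config(0.15, 0, FALSE),
                               torso_mask = mask),
               "entire roi")
})

test_that("keep-largest drops small fragments on the same side", {
  mask <- matrix(FALSE, 20, 40)
  mask[5:14, 2:11] <- TRUE      # 100-px component, left side
  mask[17:18, 14:16] <- TRUE    # 6-px fragment, left side
  mask[5:14, 25:34] <- TRUE     # right-side component
  out <- exclude_regions(mask, exclusion_config(0, 0, TRUE))
  expect_true(all(out[5:14, 2:11]))
  expect_true(all(!out[17:18, 14:16]))
  expect_true(all(out[5:14, 25:34]))
})

test_that("binarize_roi is the roi indicator", {
  img <- matrix(runif(100), 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[3:6, 4:8] <- TRUE
  b <- binarize_roi(img, roi)
  expect_identical(sum(b), sum(roi))
  expect_true(all(b[roi] == 1L) && all(b[!roi] == 0L))
  expect_error(binarize_roi(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("segmentation recovers the planted hotspot", {
  co <- tiny_cohort(3, seed = 12)
  for (i in seq_along(co$images)) {
    seg <- segment_thermogram(co$images[[i]])
    expect_gte(dice_coef(seg$roi_mask, co$images[[i]]$truth), 0.7)
  }
})
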