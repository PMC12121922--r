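# shared planted dataset: n_inf informative columns shifted by effect size d
planted_table <- function(seed, n = 200, d = 2, n_inf = 3, n_noise = 17) {
  set.seed(seed)
  y <- factor(rep(c("benign", "malignant"), each = n / 2))
  X <- matrix(rnorm(n * (n_inf + n_noise)), n)
  for (j in seq_len(n_inf)) X[y == "malignant", j] <- X[y == "malignant", j] + d
  colnames(X) <- c(paste0("inf", seq_len(n_inf)),
                   if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  list(X = scale(X), y = y)
}

test_that("subset evaluation: separable data, arithmetic, empty repair", {
  sep <- planted_table(1, d = 8, n_noise = 0)    # cleanly separable table
  ev <- evaluate_subset(rep(1, 3), sep$X, sep$y, seed = 1)
  expect_identical(ev$error, 0)
  expect_identical(ev$nf_frac, 1)

  p <- planted_table(1, d = 2)
  ev8 <- evaluate_subset(c(rep(1, 8), rep(0, 12)), p$X, p$y, seed = 1)
  expect_identical(ev8$nf_frac, 0.4)

  expect_warning(evr <- evaluate_subset(rep(0, 20), p$X, p$y, seed = 1),
                 "repaired")
  expect_identical(sum(evr$bits), 1L)
  expect_true(which(evr$bits) %in% 1:3)   # an informative column
})

test_that("pure-noise subsets score at chance level", {
  errs <- sapply(1:5, function(sd) {
    p <- planted_table(sd)
    evaluate_subset(c(rep(0, 3), rep(1, 17)), p$X, p$y, seed = sd)$error
  })
  expect_lt(abs(mean(errs) - 0.5), 0.1)
})

test_that("non-dominated sorting matches the brute-force oracle", {
  set.seed(2)
  for (i in 1:20) {
    objs <- matrix(runif(2 * sample(5:40, 1)), ncol = 2)
    expect_identical(nondominated_sort(objs), domination_ranks_brute(objs))
  }
  # hand-constructed six-point configuration with known ranks
  objs <- rbind(c(0.1, 0.9), c(0.9, 0.1), c(0.5, 0.5),
                c(0.6, 0.6), c(0.2, 1.0), c(1.0, 1.0))
  expect_identical(nondominated_sort(objs), c(1L, 1L, 1L, 2L, 2L, 3L))
})

test_that("nsga3 is seed-reproducible and returns a mutually non-dominated front", {
  p <- planted_table(3)
  r1 <- nsga3_select(p$X, p$y, seed = 7)
  r2 <- nsga3_select(p$X, p$y, seed = 7)
  expect_identical(r1$chosen_subset, r2$chosen_subset)
  expect_identical(r1$history, r2$history)

  objs <- cbind(vapply(r1$pareto, `[[`, numeric(1), "error"),
                vapply(r1$pareto, `[[`, numeric(1), "nf_frac"))
  expect_true(all(nondominated_sort(objs) == 1L))
  expect_true(all(diff(r1$history) <= 1e-12))
})

test_that("selection input contracts are enforced", {
  p <- planted_table(4)
  expect_error(nsga3_select(p$X, p$y, pop_size = 3), "at least 4")
  y1 <- factor(rep("a", 200))
  expect_error(nsga3_select(p$X, y1), "2 classes")
})

test_that("single-objective baselines descend and beat the full genome", {
  p <- planted_table(5)
  full <- evaluate_subset(rep(1, 20), p$X, p$y, seed = 9)
  J_full <- full$error + 0.01 * full$nf_frac
  for (fn in list(ga_select, pso_select, de_select)) {
    r <- fn(p$X, p$y, seed = 9)
    expect_true(all(diff(r$history) <= 1e-12))
    expect_lte(r$best_scalar, J_full + 1e-12)
    r2 <- fn(p$X, p$y, seed = 9)
    expect_identical(r2$best_scalar, r$best_scalar)
  }
})

test_that("objective-vs-k curve flags a sensible elbow", {
  p <- planted_table(6)
  r <- nsga3_select(p$X, p$y, seed = 2)
  curve <- objective_vs_k_curve(r)
  expect_true(all(diff(curve$k) > 0))
  expect_identical(sum(curve$is_elbow), 1L)
  # single-point pareto: curve of length 1
  r1 <- r; r1$pareto <- r$pareto[1]
  expect_identical(nrow(objective_vs_k_curve(r1)), 1L)
})

test_that("adding pure-noise columns cannot improve the best achievable error", {
  p <- planted_table(8, n_noise = 17)
  r_with <- nsga3_select(p$X, p$y, seed = 4)
  r_without <- nsga3_select(p$X[, 1:3], p$y, seed = 4, pop_size = 8)
  best_with <- min(vapply(r_with$pareto, `[[`, numeric(1), "error"))
  best_without <- min(vapply(r_without$pareto, `[[`, numeric(1), "error"))
  expect_lte(best_without, best_with + 0.03)   # inner-CV noise allowance
})
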