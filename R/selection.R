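#' Wrapper fitness of a feature subset
#'
#' Scores a binary feature mask by the stratified inner cross-validated
#' misclassification rate of a 5-nearest-neighbour classifier on the
#' selected columns, together with the selected fraction of features. These
#' are the two objectives the multi-objective search trades off. An empty
#' mask is repaired to the single feature with the largest absolute
#' two-sample t statistic, with a warning.
#'
#' @param bits 0/1 or logical vector, one entry per column of `table`.
#' @param table standardized numeric feature matrix (samples x features).
#' @param labels factor of class labels.
#' @param inner_cv number of inner folds, default 5.
#' @param seed integer seed controlling the fold assignment.
#' @return list with `error`, `nf_frac`, `bits` (after repair).
#' @export
evaluate_subset <- function(bits, table, labels, inner_cv = 5L, seed = 1L) {
  bits <- as.logical(bits)
  if (!any(bits)) {
    warnf("empty feature subset repaired to the best univariate feature")
    bits[best_univariate(table, labels)] <- TRUE
  }
  err <- knn_cv_error(table[, bits, drop = FALSE], labels, inner_cv, seed)
  list(error = err, nf_frac = sum(bits) / length(bits), bits = bits)
}

#' @noRd
best_univariate <- function(table, labels) {
  cl <- levels(labels)
  tstat <- vapply(seq_len(ncol(table)), function(j) {
    a <- table[labels == cl[1], j]; b <- table[labels == cl[2], j]
    s <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (s == 0) 0 else abs(mean(a) - mean(b)) / s
  }, numeric(1))
  which.max(tstat)
}

# deterministic stratified k-fold KNN(5) error
#' @noRd
knn_cv_error <- function(X, y, k_folds, seed) {
  plan <- make_folds(y, k = k_folds, seed = seed, stratified = TRUE)
  wrong <- 0L
  for (f in seq_len(k_folds)) {
    te <- plan$assignments == f
    pred <- class::knn(X[!te, , drop = FALSE], X[te, , drop = FALSE],
                       y[!te], k = 5, use.all = TRUE)
    wrong <- wrong + sum(pred != y[te])
  }
  wrong / length(y)
}

#' Non-dominated sorting (minimisation)
#'
#' @param objs n x M matrix of objective values.
#' @return integer vector of front ranks (1 = non-dominated).
#' @export
nondominated_sort <- function(objs) {
  n <- nrow(objs)
  dominated_by <- lapply(seq_len(n), function(i) integer(0))
  ndom <- integer(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    le_ij <- all(objs[i, ] <= objs[j, ]); lt_ij <- any(objs[i, ] < objs[j, ])
    le_ji <- all(objs[j, ] <= objs[i, ]); lt_ji <- any(objs[j, ] < objs[i, ])
    if (le_ij && lt_ij) {
      dominated_by[[i]] <- c(dominated_by[[i]], j); ndom[j] <- ndom[j] + 1L
    } else if (le_ji && lt_ji) {
      dominated_by[[j]] <- c(dominated_by[[j]], i); ndom[i] <- ndom[i] + 1L
    }
  }
  rank <- integer(n)
  front <- which(ndom == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) for (j in dominated_by[[i]]) {
      ndom[j] <- ndom[j] - 1L
      if (ndom[j] == 0L) nxt <- c(nxt, j)
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}

# Das-Dennis reference points on the 2-objective simplex; p divisions give
# p + 1 points
#' @noRd
das_dennis_2d <- function(p) cbind(0:p / p, p:0 / p)

# NSGA-III environmental selection: fill by fronts, resolve the split front
# by reference-point niching on normalized objectives
#' @noRd
niche_select <- function(objs, rank, n_keep, refs) {
  ord_fronts <- sort(unique(rank))
  chosen <- integer(0)
  for (fr in ord_fronts) {
    members <- which(rank == fr)
    if (length(chosen) + length(members) <= n_keep) {
      chosen <- c(chosen, members)
      if (length(chosen) == n_keep) return(chosen)
    } else {
      pool <- c(chosen, members)
      ideal <- apply(objs[pool, , drop = FALSE], 2, min)
      span <- apply(objs[pool, , drop = FALSE], 2, max) - ideal
      span[span == 0] <- 1
      norm <- sweep(sweep(objs, 2, ideal), 2, span, "/")
      # perpendicular distance of each point to each reference ray
      assoc <- function(i) {
        v <- norm[i, ]
        d <- vapply(seq_len(nrow(refs)), function(r) {
          u <- refs[r, ] / sqrt(sum(refs[r, ]^2))
          proj <- sum(v * u)
          sqrt(max(sum(v^2) - proj^2, 0))
        }, numeric(1))
        c(which.min(d), min(d))
      }
      amap <- t(vapply(pool, assoc, numeric(2)))
      niche_count <- tabulate(amap[seq_along(chosen), 1],
                              nbins = nrow(refs))
      cand <- data.frame(idx = members,
                         ref = amap[length(chosen) + seq_along(members), 1],
                         dist = amap[length(chosen) + seq_along(members), 2])
      while (length(chosen) < n_keep && nrow(cand)) {
        avail <- unique(cand$ref)
        jmin <- avail[which.min(niche_count[avail])]
        sub <- cand[cand$ref == jmin, ]
        pick <- sub$idx[which.min(sub$dist)]
        chosen <- c(chosen, pick)
        niche_count[jmin] <- niche_count[jmin] + 1L
        cand <- cand[cand$idx != pick, ]
      }
      return(chosen)
    }
  }
  chosen
}

# shared bookkeeping: memoised subset evaluation keyed on the bitstring
#' @noRd
make_evaluator <- function(table, labels, inner_cv, seed) {
  cache <- new.env(parent = emptyenv())
  fallback <- best_univariate(table, labels)
  function(bits) {
    bits <- as.logical(bits)
    if (!any(bits)) bits[fallback] <- TRUE   # silent repair inside the search
    key <- paste(as.integer(bits), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    err <- knn_cv_error(table[, bits, drop = FALSE], labels, inner_cv, seed)
    res <- list(error = err, nf_frac = mean(bits), bits = bits)
    cache[[key]] <- res
    res
  }
}

#' @noRd
scalar_objective <- function(error, nf_frac, w = 0.01) error + w * nf_frac

#' NSGA-III feature selection
#'
#' Multi-objective wrapper selection minimising the inner-CV classification
#' error and the selected-feature fraction simultaneously. Offspring are
#' produced by random parent selection, uniform crossover on the bit masks
#' and per-bit flip mutation; survivors are chosen by non-dominated sorting
#' followed by reference-point niching (Das-Dennis points, two objectives),
#' the niching step that distinguishes NSGA-III from NSGA-II. Defaults:
#' population 30, 20 generations, crossover fraction 0.7, mutation
#' fraction 0.4 with per-bit rate 0.1.
#'
#' @param table standardized feature matrix.
#' @param labels factor of class labels (2 classes, >= 10 samples each).
#' @param pop_size population size.
#' @param max_iter generations.
#' @param p_crossover fraction of the population produced by crossover.
#' @param p_mutation fraction produced by mutation.
#' @param mutation_rate per-bit flip probability.
#' @param inner_cv inner folds for the fitness.
#' @param scalar_weight weight of the feature fraction in the scalar
#'   objective used for reporting the single best subset.
#' @param seed integer seed; runs are bit-reproducible.
#' @return a `selection_result`: `pareto` (list of `bits`, `error`,
#'   `nf_frac`), `best_scalar`, `chosen_subset` (column indices), `history`
#'   (best scalar per generation, non-increasing), `method`, `runtime`.
#' @export
nsga3_select <- function(table, labels, pop_size = 30L, max_iter = 20L,
                         p_crossover = 0.7, p_mutation = 0.4,
                         mutation_rate = 0.1, inner_cv = 5L,
                         scalar_weight = 0.01, seed = 1L) {
  check_selection_input(table, labels, pop_size)
  t0 <- proc.time()[3]
  d <- ncol(table)
  evalf <- make_evaluator(table, labels, inner_cv, seed)
  refs <- das_dennis_2d(pop_size - 1L)
  out <- with_seed(seed, {
    pop <- lapply(seq_len(pop_size), function(i) stats::runif(d) < 0.5)
    evals <- lapply(pop, evalf)
    pop <- lapply(evals, `[[`, "bits")
    history <- numeric(0)
    best <- NULL
    n_cross <- 2L * round(p_crossover * pop_size / 2)
    n_mut <- round(p_mutation * pop_size)
    for (gen in seq_len(max_iter)) {
      offspring <- list()
      if (n_cross > 0) for (i in seq_len(n_cross / 2)) {
        par <- sample.int(pop_size, 2L)
        mask <- stats::runif(d) < 0.5
        c1 <- ifelse(mask, pop[[par[1]]], pop[[par[2]]])
        c2 <- ifelse(mask, pop[[par[2]]], pop[[par[1]]])
        offspring <- c(offspring, list(c1, c2))
      }
      if (n_mut > 0) for (i in seq_len(n_mut)) {
        g <- pop[[sample.int(pop_size, 1L)]]
        flip <- stats::runif(d) < mutation_rate
        offspring <- c(offspring, list(xor(g, flip)))
      }
      oeval <- lapply(offspring, evalf)
      offspring <- lapply(oeval, `[[`, "bits")
      allpop <- c(pop, offspring)
      alleval <- c(evals, oeval)
      objs <- cbind(vapply(alleval, `[[`, numeric(1), "error"),
                    vapply(alleval, `[[`, numeric(1), "nf_frac"))
      rank <- nondominated_sort(objs)
      keep <- niche_select(objs, rank, pop_size, refs)
      pop <- allpop[keep]
      evals <- alleval[keep]
      scal <- vapply(alleval, function(e)
        scalar_objective(e$error, e$nf_frac, scalar_weight), numeric(1))
      gen_best <- alleval[[which.min(scal)]]
      if (is.null(best) ||
          scalar_objective(gen_best$error, gen_best$nf_frac, scalar_weight) <
            scalar_objective(best$error, best$nf_frac, scalar_weight))
        best <- gen_best
      history <- c(history,
                   scalar_objective(best$error, best$nf_frac, scalar_weight))
    }
    objs <- cbind(vapply(evals, `[[`, numeric(1), "error"),
                  vapply(evals, `[[`, numeric(1), "nf_frac"))
    rank <- nondominated_sort(objs)
    pareto <- unique(evals[rank == 1L])
    list(pareto = pareto, best = best, history = history)
  })
  selection_result("nsga3", out$pareto, out$best, out$history,
                   scalar_weight, colnames(table),
                   runtime = proc.time()[3] - t0)
}

#' @noRd
check_selection_input <- function(table, labels, pop_size) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stopf("need at least 2 classes")
  if (min(table(labels)) < 10L) stopf("need at least 10 samples per class")
  if (pop_size < 4L) stopf("population must have at least 4 members")
  invisible(NULL)
}

#' @noRd
selection_result <- function(method, pareto, best, history, scalar_weight,
                             feature_names, runtime) {
  structure(list(
    method = method,
    pareto = lapply(pareto, function(p)
      list(bits = p$bits, error = p$error, nf_frac = p$nf_frac)),
    best_scalar = scalar_objective(best$error, best$nf_frac, scalar_weight),
    best_error = best$error,
    chosen_subset = which(best$bits),
    chosen_names = if (!is.null(feature_names)) feature_names[best$bits],
    history = history, scalar_weight = scalar_weight,
    runtime = unname(runtime)), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<%s selection: best objective %.4f, %d features [%s], %.1fs>\n",
              x$method, x$best_scalar, length(x$chosen_subset),
              paste(x$chosen_names %||% x$chosen_subset, collapse = ", "),
              x$runtime))
  invisible(x)
}

#' Genetic-algorithm feature selection (single objective)
#'
#' Minimises `error + w * nf_frac` with roulette selection under exponential
#' selection pressure, uniform crossover and per-bit mutation, with elitism.
#' Defaults: population 30, 20 generations, crossover fraction 0.8,
#' mutation fraction 0.3, per-bit rate 0.02, selection pressure 8.
#'
#' @inheritParams nsga3_select
#' @param p_mutation fraction of the population turned into mutants.
#' @param mutation_rate per-bit flip probability of a mutant.
#' @param pressure selection pressure of the roulette weights.
#' @return a `selection_result`.
#' @export
ga_select <- function(table, labels, pop_size = 30L, max_iter = 20L,
                      p_crossover = 0.8, p_mutation = 0.3,
                      mutation_rate = 0.02, pressure = 8,
                      inner_cv = 5L, scalar_weight = 0.01, seed = 1L) {
  check_selection_input(table, labels, pop_size)
  t0 <- proc.time()[3]
  d <- ncol(table)
  evalf <- make_evaluator(table, labels, inner_cv, seed)
  J <- function(e) scalar_objective(e$error, e$nf_frac, scalar_weight)
  out <- with_seed(seed, {
    pop <- lapply(seq_len(pop_size), function(i) stats::runif(d) < 0.5)
    evals <- lapply(pop, evalf)
    pop <- lapply(evals, `[[`, "bits")
    cost <- vapply(evals, J, numeric(1))
    history <- numeric(0)
    n_cross <- 2L * round(p_crossover * pop_size / 2)
    n_mut <- round(p_mutation * pop_size)
    for (gen in seq_len(max_iter)) {
      wts <- exp(-pressure * cost / max(max(cost), 1e-12))
      offspring <- list()
      if (n_cross > 0) for (i in seq_len(n_cross / 2)) {
        par <- sample.int(pop_size, 2L, prob = wts)
        mask <- stats::runif(d) < 0.5
        offspring <- c(offspring, list(
          ifelse(mask, pop[[par[1]]], pop[[par[2]]]),
          ifelse(mask, pop[[par[2]]], pop[[par[1]]])))
      }
      if (n_mut > 0) for (i in seq_len(n_mut)) {
        g <- pop[[sample.int(pop_size, 1L)]]
        offspring <- c(offspring, list(xor(g, stats::runif(d) < mutation_rate)))
      }
      oeval <- lapply(offspring, evalf)
      allpop <- c(pop, lapply(oeval, `[[`, "bits"))
      alleval <- c(evals, oeval)
      allcost <- c(cost, vapply(oeval, J, numeric(1)))
      keep <- order(allcost)[seq_len(pop_size)]       # elitist truncation
      pop <- allpop[keep]; evals <- alleval[keep]; cost <- allcost[keep]
      history <- c(history, cost[1])
    }
    list(best = evals[[1]], history = history,
         pareto = pareto_of(evals))
  })
  selection_result("ga", out$pareto, out$best, out$history, scalar_weight,
                   colnames(table), proc.time()[3] - t0)
}

# non-dominated members of a list of evaluations
#' @noRd
pareto_of <- function(evals) {
  objs <- cbind(vapply(evals, `[[`, numeric(1), "error"),
                vapply(evals, `[[`, numeric(1), "nf_frac"))
  unique(evals[nondominated_sort(objs) == 1L])
}

#' Particle-swarm feature selection (single objective)
#'
#' Continuous positions in `[0, 1]^d` thresholded at 0.5 encode the subset.
#' Defaults: swarm 20, 20 iterations, inertia 1 damped by 0.99 per
#' iteration, personal and global learning coefficients 2.
#'
#' @inheritParams nsga3_select
#' @param inertia initial inertia weight.
#' @param damping inertia damping ratio per iteration.
#' @param c1,c2 personal and global learning coefficients.
#' @return a `selection_result`.
#' @export
pso_select <- function(table, labels, pop_size = 20L, max_iter = 20L,
                       inertia = 1, damping = 0.99, c1 = 2, c2 = 2,
                       inner_cv = 5L, scalar_weight = 0.01, seed = 1L) {
  check_selection_input(table, labels, pop_size)
  t0 <- proc.time()[3]
  d <- ncol(table)
  evalf <- make_evaluator(table, labels, inner_cv, seed)
  J <- function(e) scalar_objective(e$error, e$nf_frac, scalar_weight)
  out <- with_seed(seed, {
    pos <- matrix(stats::runif(pop_size * d), pop_size, d)
    vel <- matrix(0, pop_size, d)
    vmax <- 0.2
    evals <- apply(pos, 1, function(p) evalf(p > 0.5), simplify = FALSE)
    cost <- vapply(evals, J, numeric(1))
    pbest_pos <- pos; pbest_cost <- cost; pbest_eval <- evals
    g <- which.min(cost)
    gbest_pos <- pos[g, ]; gbest_eval <- evals[[g]]; gbest_cost <- cost[g]
    history <- numeric(0)
    w <- inertia
    all_evals <- evals
    for (it in seq_len(max_iter)) {
      r1 <- matrix(stats::runif(pop_size * d), pop_size, d)
      r2 <- matrix(stats::runif(pop_size * d), pop_size, d)
      vel <- w * vel + c1 * r1 * (pbest_pos - pos) +
        c2 * r2 * (matrix(gbest_pos, pop_size, d, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, -vmax), vmax)
      pos <- pmin(pmax(pos + vel, 0), 1)
      evals <- apply(pos, 1, function(p) evalf(p > 0.5), simplify = FALSE)
      cost <- vapply(evals, J, numeric(1))
      improve <- cost < pbest_cost
      pbest_pos[improve, ] <- pos[improve, ]
      pbest_cost[improve] <- cost[improve]
      pbest_eval[improve] <- evals[improve]
      if (min(cost) < gbest_cost) {
        g <- which.min(cost)
        gbest_pos <- pos[g, ]; gbest_eval <- evals[[g]]; gbest_cost <- cost[g]
      }
      all_evals <- c(all_evals, evals)
      history <- c(history, gbest_cost)
      w <- w * damping
    }
    list(best = gbest_eval, history = history, pareto = pareto_of(all_evals))
  })
  selection_result("pso", out$pareto, out$best, out$history, scalar_weight,
                   colnames(table), proc.time()[3] - t0)
}

#' Differential-evolution feature selection (single objective)
#'
#' rand/1/bin scheme on a continuous genome decoded through a sigmoid
#' threshold (bit j selected iff `1/(1+exp(-x_j)) > 0.5`). Defaults:
#' population 20, 20 iterations, scaling factor drawn uniformly in
#' `[0.2, 0.8]` per mutation, crossover probability 0.2.
#'
#' @inheritParams nsga3_select
#' @param beta_min,beta_max bounds of the mutation scaling factor.
#' @param p_cr crossover probability.
#' @return a `selection_result`.
#' @export
de_select <- function(table, labels, pop_size = 20L, max_iter = 20L,
                      beta_min = 0.2, beta_max = 0.8, p_cr = 0.2,
                      inner_cv = 5L, scalar_weight = 0.01, seed = 1L) {
  check_selection_input(table, labels, pop_size)
  t0 <- proc.time()[3]
  d <- ncol(table)
  evalf <- make_evaluator(table, labels, inner_cv, seed)
  J <- function(e) scalar_objective(e$error, e$nf_frac, scalar_weight)
  decode <- function(x) 1 / (1 + exp(-x)) > 0.5
  out <- with_seed(seed, {
    pos <- matrix(stats::rnorm(pop_size * d), pop_size, d)
    evals <- apply(pos, 1, function(p) evalf(decode(p)), simplify = FALSE)
    cost <- vapply(evals, J, numeric(1))
    history <- numeric(0)
    all_evals <- evals
    for (it in seq_len(max_iter)) {
      for (i in seq_len(pop_size)) {
        r <- sample(setdiff(seq_len(pop_size), i), 3L)
        beta <- stats::runif(d, beta_min, beta_max)
        v <- pos[r[1], ] + beta * (pos[r[2], ] - pos[r[3], ])
        jrand <- sample.int(d, 1L)
        cross <- stats::runif(d) < p_cr
        cross[jrand] <- TRUE
        u <- ifelse(cross, v, pos[i, ])
        ue <- evalf(decode(u))
        if (J(ue) < cost[i]) {
          pos[i, ] <- u; evals[[i]] <- ue; cost[i] <- J(ue)
        }
        all_evals <- c(all_evals, list(ue))
      }
      history <- c(history, min(cost))
    }
    list(best = evals[[which.min(cost)]], history = history,
         pareto = pareto_of(all_evals))
  })
  selection_result("de", out$pareto, out$best, out$history, scalar_weight,
                   colnames(table), proc.time()[3] - t0)
}

#' Best objective per subset size and the elbow of the trade-off curve
#'
#' Summarises a Pareto set as the minimum classification error achieved at
#' each subset size, and flags the elbow: the smallest size whose error is
#' within `eps` of the overall minimum, the point past which adding
#' features no longer buys a meaningful error reduction.
#'
#' @param result a `selection_result`.
#' @param eps tolerated error excess over the curve minimum, default 0.02.
#' @return data.frame with columns `k`, `error`, `is_elbow`.
#' @export
objective_vs_k_curve <- function(result, eps = 0.02) {
  if (length(result$pareto) == 0) stopf("empty Pareto set")
  k <- vapply(result$pareto, function(p) sum(p$bits), numeric(1))
  err <- vapply(result$pareto, `[[`, numeric(1), "error")
  agg <- stats::aggregate(err, list(k = k), min)
  agg <- agg[order(agg$k), ]
  elbow <- agg$k[which(agg$x <= min(agg$x) + eps)[1]]
  data.frame(k = agg$k, error = agg$x, is_elbow = agg$k == elbow)
}
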