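# Independent brute-force oracles. Each one is deliberately written as the
# plainest possible direct computation (explicit loops, no shared code with
# the package implementation).

# exhaustive Otsu: scan every 8-bit threshold, maximise between-class
# variance, smallest argmax wins
otsu_brute <- function(pixels) {
  v <- as.numeric(pixels)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:255) {
    bg <- v[v <= t]; fg <- v[v > t]
    if (length(bg) == 0 || length(fg) == 0) next
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# direct-summation Haralick descriptors from a normalized GLCM
glcm_oracle <- function(P) {
  N <- nrow(P)
  px <- rep(0, N); py <- rep(0, N)
  for (i in 1:N) for (j in 1:N) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- 0; muy <- 0
  for (i in 1:N) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sdx <- 0; sdy <- 0
  for (i in 1:N) { sdx <- sdx + (i - mux)^2 * px[i]; sdy <- sdy + (i - muy)^2 * py[i] }
  sdx <- sqrt(sdx); sdy <- sqrt(sdy)
  psum <- rep(0, 2 * N); pdif <- rep(0, N)       # indices k and k+1
  out <- c(autocorrelation = 0, contrast = 0, correlation = 0,
           cluster_prominence = 0, cluster_shade = 0, dissimilarity = 0,
           energy = 0, entropy = 0, homogeneity = 0, maximum_probability = 0,
           variance = 0, sum_average = 0, sum_variance = 0, sum_entropy = 0,
           difference_variance = 0, difference_entropy = 0, imc1 = 0,
           imc2 = 0, inn = 0, idn = 0, idm = 0)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:N) for (j in 1:N) {
    p <- P[i, j]
    out["autocorrelation"] <- out["autocorrelation"] + i * j * p
    out["contrast"] <- out["contrast"] + (i - j)^2 * p
    out["cluster_prominence"] <- out["cluster_prominence"] + (i + j - mux - muy)^4 * p
    out["cluster_shade"] <- out["cluster_shade"] + (i + j - mux - muy)^3 * p
    out["dissimilarity"] <- out["dissimilarity"] + abs(i - j) * p
    out["energy"] <- out["energy"] + p^2
    if (p > 0) out["entropy"] <- out["entropy"] - p * log(p)
    out["homogeneity"] <- out["homogeneity"] + p / (1 + abs(i - j))
    out["maximum_probability"] <- max(out["maximum_probability"], p)
    out["variance"] <- out["variance"] + (i - mux)^2 * p
    out["inn"] <- out["inn"] + p / (1 + abs(i - j) / N)
    out["idn"] <- out["idn"] + p / (1 + (i - j)^2 / N^2)
    out["idm"] <- out["idm"] + p / (1 + (i - j)^2)
    if (sdx > 0 && sdy > 0)
      out["correlation"] <- out["correlation"] + (i - mux) * (j - muy) * p / (sdx * sdy)
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
    if (px[i] * py[j] > 0) {
      hxy1 <- hxy1 - p * log(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
    }
  }
  for (k in 2:(2 * N)) out["sum_average"] <- out["sum_average"] + k * psum[k]
  for (k in 2:(2 * N)) {
    out["sum_variance"] <- out["sum_variance"] + (k - out["sum_average"])^2 * psum[k]
    if (psum[k] > 0) out["sum_entropy"] <- out["sum_entropy"] - psum[k] * log(psum[k])
  }
  mud <- 0
  for (k in 0:(N - 1)) mud <- mud + k * pdif[k + 1]
  for (k in 0:(N - 1)) {
    out["difference_variance"] <- out["difference_variance"] + (k - mud)^2 * pdif[k + 1]
    if (pdif[k + 1] > 0)
      out["difference_entropy"] <- out["difference_entropy"] - pdif[k + 1] * log(pdif[k + 1])
  }
  hx <- 0; hy <- 0
  for (i in 1:N) {
    if (px[i] > 0) hx <- hx - px[i] * log(px[i])
    if (py[i] > 0) hy <- hy - py[i] * log(py[i])
  }
  if (max(hx, hy) > 0)
    out["imc1"] <- (out[["entropy"]] - hxy1) / max(hx, hy)
  out["imc2"] <- sqrt(max(1 - exp(-2 * (hxy2 - out[["entropy"]])), 0))
  out
}

# triple-loop sample entropy (Chebyshev, self-matches excluded)
sampen_brute <- function(s, m, r) {
  n <- length(s)
  a <- 0; b <- 0
  for (i in 1:(n - m)) for (j in 1:(n - m)) {
    if (j <= i) next
    da <- 0; db <- 0
    for (k in 0:(m - 1)) da <- max(da, abs(s[i + k] - s[j + k]))
    for (k in 0:m) db <- max(db, abs(s[i + k] - s[j + k]))
    if (da <= r) a <- a + 1
    if (db <= r) b <- b + 1
  }
  -log(b / a)
}

# direct pair count of the correlation sum
corr_sum_brute <- function(pts, radii, theiler = 0L) {
  n <- nrow(pts)
  eligible <- 0
  hits <- rep(0, length(radii))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i <= theiler) next
    eligible <- eligible + 1
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    for (k in seq_along(radii)) if (d <= radii[k]) hits[k] <- hits[k] + 1
  }
  hits / eligible
}

# quadratic-loop domination ranks (peeling)
domination_ranks_brute <- function(objs) {
  n <- nrow(objs)
  dominates <- function(a, b) all(objs[a, ] <= objs[b, ]) && any(objs[a, ] < objs[b, ])
  rank <- rep(NA_integer_, n)
  level <- 0L
  remaining <- seq_len(n)
  while (length(remaining)) {
    level <- level + 1L
    front <- c()
    for (i in remaining) {
      dominated <- FALSE
      for (j in remaining) if (j != i && dominates(j, i)) { dominated <- TRUE; break }
      if (!dominated) front <- c(front, i)
    }
    rank[front] <- level
    remaining <- setdiff(remaining, front)
  }
  rank
}

# closed-form dual solution of the RBF SVM on the symmetric 4-point XOR
# problem: by symmetry all alphas are equal, a = 4 / sum_ij y_i y_j K_ij
# (valid while a < C); decision value f(x) = sum_i a y_i K(x_i, x) (b = 0)
xor_svm_oracle <- function(X, y_pm, sigma, C) {
  K <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma^2))
  S <- 0
  for (i in 1:4) for (j in 1:4) S <- S + y_pm[i] * y_pm[j] * K[i, j]
  a <- 4 / S
  stopifnot(a < C)              # interior solution, symmetry argument valid
  f <- sapply(1:4, function(k) sum(a * y_pm * K[, k]))
  sign(f)
}

# tiny phantom cohort shared by several tests
tiny_cohort <- function(n_per_class = 3, seed = 99)
  phantom_cohort(n_per_class, seed = seed)

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
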