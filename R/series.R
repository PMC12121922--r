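#' Reference series and point sets with known complexity
#'
#' Generates deterministic (seeded) dynamical-system trajectories and planar
#' point sets whose fractal dimension, Lyapunov exponent or correlation
#' dimension is known in closed form. These serve as ground truth when
#' validating the nonlinear feature estimators: the logistic map at r = 4 has
#' largest Lyapunov exponent ln 2, a pure sinusoid has exponent 0, the
#' Sierpinski triangle has box-counting dimension log 3 / log 2, a line has
#' dimension 1 and a filled square dimension 2.
#'
#' @param name one of `"logistic"`, `"henon"`, `"sine"`, `"const"`,
#'   `"white_noise"` (scalar series) or `"sierpinski"`, `"line"`,
#'   `"filled_square"` (binary images).
#' @param params named list of map/set parameters. Series: `r` (logistic,
#'   default 4), `a`,`b` (Henon, defaults 1.4, 0.3), `freq` in cycles/sample
#'   and `phase` (sine), `value` (const), `sd` (white noise). Point sets:
#'   `depth` (Sierpinski recursion depth, default 7), `size` (image side,
#'   default 128).
#' @param n series length (ignored for point sets); at least 500.
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @return an object of class `attractor_series`: a list with `name`,
#'   `values` (numeric vector) or `image` (binary matrix), `params`, `seed`.
#' @examples
#' s <- generate_series("logistic", list(r = 4), n = 1000, seed = 1)
#' range(s$values)  # inside [0, 1]
#' @export
generate_series <- function(name, params = list(), n = 1000, seed = 1) {
  name <- match.arg(name, c("logistic", "henon", "sine", "const",
                            "white_noise", "sierpinski", "line",
                            "filled_square"))
  is_series <- name %in% c("logistic", "henon", "sine", "const", "white_noise")
  if (is_series && n < 500) stopf("series length must be >= 500, got %d", n)
  p <- params
  out <- with_seed(seed, switch(name,
    logistic = {
      r <- p$r %||% 4
      x <- p$x0 %||% runif(1, 0.05, 0.95)
      burn <- 100L
      v <- numeric(n + burn)
      v[1] <- x
      for (t in seq_len(n + burn - 1L)) v[t + 1L] <- r * v[t] * (1 - v[t])
      list(values = v[(burn + 1L):(burn + n)])
    },
    henon = {
      a <- p$a %||% 1.4; b <- p$b %||% 0.3
      burn <- 100L
      x <- numeric(n + burn); y <- numeric(n + burn)
      x[1] <- runif(1, -0.1, 0.1); y[1] <- runif(1, -0.1, 0.1)
      for (t in seq_len(n + burn - 1L)) {
        x[t + 1L] <- 1 - a * x[t]^2 + y[t]
        y[t + 1L] <- b * x[t]
      }
      list(values = x[(burn + 1L):(burn + n)])
    },
    sine = {
      freq <- p$freq %||% 0.02370571  # irrational fraction of sampling rate
      phase <- p$phase %||% runif(1, 0, 2 * pi)
      list(values = sin(2 * pi * freq * seq_len(n) + phase))
    },
    const = list(values = rep(p$value %||% 1, n)),
    white_noise = list(values = rnorm(n, sd = p$sd %||% 1)),
    sierpinski = {
      depth <- p$depth %||% 7L
      side <- 2L^depth
      idx <- 0:(side - 1L)
      img <- outer(idx, idx, function(i, j) as.integer(bitwAnd(i, j) == 0L))
      list(image = img)
    },
    line = {
      size <- p$size %||% 128L
      img <- matrix(0L, size, size)
      img[size %/% 2L, ] <- 1L
      list(image = img)
    },
    filled_square = {
      size <- p$size %||% 128L
      list(image = matrix(1L, size, size))
    }
  ))
  structure(c(list(name = name, params = p, seed = seed), out),
            class = "attractor_series")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
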