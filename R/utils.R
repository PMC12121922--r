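# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# x log x with the 0 log 0 = 0 convention, natural log
#' @noRd
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# 3x3 box blur with edge replication, `passes` times
#' @noRd
box_blur <- function(m, passes = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    acc <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      acc <- acc + m[rs, cs]
    }
    m <- acc / 9
  }
  m
}

# fill interior holes: complement components not touching the image border.
# works on the mask bounding box (+1 margin) for speed.
#' @noRd
fill_holes <- function(mask) {
  if (!any(mask)) return(mask)
  bb <- mask_bbox(mask)
  r0 <- max(bb["rmin"] - 1L, 1L); r1 <- min(bb["rmax"] + 1L, nrow(mask))
  c0 <- max(bb["cmin"] - 1L, 1L); c1 <- min(bb["cmax"] + 1L, ncol(mask))
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  lab <- label_components(!sub, connectivity = 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sub <- sub | (!(lab %in% border[border > 0L]) & lab > 0L)
  mask[r0:r1, c0:c1] <- sub
  mask
}

# one binary closing pass (3x3 square structuring element)
#' @noRd
binary_close <- function(mask) {
  shift_or <- function(m, f) {
    out <- m
    nr <- nrow(m); nc <- ncol(m)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      out <- f(out, m[rs, cs])
    }
    out
  }
  dil <- shift_or(mask, `|`)
  shift_or(dil, `&`)
}

# bounding box (rmin, rmax, cmin, cmax) of TRUE cells in a logical matrix
#' @noRd
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("mask is empty")
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}

# 4/8-connected component labelling by breadth-first flood fill.
# Small masks only; returns an integer matrix, 0 = background.
#' @noRd
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- ((p - 1L) %% nr) + 1L
      c0 <- ((p - 1L) %/% nr) + 1L
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      q <- (cc[ok] - 1L) * nr + rr[ok]
      q <- q[mask[q] & lab[q] == 0L]
      if (length(q)) {
        lab[q] <- cur
        queue <- c(queue, q)
      }
    }
  }
  lab
}
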