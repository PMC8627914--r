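# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# user's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic orthonormal basis perpendicular to unit vector d.
perp_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(cross3(d, ref))
  v <- cross3(d, u)
  list(u = u, v = v)
}

# Cumulative arc length of an n x 3 polyline matrix (mm).
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Minimum distance between two 3-D segments (a1-a2, b1-b2).
segment_distance <- function(a1, a2, b1, b2) {
  d1 <- a2 - a1
  d2 <- b2 - b1
  r <- a1 - b1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  tiny <- 1e-12
  if (a <= tiny && e <= tiny) return(vnorm(r))
  if (a <= tiny) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    cc <- sum(d1 * r)
    if (e <= tiny) {
      t <- 0; s <- min(max(-cc / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > tiny) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  vnorm((a1 + s * d1) - (b1 + t * d2))
}
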