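# Internal geometry and RNG helpers shared across modules.

# Evaluate `expr` with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed < 2^31 from a parent seed and a stream index.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}

# Fibonacci lattice: n quasi-uniform points on the unit sphere.
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i      # golden-angle longitudes
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Angular (great-circle) distance matrix between rows of two unit-vector sets.
angular_distance <- function(a, b = a) {
  d <- tcrossprod(a, b)
  d[d > 1] <- 1
  d[d < -1] <- -1
  acos(d)
}

# Sample-standard-deviation z-score of a vector (ddof = 1).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

# Column-wise z-scoring of a matrix; zero-variance columns raise unless
# `fill0` maps them to all-zero columns (used inside bootstrap refits).
zscore_cols <- function(m, fill0 = FALSE) {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  bad <- !is.finite(s) | s == 0
  if (any(bad) && !fill0)
    stop("zero-variance column(s): ", paste(utils::head(colnames(m)[bad], 5), collapse = ", "))
  s[bad] <- 1
  out <- sweep(sweep(m, 2, mu), 2, s, "/")
  if (any(bad)) out[, bad] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
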