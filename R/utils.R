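# Shared numeric helpers: circular arithmetic and Gaussian smoothing kernels.
# Angles are radians in [0, 2*pi); bins are 1-based; intervals half-open [a, b).

wrap_angle <- function(theta) theta %% (2 * pi)

# Undo 2*pi jumps so a wrapped angle series can be interpolated.
unwrap_angle <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1] + cumsum(c(0, d))
}

# Signed minimal circular difference b - a on a circle of the given period,
# in [-period/2, period/2).
circ_signed_diff <- function(a, b, period = 2 * pi) {
  ((b - a + period / 2) %% period) - period / 2
}

# Fold an out-of-range index back into 1..n by mirror reflection (edge value
# repeated, scipy-style 'reflect'); used for boundary handling of short
# non-circular score sequences.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  ifelse(j < n, j + 1L, p - j)
}

# Circular (wrap-around) Gaussian smoothing of a length-n vector, sigma in
# index units. Kernel weights are renormalised so a uniform input is fixed.
smooth_circular <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  off <- (-r):r
  w <- dnorm(off, 0, sigma)
  w <- w / sum(w)
  idx <- outer(seq_len(n), off, function(i, o) ((i + o - 1L) %% n) + 1L)
  as.vector(matrix(x[idx], n, length(off)) %*% w)
}

# Gaussian smoothing with reflective boundaries for linear (non-circular)
# sequences such as per-visit selectivity scores.
smooth_reflect <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0 || n == 1L) return(x)
  r <- max(1L, ceiling(4 * sigma))
  off <- (-r):r
  w <- dnorm(off, 0, sigma)
  w <- w / sum(w)
  idx <- outer(seq_len(n), off, `+`)
  idx <- matrix(reflect_index(as.vector(idx), n), n, length(off))
  as.vector(matrix(x[idx], n, length(off)) %*% w)
}

# Centred running mean with partial windows at the edges (width in samples).
running_mean <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

circular_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

#' Circular correlation between two angle series
#'
#' Fisher--Lee T-linear circular association
#' \deqn{\rho = \frac{\sum_{i<j} \sin(a_i - a_j)\sin(b_i - b_j)}
#'   {\sqrt{\sum_{i<j}\sin^2(a_i - a_j)\sum_{i<j}\sin^2(b_i - b_j)}},}
#' computed in O(n) via trigonometric sum identities. It is invariant to
#' rotations of either variable and — unlike mean-direction-based
#' coefficients — remains well defined when the angles are uniformly
#' distributed on the circle, the typical case when comparing the angular
#' order of a ring embedding with the animal's position on the track.
#' A reflected ring gives -1.
#'
#' @param a,b Numeric vectors of angles in radians, equal length.
#' @return A single correlation value in \[-1, 1\].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 50)
#' circular_correlation(th, th + 0.3)
#' @export
circular_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  sa <- sin(a)
  ca <- cos(a)
  sb <- sin(b)
  cb <- cos(b)
  num <- sum(sa * sb) * sum(ca * cb) - sum(sa * cb) * sum(ca * sb)
  den_a <- sum(sa^2) * sum(ca^2) - sum(sa * ca)^2
  den_b <- sum(sb^2) * sum(cb^2) - sum(sb * cb)^2
  num / sqrt(den_a * den_b)
}

#' Cosine similarity between two vectors
#'
#' Used to compare the across-animal distribution of mean unselectivity
#' scores with the distribution of mean reconstruction error (residual
#' variance).
#'
#' @param u,v Numeric vectors of equal length (at least 2).
#' @return `sum(u * v) / (||u|| * ||v||)`.
#' @examples
#' cosine_similarity(c(1, 2, 3), c(2, 4, 6)) # collinear -> 1
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("cosine similarity undefined for a zero vector")
  }
  sum(u * v) / (nu * nv)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
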