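# Independent brute-force oracles, deliberately written in the most literal
# style possible (explicit loops) so they share no code path with the package.

# Reflective-boundary Gaussian smoothing by direct double loop.
oracle_smooth_reflect <- function(x, sigma) {
  n <- length(x)
  if (n == 1) return(x)
  r <- max(1, ceiling(4 * sigma))
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (o in (-r):r) {
      j <- i + o
      # mirror until inside [1, n]; the edge value is repeated
      # (j = 0 -> 1, j = -1 -> 2, j = n+1 -> n, ...)
      while (j < 1 || j > n) {
        if (j < 1) j <- 1 - j
        if (j > n) j <- 2 * n - j + 1
      }
      w <- exp(-o^2 / (2 * sigma^2))
      num <- num + w * x[j]
      den <- den + w
    }
    out[i] <- num / den
  }
  out
}

# Circular Gaussian smoothing by direct double loop.
oracle_smooth_circular <- function(x, sigma) {
  n <- length(x)
  r <- max(1, ceiling(4 * sigma))
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (o in (-r):r) {
      j <- ((i + o - 1) %% n) + 1
      w <- exp(-o^2 / (2 * sigma^2))
      num <- num + w * x[j]
      den <- den + w
    }
    out[i] <- num / den
  }
  out
}

# Raw selectivity score of one epoch by literal counting.
oracle_selectivity <- function(event_times, t_enter, t_exit, flank_start, flank_end) {
  n_in <- 0
  n_tot <- 0
  for (tt in event_times) {
    if (tt >= t_enter && tt < t_exit) n_in <- n_in + 1
    if (tt >= flank_start && tt < flank_end) n_tot <- n_tot + 1
  }
  if (n_tot == 0) return(NA_real_)
  n_in / n_tot
}

# Dense generalized eigen solver for L v = lambda D v via the non-symmetric
# standard problem D^{-1} L v = lambda v.
oracle_generalized_eigen <- function(adjacency) {
  deg <- rowSums(adjacency)
  L <- diag(deg) - adjacency
  e <- eigen(diag(1 / deg) %*% L)
  sort(Re(e$values))
}

# First start of a run of >= min_run TRUEs, by explicit scanning.
oracle_first_run <- function(flags, min_run) {
  n <- length(flags)
  for (s in seq_len(n)) {
    if (s + min_run - 1 > n) break
    if (all(flags[s:(s + min_run - 1)])) return(s)
  }
  NA_integer_
}

# Minimal signed circular difference by exhaustive candidate search.
oracle_circ_diff <- function(a, b, period) {
  cand <- b - a + c(-2, -1, 0, 1, 2) * period
  cand[which.min(abs(cand))]
}
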