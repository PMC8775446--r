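# Population-manifold stage: block-averaged activity matrix, k-nearest-
# neighbour similarity graph, Laplacian-eigenmaps embedding via the
# generalized eigenproblem L v = lambda D v, a PCA baseline, and residual
# variance as the measure of track-geometry reconstruction.

#' Prepare the population activity matrix
#'
#' Drops cells with fewer than `min_events` detected calcium events, then
#' applies a non-overlapping mean filter of width `w` frames, so the number
#' of time windows is `floor(T / w)`. Each column is one population activity
#' vector (a point in R^N).
#'
#' @param traces Cells x frames trace matrix (rownames are cell ids, `fps`
#'   attribute as produced by [render_traces()] or [read_traces_csv()]).
#' @param events Event tibble (`cell_id`, `t0`) used only for the
#'   event-count filter; cells absent from `events` count zero events.
#' @param w Window size in frames (positive integer; `w = 1` is the
#'   identity).
#' @param min_events Minimum number of events for a cell to be kept.
#' @param fps Frame rate in Hz.
#' @return A cells x windows matrix of class `activity_matrix` with
#'   attributes `fps`, `w` and `window_t` (window-centre times in seconds).
#' @export
prepare_activity <- function(traces, events, w = 8, min_events = 5,
                             fps = attr(traces, "fps")) {
  if (w < 1 || w != round(w)) abort("w must be a positive integer")
  if (is.null(fps)) abort("fps is required (no fps attribute on traces)")
  ids <- rownames(traces) %||% sprintf("cell%03d", seq_len(nrow(traces)))
  counts <- table(factor(events$cell_id, levels = ids))
  keep <- as.vector(counts) >= min_events
  if (!any(keep)) abort("no cell has enough events (min_events filter)")
  X <- traces[keep, , drop = FALSE]
  n_frames <- ncol(X)
  t_eff <- n_frames %/% w
  if (t_eff < 2) abort("too few frames for the requested window size")
  if (w > 1) {
    acc <- X[, seq(1, t_eff * w, by = w), drop = FALSE] * 0
    for (j in seq_len(w)) {
      acc <- acc + X[, seq(j, t_eff * w, by = w), drop = FALSE]
    }
    X <- acc / w
    rownames(X) <- ids[keep]
  }
  window_t <- (seq_len(t_eff) - 0.5) * w / fps
  structure(X,
    fps = fps, w = w, window_t = window_t,
    class = c("activity_matrix", "matrix", "array")
  )
}

#' Mean physical position of each activity window
#'
#' Positions aligned to the windows of [prepare_activity()]: the mean
#' `(x, y)` of each window's frames, plus the circular-mean angle.
#'
#' @param traj Trajectory tibble (`t`, `x`, `y`, `theta`).
#' @param w Window size in frames (must match the activity matrix).
#' @return A tibble with `window`, `t`, `x`, `y`, `theta`, one row per
#'   window.
#' @export
window_positions <- function(traj, w = 8) {
  n <- nrow(traj)
  t_eff <- n %/% w
  idx <- rep(seq_len(t_eff), each = w)
  used <- seq_len(t_eff * w)
  tibble(
    window = seq_len(t_eff),
    t = tapply(traj$t[used], idx, mean),
    x = tapply(traj$x[used], idx, mean),
    y = tapply(traj$y[used], idx, mean),
    theta = as.numeric(tapply(seq_along(used), idx, function(i) {
      circular_mean(traj$theta[used][i])
    }))
  )
}

#' Build the k-nearest-neighbour similarity graph
#'
#' Each window (column of the activity matrix) is connected to its `k`
#' nearest neighbours by Euclidean distance in R^N; the adjacency is then
#' symmetrized by logical OR, so `k` sets only the minimum degree. If the
#' graph is disconnected, the largest connected component is kept provided
#' the discarded share of nodes does not exceed 5%; otherwise the reduction
#' is considered unsuccessful and an error asks for a larger `k`.
#'
#' @param activity An `activity_matrix` (cells x windows), or any numeric
#'   matrix whose columns are the points to connect.
#' @param k Number of nearest neighbours (>= 1, < number of windows).
#' @param max_discard Maximum tolerated share of discarded nodes.
#' @return An object of class `knn_graph`: list with `adjacency` (binary
#'   symmetric matrix over kept nodes, zero diagonal), `k`, `kept_nodes`
#'   (indices into the original windows), `n_total`, `window_t` (times of
#'   kept windows when available).
#' @export
knn_graph <- function(activity, k, max_discard = 0.05) {
  n <- ncol(activity)
  if (k < 1 || k >= n) abort("need 1 <= k < number of windows")
  D <- as.matrix(dist(t(activity)))
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1)] # skip self (distance 0 ranks first)
    A[i, nb] <- TRUE
  }
  A <- A | t(A)
  diag(A) <- FALSE

  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  kept <- seq_len(n)
  if (comp$no > 1) {
    largest <- which.max(comp$csize)
    kept <- which(comp$membership == largest)
    discarded <- 1 - length(kept) / n
    if (discarded > max_discard) {
      abort(sprintf(
        "dimensionality reduction unsuccessful: %.1f%% of nodes outside the largest component (> %.0f%%); increase k",
        100 * discarded, 100 * max_discard
      ))
    }
    A <- A[kept, kept, drop = FALSE]
  }
  wt <- attr(activity, "window_t")
  structure(
    list(
      adjacency = A * 1, k = k, kept_nodes = kept, n_total = n,
      window_t = if (!is.null(wt)) wt[kept] else NULL
    ),
    class = "knn_graph"
  )
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf(
    "<knn_graph> %d/%d nodes kept, k = %d, %d edges\n",
    nrow(x$adjacency), x$n_total, x$k, sum(x$adjacency) / 2
  ))
  invisible(x)
}

#' Choose the smallest viable neighbour count
#'
#' Returns the smallest `k` among the candidates whose similarity graph
#' passes the connectivity rule (discarded share at most 5%); `k` should be
#' as small as possible so Euclidean distances remain locally meaningful on
#' the curved manifold.
#'
#' @inheritParams knn_graph
#' @param candidates Candidate neighbour counts, tried in increasing order.
#' @return The chosen `k` (integer).
#' @export
choose_k <- function(activity, candidates = c(5, 10, 15, 20, 30),
                     max_discard = 0.05) {
  for (k in sort(candidates)) {
    ok <- tryCatch(
      {
        knn_graph(activity, k, max_discard)
        TRUE
      },
      error = function(e) FALSE
    )
    if (ok) return(as.integer(k))
  }
  abort("no candidate k yields a sufficiently connected graph")
}

#' Laplacian-eigenmaps embedding of a similarity graph
#'
#' Solves the generalized eigenproblem `L v = lambda D v`, where `L = D - A`
#' is the graph Laplacian and `D` the degree matrix, via the symmetric
#' normalized form `D^{-1/2} L D^{-1/2} u = lambda u`, `v = D^{-1/2} u`.
#' Eigenvalues are sorted ascending; the first (zero, constant eigenvector)
#' mode is verified and dropped; the next `m` eigenvectors are the embedding
#' coordinates. More than one numerically-zero eigenvalue means the graph is
#' disconnected and is an error.
#'
#' @param graph A [knn_graph()].
#' @param m Embedding dimension (`m < n_nodes`).
#' @param zero_tol Numerical tolerance for zero eigenvalues.
#' @return An object of class `pf_embedding`: list with `coords`
#'   (kept_nodes x m matrix), `eigenvalues` (the m+1 smallest, ascending,
#'   first ~0), `method = "LE"`, `kept_nodes`, `window_t`, `k`. Eigenvector
#'   sign is fixed by making the largest-magnitude component positive.
#' @export
laplacian_eigenmaps <- function(graph, m = 2, zero_tol = 1e-8) {
  A <- graph$adjacency
  n <- nrow(A)
  if (m >= n) abort("m must be smaller than the number of nodes")
  deg <- rowSums(A)
  if (any(deg == 0)) abort("graph has isolated nodes")
  isq <- 1 / sqrt(deg)
  L_sym <- diag(n) - A * outer(isq, isq)
  L_sym <- (L_sym + t(L_sym)) / 2
  e <- eigen(L_sym, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, n:1, drop = FALSE]
  n_zero <- sum(abs(vals) < zero_tol)
  if (n_zero != 1) {
    abort(sprintf(
      "connectivity violation: %d numerically-zero eigenvalues (graph must be connected)",
      n_zero
    ))
  }
  coords <- vecs[, 2:(m + 1), drop = FALSE] * isq
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  structure(
    list(
      coords = coords, eigenvalues = vals[seq_len(m + 1)], method = "LE",
      kept_nodes = graph$kept_nodes, window_t = graph$window_t, k = graph$k
    ),
    class = "pf_embedding"
  )
}

#' PCA baseline embedding
#'
#' Column-centred projection of the window activity vectors onto the top `m`
#' principal components. Linear baseline for comparison with
#' [laplacian_eigenmaps()].
#'
#' @param activity An `activity_matrix` (cells x windows).
#' @param m Embedding dimension.
#' @return A `pf_embedding` with `method = "PCA"`; `eigenvalues` holds the
#'   variances of all principal components (descending).
#' @export
pca_embedding <- function(activity, m = 2) {
  if (m > min(dim(activity))) abort("m must not exceed min(cells, windows)")
  pc <- prcomp(t(activity), center = TRUE, scale. = FALSE)
  structure(
    list(
      coords = pc$x[, seq_len(m), drop = FALSE],
      eigenvalues = pc$sdev^2, method = "PCA",
      kept_nodes = seq_len(ncol(activity)),
      window_t = attr(activity, "window_t"), k = NA_integer_
    ),
    class = "pf_embedding"
  )
}

#' @export
print.pf_embedding <- function(x, ...) {
  cat(sprintf(
    "<pf_embedding> %s: %d nodes -> %d dims\n",
    x$method, nrow(x$coords), ncol(x$coords)
  ))
  invisible(x)
}

#' @rdname laplacian_eigenmaps
#' @param x A `pf_embedding` object.
#' @param ... Unused.
#' @export
tidy.pf_embedding <- function(x, ...) {
  out <- tibble(window = x$kept_nodes)
  if (!is.null(x$window_t)) out$t <- x$window_t
  cc <- as_tibble(x$coords, .name_repair = ~ paste0("dim", seq_along(.x)))
  dplyr::bind_cols(out, cc)
}

#' @rdname laplacian_eigenmaps
#' @export
glance.pf_embedding <- function(x, ...) {
  tibble(
    method = x$method, n_nodes = nrow(x$coords), m = ncol(x$coords),
    k = x$k,
    fiedler_value = if (x$method == "LE") x$eigenvalues[2] else NA_real_
  )
}

#' Residual variance of a geometry reconstruction
#'
#' `RV = 1 - rho^2`, where `rho` is the Pearson correlation between the
#' pairwise Euclidean distances of the physical positions and those of the
#' embedding coordinates (strictly-upper-triangular entries). 0 means the
#' embedding reproduces track geometry up to a similarity transform; 1 means
#' no geometric correspondence.
#'
#' @param positions Window positions: a tibble from [window_positions()]
#'   (columns `x`, `y`) or a numeric matrix with one row per window,
#'   covering *all* windows (the embedding's `kept_nodes` selects rows).
#' @param embedding A `pf_embedding`, or a coordinate matrix aligned with
#'   `positions`.
#' @return An object of class `rv_result`: list with `rv`, `rho`, `n`.
#' @export
residual_variance <- function(positions, embedding) {
  P <- if (is.data.frame(positions)) {
    as.matrix(positions[, c("x", "y")])
  } else {
    as.matrix(positions)
  }
  if (inherits(embedding, "pf_embedding")) {
    C <- embedding$coords
    P <- P[embedding$kept_nodes, , drop = FALSE]
  } else {
    C <- as.matrix(embedding)
  }
  if (nrow(P) != nrow(C)) abort("positions and embedding are not aligned")
  rho <- cor(as.vector(dist(P)), as.vector(dist(C)))
  structure(list(rv = 1 - rho^2, rho = rho, n = nrow(C)), class = "rv_result")
}

#' @export
print.rv_result <- function(x, ...) {
  cat(sprintf(
    "<rv_result> residual variance %.4f (rho = %.4f, n = %d windows)\n",
    x$rv, x$rho, x$n
  ))
  invisible(x)
}

#' Sliding-window residual variance
#'
#' Recomputes the full graph + Laplacian-eigenmaps + residual-variance
#' pipeline on successive time slices of the session, tracking how the
#' quality of the track-geometry reconstruction evolves as the animal
#' becomes familiar with the environment.
#'
#' @param activity An `activity_matrix`.
#' @param positions Window positions tibble from [window_positions()],
#'   aligned with `activity` (same `w`).
#' @param window Slice length in seconds.
#' @param stride Step between slice starts in seconds.
#' @param k Neighbour count for each slice's graph.
#' @param m Embedding dimension.
#' @return A tibble with `t_center` (s), `rv`, `n_nodes`, `ok` (FALSE when a
#'   slice's graph failed the connectivity rule; `rv` is then `NA`).
#' @export
sliding_rv <- function(activity, positions, window = 250, stride = 25,
                       k = 15, m = 2) {
  wt <- attr(activity, "window_t")
  if (is.null(wt)) abort("activity must carry window_t (use prepare_activity)")
  t_end <- max(wt)
  starts <- seq(0, max(0, t_end - window), by = stride)
  if (length(starts) == 0) starts <- 0
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    sel <- which(wt >= starts[i] & wt < starts[i] + window)
    row <- tibble(
      t_center = starts[i] + window / 2, rv = NA_real_,
      n_nodes = length(sel), ok = FALSE
    )
    if (length(sel) > k + m + 1) {
      sub <- activity[, sel, drop = FALSE]
      attr(sub, "window_t") <- wt[sel]
      res <- tryCatch(
        {
          g <- knn_graph(sub, k)
          emb <- laplacian_eigenmaps(g, m)
          rv <- residual_variance(positions[sel, , drop = FALSE], emb)
          list(rv = rv$rv, n = rv$n)
        },
        error = function(e) NULL
      )
      if (!is.null(res)) {
        row$rv <- res$rv
        row$n_nodes <- res$n
        row$ok <- TRUE
      }
    }
    out[[i]] <- row
  }
  bind_rows(out)
}

#' Time-resolved unselectivity score
#'
#' One minus the mean selectivity score over fields, as a function of time:
#' each field's raw per-visit scores are placed at the visit entry times,
#' linearly interpolated onto a regular time grid, averaged across fields,
#' negated plus one, and smoothed with a running-average filter.
#'
#' @param scores Selectivity tibble from [selectivity_scores()] (or
#'   [smooth_selectivity()]); scoreless (`NA`) visits are ignored.
#' @param t_max End of the time grid in seconds.
#' @param window Running-average window length in seconds.
#' @param dt Grid step in seconds.
#' @return A tibble with `t` and `unselectivity` in \[0, 1\].
#' @export
unselectivity_curve <- function(scores, t_max, window = 250, dt = 1) {
  sc <- filter(scores, !is.na(.data$raw))
  if (nrow(sc) == 0) abort("no scored visits")
  grid <- seq(0, t_max, by = dt)
  per_field <- split(sc, paste(sc$cell_id, sc$field_id))
  curves <- vapply(per_field, function(f) {
    if (nrow(f) == 1) {
      rep(f$raw, length(grid))
    } else {
      approx(f$t_enter, f$raw, xout = grid, rule = 2)$y
    }
  }, numeric(length(grid)))
  u <- 1 - rowMeans(curves)
  tibble(t = grid, unselectivity = running_mean(u, round(window / dt)))
}
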