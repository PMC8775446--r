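# Population manifold: activity preparation, k-NN graph, Laplacian
# eigenmaps, PCA baseline, residual variance, sliding windows.

as_activity <- function(m, window_t = NULL) {
  structure(m,
    fps = 20, w = 1,
    window_t = window_t %||% seq_len(ncol(m)),
    class = c("activity_matrix", "matrix", "array")
  )
}

ring_points <- function(n, radius = 1) {
  th <- (seq_len(n) - 1) / n * 2 * pi
  rbind(radius * cos(th), radius * sin(th))
}

test_that("activity preparation filters cells and block-averages windows", {
  set.seed(1)
  tr <- matrix(rnorm(3 * 40), 3, 40, dimnames = list(c("a", "b", "c"), NULL))
  attr(tr, "fps") <- 20
  ev <- tibble::tibble(
    cell_id = c(rep("a", 6), rep("b", 4), rep("c", 5)),
    t0 = runif(15, 0, 2)
  )
  # w = 1 is the identity on kept cells
  a1 <- prepare_activity(tr, ev, w = 1, min_events = 5)
  expect_identical(rownames(a1), c("a", "c")) # b has 4 events -> dropped
  expect_equal(unclass(a1)[, ], tr[c("a", "c"), ], ignore_attr = TRUE)

  # w = 8: floor(40/8) = 5 windows of plain means
  a8 <- prepare_activity(tr, ev, w = 8, min_events = 5)
  expect_identical(ncol(a8), 5L)
  expect_equal(unname(a8["a", 2]), mean(tr["a", 9:16]), tolerance = 1e-12)
  expect_equal(attr(a8, "window_t")[1], 8 / 2 / 20, tolerance = 1e-12)

  # T = 18000, w = 8 -> 2250 windows
  big <- matrix(0, 1, 18000, dimnames = list("a", NULL))
  attr(big, "fps") <- 20
  ev_a <- tibble::tibble(cell_id = rep("a", 6), t0 = 1:6)
  expect_identical(ncol(prepare_activity(big, ev_a, w = 8)), 2250L)
})

test_that("the k-NN graph is symmetric and respects the discard rule", {
  # three collinear equidistant points, k = 1 -> path graph after OR
  x <- matrix(c(0, 1, 2), 1, 3)
  g <- knn_graph(as_activity(x), k = 1)
  expect_equal(g$adjacency, rbind(
    c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)
  ), ignore_attr = TRUE)
  expect_equal(rowSums(g$adjacency)[2], 2) # middle node degree 2

  # two far clusters, minority 4 of 100 -> largest kept, 4% discarded
  set.seed(2)
  pts <- cbind(
    ring_points(96) + rnorm(2 * 96, 0, 0.01),
    ring_points(4) + 100
  )
  g2 <- knn_graph(as_activity(pts), k = 2)
  expect_identical(length(g2$kept_nodes), 96L)
  expect_setequal(g2$kept_nodes, 1:96)

  # minority 10 of 100 -> 10% discard exceeds the 5% rule
  pts_bad <- cbind(
    ring_points(90) + rnorm(2 * 90, 0, 0.01),
    ring_points(10, radius = 0.2) + 100
  )
  expect_error(knn_graph(as_activity(pts_bad), k = 2), "increase k")

  # symmetry, zero diagonal, minimum degree k on a generic cloud
  set.seed(3)
  cloud <- matrix(rnorm(5 * 60), 5, 60)
  g3 <- knn_graph(as_activity(cloud), k = 4)
  expect_identical(g3$adjacency, t(g3$adjacency))
  expect_true(all(diag(g3$adjacency) == 0))
  expect_true(all(rowSums(g3$adjacency) >= 4))
})

test_that("choose_k returns the smallest candidate passing the connectivity rule", {
  set.seed(4)
  pts <- cbind(
    ring_points(70) + rnorm(140, 0, 0.05),
    ring_points(30, radius = 0.8) + 50 + rnorm(60, 0, 0.05)
  )
  ks <- c(2, 5, 50)
  k_star <- choose_k(as_activity(pts), candidates = ks)
  expect_true(k_star %in% ks)
  # chosen k works; all smaller candidates fail
  expect_s3_class(knn_graph(as_activity(pts), k_star), "knn_graph")
  for (k in ks[ks < k_star]) {
    expect_error(knn_graph(as_activity(pts), k))
  }
})

test_that("cycle-graph eigenvalues match the closed form 1 - cos(2*pi*j/n)", {
  n <- 12
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, (i %% n) + 1] <- 1
    A[(i %% n) + 1, i] <- 1
  }
  g <- list(adjacency = A, k = 2, kept_nodes = seq_len(n), window_t = NULL)
  class(g) <- "knn_graph"
  emb <- laplacian_eigenmaps(g, m = 4)
  want <- sort(1 - cos(2 * pi * (0:(n - 1)) / n))[1:5]
  expect_equal(emb$eigenvalues, want, tolerance = 1e-10)
  # the first nontrivial pair embeds the cycle in order on a circle
  ang <- atan2(emb$coords[, 2], emb$coords[, 1])
  steps <- diff(c(ang, ang[1]))
  steps <- ((steps + pi) %% (2 * pi)) - pi
  expect_true(all(steps > 0) || all(steps < 0))
})

test_that("complete-graph spectrum and constant zero-mode are reproduced", {
  A <- matrix(1, 4, 4) - diag(4)
  g <- list(adjacency = A, k = 3, kept_nodes = 1:4, window_t = NULL)
  class(g) <- "knn_graph"
  emb <- laplacian_eigenmaps(g, m = 3)
  expect_equal(emb$eigenvalues, c(0, 4 / 3, 4 / 3, 4 / 3), tolerance = 1e-10)
})

test_that("generalized eigenpairs agree with a dense independent solver", {
  set.seed(5)
  for (rep in 1:4) {
    n <- sample(30:80, 1)
    repeat {
      A <- matrix(rbinom(n * n, 1, 3 / n), n, n)
      A[lower.tri(A, diag = TRUE)] <- 0
      A <- A + t(A)
      A[A > 1] <- 1
      g_i <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      if (igraph::is_connected(g_i) && all(rowSums(A) > 0)) break
    }
    g <- list(adjacency = A, k = NA, kept_nodes = seq_len(n), window_t = NULL)
    class(g) <- "knn_graph"
    m <- 5
    emb <- laplacian_eigenmaps(g, m = m)
    want <- oracle_generalized_eigen(A)
    expect_equal(emb$eigenvalues, want[seq_len(m + 1)], tolerance = 1e-8)
    # each coordinate satisfies L v = lambda D v
    deg <- rowSums(A)
    L <- diag(deg) - A
    for (j in seq_len(m)) {
      v <- emb$coords[, j]
      lam <- emb$eigenvalues[j + 1]
      expect_lt(max(abs(L %*% v - lam * deg * v)), 1e-8)
    }
  }
})

test_that("disconnected graphs are rejected by the embedding", {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  A[4, 5] <- A[5, 4] <- A[5, 6] <- A[6, 5] <- 1
  g <- list(adjacency = A, k = 1, kept_nodes = 1:6, window_t = NULL)
  class(g) <- "knn_graph"
  expect_error(laplacian_eigenmaps(g, 2), "connectivity violation")
})

test_that("PCA baseline reproduces exactly low-rank structure", {
  set.seed(6)
  # rank-2 data in an orthonormal plane: the 2-D PCA embedding preserves
  # all pairwise distances -> rv 0
  basis <- qr.Q(qr(matrix(rnorm(10 * 2), 10, 2)))
  scores <- matrix(rnorm(2 * 50), 2, 50)
  X <- basis %*% scores
  emb <- pca_embedding(as_activity(X), m = 2)
  pos <- t(scores)
  rv <- residual_variance(cbind(x = pos[, 1], y = pos[, 2]), emb$coords)
  expect_lt(rv$rv, 1e-10)

  # rank-1 data: the first component carries all the variance
  X1 <- matrix(rnorm(8), 8, 1) %*% matrix(rnorm(40), 1, 40)
  e1 <- pca_embedding(as_activity(X1), m = 3)
  expect_gt(e1$eigenvalues[1] / sum(e1$eigenvalues), 1 - 1e-10)

  # isotropic noise: top-m share of variance near m/N
  Xi <- matrix(rnorm(40 * 2000), 40, 2000)
  ei <- pca_embedding(as_activity(Xi), m = 2)
  expect_equal(sum(ei$eigenvalues[1:2]) / sum(ei$eigenvalues), 2 / 40,
    tolerance = 0.25
  )
})

test_that("residual variance is zero under similarity transforms and ~1 for noise", {
  set.seed(7)
  geom <- track_geometry()
  traj <- simulate_trajectory(geom, duration = 300, turn_prob = 0.1, seed = 7)
  pos <- window_positions(traj, w = 8)
  P <- as.matrix(pos[, c("x", "y")])

  expect_lt(residual_variance(pos, P)$rv, 1e-12)

  a <- 0.7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  transformed <- 3.2 * P %*% R + matrix(c(5, -2), nrow(P), 2, byrow = TRUE)
  expect_lt(residual_variance(pos, transformed)$rv, 1e-12)

  noise <- matrix(rnorm(nrow(P) * 2), ncol = 2)
  rv_noise <- residual_variance(pos, noise)$rv
  expect_gte(nrow(P), 500)
  expect_gt(rv_noise, 0.9)
})

test_that("a sliding window covering the whole session equals the global value", {
  set.seed(8)
  geom <- track_geometry()
  cells <- place_cell_population(60)
  ses <- simulate_session(cells, geom, duration = 240, seed = 12)
  ev <- dplyr::rename(ses$spikes, t0 = t)
  act <- prepare_activity(ses$traces, ev, w = 8)
  pos <- window_positions(ses$trajectory, w = 8)

  g <- knn_graph(act, 10)
  global <- residual_variance(pos, laplacian_eigenmaps(g, 2))$rv
  srv <- sliding_rv(act, pos, window = 240, stride = 240, k = 10, m = 2)
  expect_identical(nrow(srv), 1L)
  expect_equal(srv$rv, global, tolerance = 1e-10)
})

test_that("unselectivity curve reflects constant and step score histories", {
  mk_scores <- function(raw) {
    tibble::tibble(
      cell_id = "c1", field_id = 1L, visit = seq_along(raw),
      t_enter = seq(10, 590, length.out = length(raw)), raw = raw
    )
  }
  flat1 <- unselectivity_curve(mk_scores(rep(1, 12)), t_max = 600)
  expect_true(all(abs(flat1$unselectivity) < 1e-12))
  flat0 <- unselectivity_curve(mk_scores(rep(0, 12)), t_max = 600)
  expect_true(all(abs(flat0$unselectivity - 1) < 1e-12))

  # a 0 -> 1 step smoothed by a 250 s boxcar: non-increasing ramp
  step <- unselectivity_curve(
    mk_scores(c(rep(0, 6), rep(1, 6))),
    t_max = 600, window = 250
  )
  expect_true(all(diff(step$unselectivity) <= 1e-9))
  expect_gt(step$unselectivity[1], 0.9)
  expect_lt(step$unselectivity[nrow(step)], 0.1)
})

test_that("cosine similarity matches hand values", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, -1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("circular correlation is high for rotated angles and ~0 for independent ones", {
  th <- seq(0, 2 * pi, length.out = 200)
  expect_equal(circular_correlation(th, (th + 1) %% (2 * pi)), 1,
    tolerance = 1e-6
  )
  set.seed(9)
  expect_lt(abs(circular_correlation(th, runif(200, 0, 2 * pi))), 0.2)
})
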