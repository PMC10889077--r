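test_that("collinear toy graph matches hand enumeration", {
  # points 0, 1, 3 with k = ks = 1: mutual edge (1,2); MST adds (2,3)
  g <- mutual_knn_path_graph(matrix(c(0, 1, 3), 3, 1), k = 1, ks = 1)
  a <- as.matrix(g$adjacency)
  expect_equal(a[1, 2], 1)
  expect_equal(a[2, 3], 2)
  expect_equal(a[1, 3], 0)
  expect_equal(a, t(a))
})

test_that("path-connectivity graph is always one connected component", {
  set.seed(9)
  for (trial in 1:50) {
    n <- sample(5:60, 1)
    d <- sample(2:5, 1)
    # include well-separated clumps to stress the MST repair
    X <- rbind(matrix(rnorm(ceiling(n / 2) * d), ncol = d),
               matrix(rnorm(floor(n / 2) * d, mean = 50), ncol = d))
    mode <- sample(c("min_tree", "full_tree"), 1)
    g <- mutual_knn_path_graph(X, k = sample(1:5, 1), ks = sample(5:10, 1),
                               connectivity_mode = mode)
    ig <- igraph::graph_from_adjacency_matrix(g$adjacency, "undirected",
                                              weighted = TRUE)
    expect_equal(igraph::components(ig)$no, 1)
    expect_true(Matrix::isSymmetric(g$adjacency))
  }
})

test_that("fuzzy weights satisfy the calibration and symmetrization rules", {
  set.seed(10)
  X <- matrix(rnorm(120 * 3), 120, 3)
  g <- mutual_knn_path_graph(X, k = 10, ks = 20)
  fz <- fuzzy_simplicial_set(g, k = 10)
  expect_lt(max(abs(attr(fz, "residual"))), 1e-5)
  w <- fz$adjacency@x
  expect_true(all(w > 0 & w <= 1))
  expect_identical(as.matrix(fz$adjacency), t(as.matrix(fz$adjacency)))
  # nearest neighbor gets directed weight exp(0) = 1; after the t-conorm
  # a + b - ab with any b, it stays 1
  nn1 <- apply(as.matrix(g$adjacency), 1, function(r) which(r > 0)[which.min(r[r > 0])])
  # symmetrization of (0.5, 0.5) -> 0.75 (t-conorm identity)
  expect_equal(0.5 + 0.5 - 0.25, 0.75)
})

test_that("CPM quality behaves analytically", {
  m <- matrix(0, 8, 8); m[1:4, 1:4] <- 1; m[5:8, 5:8] <- 1; diag(m) <- 0
  m[4, 5] <- m[5, 4] <- 1
  g <- structure(list(adjacency = Matrix::drop0(Matrix::Matrix(m, sparse = TRUE)),
                      mode = "membership", n = 8), class = "WeightedGraph")
  split_part <- rep(c(0, 1), each = 4)
  merged <- rep(0, 8)
  # split: 2 * (6 - 0.5*6) = 6; merged: 13 - 0.5*28 = -1
  expect_equal(cpm_quality(g, split_part, 0.5), 6)
  expect_equal(cpm_quality(g, merged, 0.5), -1)
  # quality monotone non-increasing in gamma for a fixed partition
  gammas <- seq(0, 2, by = 0.25)
  q <- vapply(gammas, function(gm) cpm_quality(g, split_part, gm), numeric(1))
  expect_true(all(diff(q) <= 1e-12))
})

test_that("Leiden-CPM finds the planted two-clique split and is seed-stable", {
  m <- matrix(0, 8, 8); m[1:4, 1:4] <- 1; m[5:8, 5:8] <- 1; diag(m) <- 0
  m[4, 5] <- m[5, 4] <- 1
  g <- structure(list(adjacency = Matrix::drop0(Matrix::Matrix(m, sparse = TRUE)),
                      mode = "membership", n = 8), class = "WeightedGraph")
  p <- leiden_cpm(g, gamma = 0.5, seed = 3)
  expect_equal(p$membership[1:4], rep(p$membership[1], 4))
  expect_equal(p$membership[5:8], rep(p$membership[5], 4))
  expect_false(p$membership[1] == p$membership[5])
  expect_equal(p$quality, 6)
  expect_identical(leiden_cpm(g, gamma = 0.5, seed = 3)$membership,
                   p$membership)
  # gamma = 0: one cluster is optimal
  p0 <- leiden_cpm(g, gamma = 0, seed = 3)
  expect_equal(length(unique(p0$membership)), 1)
  expect_error(leiden_cpm(g, gamma = -1), "non-negative")
})

test_that("Leiden-CPM reaches the exhaustive optimum on small random graphs", {
  # all set partitions of <= 8 vertices, enumerated via restricted growth
  all_partitions <- function(n) {
    out <- list()
    rec <- function(assign, k) {
      i <- length(assign) + 1
      if (i > n) { out[[length(out) + 1]] <<- assign; return() }
      for (c in seq_len(k + 1)) rec(c(assign, c), max(k, c))
    }
    rec(integer(0), 0)
    out
  }
  set.seed(12)
  parts_by_n <- list()
  for (trial in 1:30) {
    n <- sample(4:7, 1)
    p_edge <- runif(1, 0.3, 0.9)
    m <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < p_edge) m[i, j] <- m[j, i] <- runif(1, 0.1, 2)
    g <- structure(list(adjacency = Matrix::drop0(Matrix::Matrix(m, sparse = TRUE)),
                        mode = "membership", n = n), class = "WeightedGraph")
    gamma <- runif(1, 0, 1)
    key <- as.character(n)
    if (is.null(parts_by_n[[key]])) parts_by_n[[key]] <- all_partitions(n)
    best <- max(vapply(parts_by_n[[key]], function(pp)
      cpm_quality(g, pp, gamma), numeric(1)))
    found <- leiden_cpm(g, gamma = gamma, seed = trial)$quality
    expect_gte(found, best - 1e-9)
  }
})

test_that("resolution selection follows the stability-then-quality rule", {
  mk <- function(membership, gamma, quality)
    structure(list(membership = membership, resolution = gamma,
                   quality = quality), class = "Partition")
  # identical partitions at every resolution: lowest returned
  same <- lapply(c("0.1", "0.5", "1"), function(r) mk(rep(0:1, 5), as.numeric(r), 1 / as.numeric(r)))
  names(same) <- c("0.1", "0.5", "1")
  expect_equal(select_resolution(same), 0.1)
  expect_error(select_resolution(list()), "no partitions")
})

test_that("resolution scan recovers planted Gaussian blobs", {
  set.seed(13)
  X <- rbind(matrix(rnorm(60 * 2), 60, 2),
             matrix(rnorm(60 * 2, mean = 8), 60, 2))
  truth <- rep(0:1, each = 60)
  g <- fuzzy_simplicial_set(mutual_knn_path_graph(X, k = 10, ks = 20), k = 10)
  gammas <- c(0.001, 0.005, 0.01, 0.05, 0.1)
  parts <- lapply(gammas, function(gm) leiden_cpm(g, gamma = gm, seed = 2))
  names(parts) <- gammas
  chosen <- select_resolution(parts)
  memb <- parts[[as.character(chosen)]]$membership
  expect_gte(mclust::adjustedRandIndex(memb, truth), 0.95)
})

test_that("cluster-graph connectivity matches hand arithmetic on a toy", {
  # two triangles (clusters) fully tied by unit-weight cross edges
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 1; diag(m) <- 0
  for (i in 1:3) for (j in 4:6) m[i, j] <- m[j, i] <- 1
  g <- structure(list(adjacency = Matrix::drop0(Matrix::Matrix(m, sparse = TRUE)),
                      mode = "membership", n = 6), class = "WeightedGraph")
  memb <- rep(1:2, each = 3)
  # W = 15, deg_a = deg_b = 15, expected = 15*15/30 = 7.5; observed = 9
  # ratio 1.2 -> clipped to 1
  cc <- paga_connectivity(g, memb)
  expect_equal(cc[1, 2], 1)
  expect_equal(cc, t(cc))
  expect_equal(diag(cc), c(0, 0))
  # no cross edges -> 0
  m2 <- m; m2[1:3, 4:6] <- 0; m2[4:6, 1:3] <- 0
  g2 <- structure(list(adjacency = Matrix::drop0(Matrix::Matrix(m2, sparse = TRUE)),
                       mode = "membership", n = 6), class = "WeightedGraph")
  expect_equal(paga_connectivity(g2, memb)[1, 2], 0)
  # singleton partition: 1x1 zero matrix
  expect_equal(paga_connectivity(g, rep(1, 6)), matrix(0, 1, 1))
})

test_that("label projection recovers separable training labels", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40 * 2), 40, 2),
             matrix(rnorm(40 * 2, mean = 6), 40, 2))
  labs <- rep(c("a", "b"), each = 40)
  pred <- project_microclusters(X, labs, X)
  expect_equal(pred, labs)
  # predicted labels stay inside the training label set
  Xnew <- matrix(rnorm(30 * 2, mean = 3), 30, 2)
  prednew <- project_microclusters(X, labs, Xnew)
  expect_true(all(prednew %in% c("a", "b")))
  expect_identical(prednew, project_microclusters(X, labs, Xnew))
  expect_warning(project_microclusters(X, rep("a", 80), Xnew), "single class")
})

test_that("multiplex CPM equals the summed-layer identity", {
  m1 <- matrix(0, 6, 6); m1[1:3, 1:3] <- 1; m1[4:6, 4:6] <- 1; diag(m1) <- 0
  m2 <- m1 * 0.5
  mk <- function(m) structure(list(adjacency = Matrix::drop0(Matrix::Matrix(m, sparse = TRUE)),
                                   mode = "membership", n = 6), class = "WeightedGraph")
  layers <- list(mk(m1), mk(m2))
  p <- leiden_cpm_multiplex(layers, gamma = 0.3, seed = 2)
  # quality reported is the sum of per-layer qualities at the shared partition
  expect_equal(p$quality,
               cpm_quality(layers[[1]], p$membership, 0.3) +
                 cpm_quality(layers[[2]], p$membership, 0.3))
  # the planted two-block structure is recovered
  expect_equal(length(unique(p$membership)), 2)
  small <- structure(list(adjacency = Matrix::drop0(Matrix::Matrix(m1[1:5, 1:5],
                                                                   sparse = TRUE)),
                          mode = "membership", n = 5), class = "WeightedGraph")
  expect_error(leiden_cpm_multiplex(list(mk(m1), small)), "vertex set")
})
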