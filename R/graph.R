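# ---------------------------------------------------------------------------
# Mutual-kNN/MST path-connectivity graphs, fuzzy simplicial weighting,
# CPM-Leiden microclustering, resolution selection, cluster-graph
# abstraction (PAGA-style) and SVM label projection.
# ---------------------------------------------------------------------------

# Both triangles of a (possibly symmetric-storage) adjacency, so that
# Matrix::summary enumerates every directed edge.
.general_adj <- function(adj) {
  as(as(adj, "CsparseMatrix"), "generalMatrix")
}

# Sparse symmetric weighted graph constructor; zero weights (duplicate
# points) are stored as a tiny positive number so the edge survives in the
# sparse representation.
.make_graph <- function(i, j, w, n, mode) {
  w[w == 0] <- 1e-300
  a <- i > j
  tmp <- i[a]; i[a] <- j[a]; j[a] <- tmp      # canonical orientation
  key <- paste(i, j)
  keep <- !duplicated(key) & i != j
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                              dims = c(n, n))
  structure(list(adjacency = adj, mode = mode, n = n), class = "WeightedGraph")
}

#' Mutual-kNN graph with MST path-connectivity
#'
#' Builds the expanded `ks`-nearest-neighbor graph, keeps mutual edges
#' (each endpoint inside the other's `ks`-neighborhood), then restores
#' connectivity with minimum-spanning-tree edges: `"min_tree"` adds only the
#' MST edges needed to connect components, `"full_tree"` adds every MST
#' edge.  Vertices left with fewer than `k` neighbors receive their nearest
#' remaining candidates.  The result is symmetric and connected by
#' construction.
#'
#' @param embedding Points-by-dims numeric matrix (at least 2 points).
#' @param k Minimum neighbor count per vertex (default 10).
#' @param ks Expanded neighborhood size for the mutual test (default
#'   `k + 10`).
#' @param metric `"euclidean"` or `"cosine"`.
#' @param connectivity_mode `"min_tree"` or `"full_tree"`.
#' @return A `WeightedGraph` of distances.
#' @export
mutual_knn_path_graph <- function(embedding, k = 10, ks = k + 10,
                                  metric = c("euclidean", "cosine"),
                                  connectivity_mode = c("min_tree", "full_tree")) {
  metric <- match.arg(metric)
  connectivity_mode <- match.arg(connectivity_mode)
  X <- as.matrix(embedding)
  n <- nrow(X)
  if (n < 2) {
    warning("single point: returning empty graph")
    return(.make_graph(integer(0), integer(0), numeric(0), n, "distance"))
  }
  stopifnot(ks >= k, k >= 1)
  if (metric == "cosine") X <- .cosine_normalize(X)
  ks_eff <- min(ks, n - 1L)
  k_eff <- min(k, n - 1L)
  nn <- .knn_index(X, ks_eff)
  # mutual edges within the expanded neighborhoods
  src <- rep(seq_len(n), each = ks_eff)
  dst <- as.vector(t(nn$index))
  dd <- as.vector(t(nn$dist))
  in_nn <- matrix(FALSE, n, n)
  in_nn[cbind(src, dst)] <- TRUE
  mutual <- in_nn[cbind(src, dst)] & in_nn[cbind(dst, src)]
  ei <- src[mutual]; ej <- dst[mutual]; ew <- dd[mutual]
  # MST over the kNN union distance graph (falls back to nearest-pair
  # linking when that graph is itself disconnected)
  g_knn <- igraph::graph_from_data_frame(
    data.frame(from = src, to = dst), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::E(g_knn)$weight <- dd
  forest <- igraph::mst(g_knn)
  fe <- igraph::as_edgelist(forest, names = TRUE)
  fi <- as.integer(fe[, 1]); fj <- as.integer(fe[, 2])
  fw <- igraph::E(forest)$weight
  ord <- order(fw)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in seq_along(ei)) {
    a <- find(ei[e]); b <- find(ej[e]); if (a != b) comp[a] <- b
  }
  add_i <- integer(0); add_j <- integer(0); add_w <- numeric(0)
  for (e in ord) {
    a <- find(fi[e]); b <- find(fj[e])
    if (connectivity_mode == "full_tree" || a != b) {
      add_i <- c(add_i, fi[e]); add_j <- c(add_j, fj[e]); add_w <- c(add_w, fw[e])
      if (a != b) comp[a] <- b
    }
  }
  # nearest-pair linking across any components the forest did not join
  roots <- vapply(seq_len(n), function(v) as.integer(find(v)), integer(1))
  while (length(unique(roots)) > 1) {
    cl <- split(seq_len(n), roots)
    a_set <- cl[[1]]
    best <- c(Inf, 0, 0)
    for (other in cl[-1]) {
      d2 <- .dist2(X[a_set, , drop = FALSE], X[other, , drop = FALSE])
      w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      if (d2[w[1], w[2]] < best[1])
        best <- c(d2[w[1], w[2]], a_set[w[1]], other[w[2]])
    }
    add_i <- c(add_i, as.integer(best[2])); add_j <- c(add_j, as.integer(best[3]))
    add_w <- c(add_w, sqrt(best[1]))
    comp[find(as.integer(best[2]))] <- find(as.integer(best[3]))
    roots <- vapply(seq_len(n), function(v) as.integer(find(v)), integer(1))
  }
  ei <- c(ei, add_i); ej <- c(ej, add_j); ew <- c(ew, add_w)
  g <- .make_graph(ei, ej, ew, n, "distance")
  # top up vertices below the minimum degree with their nearest candidates
  deg <- Matrix::colSums(g$adjacency != 0)
  low <- which(deg < k_eff)
  if (length(low)) {
    xi <- integer(0); xj <- integer(0); xw <- numeric(0)
    for (v in low) {
      have <- which(g$adjacency[, v] != 0)
      cand <- setdiff(nn$index[v, ], c(have, v))
      need <- k_eff - deg[v]
      if (need > 0 && length(cand)) {
        taken <- head(cand, need)
        xi <- c(xi, rep(v, length(taken))); xj <- c(xj, taken)
        xw <- c(xw, nn$dist[v, match(taken, nn$index[v, ])])
      }
    }
    if (length(xi)) {
      sm <- Matrix::summary(g$adjacency)
      up <- sm$i < sm$j
      g <- .make_graph(c(sm$i[up], xi), c(sm$j[up], xj), c(sm$x[up], xw),
                       n, "distance")
    }
  }
  g
}

#' Fuzzy simplicial set weighting of a distance graph
#'
#' Converts neighbor distances into locally adaptive membership strengths:
#' per vertex, `rho_i` is the distance to its nearest neighbor and `sigma_i`
#' is solved by binary search so that
#' `sum_j exp(-max(0, d_ij - rho_i) / sigma_i) = log2(k)`.
#' Directed weights `w_ij = exp(-max(0, d_ij - rho_i) / sigma_i)` are
#' symmetrized with the probabilistic t-conorm `w + w' - w w'`.
#'
#' @param distance_graph A connected `WeightedGraph` of distances.
#' @param k Neighborhood-size parameter of the calibration target.
#' @return A `WeightedGraph` of membership strengths in (0, 1], with the
#'   per-vertex `rho`, `sigma` and calibration residuals attached as
#'   attributes.
#' @export
fuzzy_simplicial_set <- function(distance_graph, k) {
  stopifnot(inherits(distance_graph, "WeightedGraph"))
  adj <- .general_adj(distance_graph$adjacency)
  n <- distance_graph$n
  target <- log2(k)
  sm <- Matrix::summary(adj)
  nbrs <- split(seq_len(nrow(sm)), sm$i)     # row-wise edge pointers
  if (length(nbrs) < n) stop("graph has isolated vertices")
  rho <- numeric(n); sigma <- numeric(n); resid <- numeric(n)
  w_dir <- numeric(nrow(sm))
  for (v in seq_len(n)) {
    ptr <- nbrs[[as.character(v)]]
    d <- sm$x[ptr]
    d[d < 1e-299] <- 0                       # undo the zero-edge sentinel
    rho[v] <- min(d)
    dd <- pmax(0, d - rho[v])
    f <- function(s) sum(exp(-dd / s))
    lo <- 1e-12; hi <- max(max(dd), 1e-6)
    while (f(hi) < target && hi < 1e12) hi <- hi * 2
    if (f(hi) < target) {                    # target unreachable: saturate
      sigma[v] <- hi
    } else {
      for (it in 1:64) {
        mid <- (lo + hi) / 2
        if (f(mid) < target) lo <- mid else hi <- mid
      }
      sigma[v] <- (lo + hi) / 2
    }
    resid[v] <- f(sigma[v]) - target
    w_dir[ptr] <- exp(-dd / sigma[v])
  }
  W <- Matrix::sparseMatrix(i = sm$i, j = sm$j, x = w_dir, dims = c(n, n))
  Wt <- Matrix::t(W)
  S <- W + Wt - W * Wt
  out <- structure(list(adjacency = Matrix::drop0(S), mode = "membership",
                        n = n), class = "WeightedGraph")
  attr(out, "rho") <- rho
  attr(out, "sigma") <- sigma
  attr(out, "residual") <- resid
  out
}

#' Constant Potts model quality of a partition
#'
#' `Q = sum_c [w_c - gamma * n_c (n_c - 1) / 2]` with `w_c` the total
#' internal edge weight of cluster `c`.
#'
#' @param graph A `WeightedGraph`.
#' @param membership Integer cluster ids, one per vertex.
#' @param gamma Resolution parameter.
#' @return Numeric quality value.
#' @export
cpm_quality <- function(graph, membership, gamma) {
  sm <- Matrix::summary(.general_adj(graph$adjacency))
  up <- sm$i < sm$j
  internal <- membership[sm$i[up]] == membership[sm$j[up]]
  w_int <- sum(sm$x[up][internal])
  sizes <- table(membership)
  w_int - gamma * sum(sizes * (sizes - 1) / 2)
}

#' CPM-Leiden microclustering
#'
#' Partitions a weighted graph by (near-)maximizing the constant Potts
#' model quality with the Leiden algorithm, run to convergence from
#' `n_restarts` seeded starts; the best-quality partition is returned.
#' The default resolution 0.0112 produces the fine microclusters used as
#' cross-validation groups downstream.
#'
#' @param graph A `WeightedGraph` (membership or distance weights).
#' @param gamma CPM resolution parameter (must be non-negative).
#' @param seed Integer seed; results are deterministic under it.
#' @param n_restarts Number of seeded Leiden starts.
#' @return A `Partition` list: `membership` (contiguous ids from 0),
#'   `resolution`, `quality`.
#' @export
leiden_cpm <- function(graph, gamma = 0.0112, seed = 1L, n_restarts = 10) {
  stopifnot(inherits(graph, "WeightedGraph"))
  if (gamma < 0) stop("gamma must be non-negative")
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                           weighted = TRUE)
  n <- graph$n
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(.derive_seed(seed, paste0("leiden", r)))
    # restart 1 from the default singleton start, later restarts from
    # random coarse partitions: diversified starts escape the rare local
    # optimum that needs a coordinated move-plus-merge to leave
    init <- if (r == 1) NULL else
      sample.int(max(2L, sample.int(max(2L, ceiling(n / 2)), 1)), n,
                 replace = TRUE)
    cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                                 resolution = gamma,
                                 weights = igraph::E(g)$weight,
                                 initial_membership = init,
                                 n_iterations = 10)
    memb <- .cpm_polish(graph, as.integer(igraph::membership(cl)), gamma)
    q <- cpm_quality(graph, memb, gamma)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  memb0 <- as.integer(factor(best)) - 1L
  structure(list(membership = memb0, resolution = gamma, quality = best_q),
            class = "Partition")
}

# Greedy CPM polish: single-vertex moves (to any neighboring cluster, an
# empty cluster, or any cluster on small graphs) and pairwise cluster
# merges, iterated to a local optimum.  Leiden's refinement occasionally
# stops short on small weighted graphs; this pass closes that gap.
.cpm_polish <- function(graph, memb, gamma, max_sweeps = 25) {
  n <- graph$n
  sm <- Matrix::summary(.general_adj(graph$adjacency))
  nb_idx <- split(sm$j, sm$i)
  nb_w <- split(sm$x, sm$i)
  memb <- as.integer(factor(memb))
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    sizes <- tabulate(memb, max(memb))
    for (v in seq_len(n)) {
      key <- as.character(v)
      nbs <- nb_idx[[key]]
      if (is.null(nbs)) next
      wts <- nb_w[[key]]
      w_to <- tapply(wts, memb[nbs], sum)
      cur <- memb[v]
      w_cur <- if (as.character(cur) %in% names(w_to)) w_to[[as.character(cur)]] else 0
      # quality change of leaving the current cluster
      leave <- -w_cur + gamma * (sizes[cur] - 1)
      cand <- as.integer(names(w_to))
      cand <- cand[cand != cur]
      gains <- if (length(cand))
        leave + vapply(cand, function(cc) w_to[[as.character(cc)]] -
                         gamma * sizes[cc], numeric(1)) else numeric(0)
      gain_single <- leave                    # move to a new singleton
      all_gains <- c(gains, gain_single)
      targets <- c(cand, max(memb) + 1L)
      bi <- which.max(all_gains)
      if (all_gains[bi] > 1e-12) {
        sizes[cur] <- sizes[cur] - 1L
        tgt <- targets[bi]
        if (tgt > length(sizes)) sizes <- c(sizes, 0L)
        sizes[tgt] <- sizes[tgt] + 1L
        memb[v] <- tgt
        changed <- TRUE
      }
    }
    # pairwise cluster merges
    memb <- as.integer(factor(memb))
    K <- max(memb)
    if (K > 1) {
      sizes <- tabulate(memb, K)
      up <- sm$i < sm$j
      ca <- memb[sm$i[up]]; cb <- memb[sm$j[up]]; w <- sm$x[up]
      cross <- ca != cb
      if (any(cross)) {
        lo <- pmin(ca[cross], cb[cross]); hi <- pmax(ca[cross], cb[cross])
        pair_w <- tapply(w[cross], paste(lo, hi), sum)
        for (p in names(sort(pair_w, decreasing = TRUE))) {
          ab <- as.integer(strsplit(p, " ")[[1]])
          gain <- pair_w[[p]] - gamma * sizes[ab[1]] * sizes[ab[2]]
          if (gain > 1e-12 && sizes[ab[1]] > 0 && sizes[ab[2]] > 0 &&
              ab[1] != ab[2]) {
            memb[memb == ab[2]] <- ab[1]
            sizes[ab[1]] <- sizes[ab[1]] + sizes[ab[2]]
            sizes[ab[2]] <- 0L
            changed <- TRUE
          }
        }
        memb <- as.integer(factor(memb))
      }
    }
    if (!changed) break
  }
  memb
}

#' CPM microclustering across multiplexed graph layers
#'
#' Optimizes the summed CPM quality of several graph layers sharing one
#' vertex set under a single membership.  Because CPM is linear in edge
#' weights, the multiplex optimum equals the single-layer optimum of the
#' weight-summed graph at resolution `gamma * n_layers`; this identity is
#' used directly.
#'
#' @param graphs List of `WeightedGraph`s over the same vertices.
#' @param gamma Per-layer CPM resolution.
#' @param seed,n_restarts Passed to [leiden_cpm()].
#' @return A `Partition`; its `quality` is the summed per-layer quality.
#' @export
leiden_cpm_multiplex <- function(graphs, gamma = 0.0112, seed = 1L,
                                 n_restarts = 10) {
  stopifnot(length(graphs) >= 1)
  n <- graphs[[1]]$n
  if (!all(vapply(graphs, function(g) as.numeric(g$n), numeric(1)) == n))
    stop("all layers must share one vertex set")
  total <- Reduce(`+`, lapply(graphs, function(g) .general_adj(g$adjacency)))
  summed <- structure(list(adjacency = total, mode = "membership", n = n),
                      class = "WeightedGraph")
  part <- leiden_cpm(summed, gamma = gamma * length(graphs), seed = seed,
                     n_restarts = n_restarts)
  part$quality <- sum(vapply(graphs, function(g)
    cpm_quality(g, part$membership, gamma), numeric(1)))
  part$resolution <- gamma
  part
}

#' Choose a clustering resolution by multi-resolution stability
#'
#' Scores each scanned resolution by the mean adjusted Rand index of its
#' partition against its resolution neighbors (a stability surrogate for
#' the adjusted multi-resolution Rand index).  The maximal-stability
#' resolution is chosen, unless a higher-quality partition lies within 0.05
#' of that maximum, in which case it is preferred; remaining ties go to the
#' lowest resolution.
#'
#' @param partitions Named list of `Partition`s, names = resolutions.
#' @return The chosen resolution (numeric).
#' @export
select_resolution <- function(partitions) {
  if (length(partitions) == 0) stop("no partitions supplied")
  res <- as.numeric(names(partitions))
  ord <- order(res)
  res <- res[ord]; partitions <- partitions[ord]
  m <- length(partitions)
  if (m == 1) return(res[1])
  stab <- vapply(seq_len(m), function(i) {
    nb <- c(i - 1, i + 1); nb <- nb[nb >= 1 & nb <= m]
    mean(vapply(nb, function(j)
      mclust::adjustedRandIndex(partitions[[i]]$membership,
                                partitions[[j]]$membership), numeric(1)))
  }, numeric(1))
  qual <- vapply(partitions, function(p) p$quality, numeric(1))
  cand <- which(stab >= max(stab) - 0.05)
  pick <- cand[order(-qual[cand], res[cand])][1]
  res[pick]
}

#' Cluster-level connectivity (partition-based graph abstraction)
#'
#' `c_ab` = observed inter-cluster edge weight over the weight expected when
#' edges are placed at random proportionally to cluster total degrees
#' (`deg_a * deg_b / (2W)`), clipped to `[0, 1]`; the diagonal is 0.
#'
#' @param graph A `WeightedGraph`.
#' @param membership Integer cluster ids per vertex.
#' @return Symmetric clusters-by-clusters matrix.
#' @export
paga_connectivity <- function(graph, membership) {
  membership <- as.integer(factor(membership))
  K <- max(membership)
  if (K == 1) return(matrix(0, 1, 1))
  sm <- Matrix::summary(.general_adj(graph$adjacency))
  up <- sm$i < sm$j
  ca <- membership[sm$i[up]]; cb <- membership[sm$j[up]]; w <- sm$x[up]
  W <- sum(w)
  deg <- vapply(seq_len(K), function(c)
    sum(Matrix::rowSums(graph$adjacency)[membership == c]), numeric(1))
  obs <- matrix(0, K, K)
  for (e in seq_along(w)) {
    if (ca[e] != cb[e]) {
      obs[ca[e], cb[e]] <- obs[ca[e], cb[e]] + w[e]
      obs[cb[e], ca[e]] <- obs[cb[e], ca[e]] + w[e]
    }
  }
  expd <- outer(deg, deg) / (2 * W)
  out <- obs / expd
  out[expd == 0] <- 0
  out[out > 1] <- 1
  diag(out) <- 0
  out
}

#' Project cluster labels onto a new embedding with linear SVMs
#'
#' Trains one-vs-rest linear-kernel SVMs (fit strength `C = 100`) on the
#' labeled embedding and assigns each target point the label with the
#' largest decision value.
#'
#' @param labeled_embedding Points-by-dims matrix with known labels.
#' @param labels Label vector (at least 2 classes for a real fit; a single
#'   class yields a constant prediction with a warning).
#' @param target_embedding Points to label.
#' @param cost SVM fit strength (default 100).
#' @return Character labels for the target points (subset of the training
#'   label set).
#' @export
project_microclusters <- function(labeled_embedding, labels,
                                  target_embedding, cost = 100) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  X <- as.matrix(labeled_embedding)
  Xt <- as.matrix(target_embedding)
  if (length(classes) < 2) {
    warning("single class: constant prediction")
    return(rep(classes[1], nrow(Xt)))
  }
  scores <- vapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "target", "other"),
                levels = c("target", "other"))
    fit <- e1071::svm(X, y, type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    dv <- attr(predict(fit, Xt, decision.values = TRUE), "decision.values")
    v <- dv[, 1]
    if (!grepl("^target/", colnames(dv)[1])) v <- -v
    v
  }, numeric(nrow(Xt)))
  classes[max.col(scores, ties.method = "first")]
}

#' Write a WeightedGraph as an edge-list TSV
#' @param graph A `WeightedGraph`.
#' @param path Output path; columns i, j, weight (i < j).
#' @return The path, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  sm <- Matrix::summary(graph$adjacency)
  up <- sm$i < sm$j
  write.table(data.frame(i = sm$i[up], j = sm$j[up], weight = sm$x[up]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
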