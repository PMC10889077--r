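# ---------------------------------------------------------------------------
# The walk-back core: pairwise regional x reference integration (soft
# k-means with per-cluster linear batch correction), anchor-gene rankings,
# robust rank aggregation into a shared functional-state signature, and
# signature subtraction with correlated-gene removal.
# ---------------------------------------------------------------------------

#' Soft k-means batch integration of an embedding
#'
#' Iterates (i) entropy-style soft k-means assignment with a batch-diversity
#' penalty that upweights clusters mixing batches, and (ii) per-cluster
#' ridge estimation of batch offsets which are subtracted from the
#' embedding.  Stops when the fraction of cells changing their argmax
#' cluster drops below `tol`, or after `max_iter` rounds (with a warning).
#'
#' @param Z Cells-by-dims numeric embedding.
#' @param batch Factor (or vector) of batch labels, one per cell.
#' @param k_clusters Number of soft clusters; default
#'   `max(5, round(sqrt(n)/10))`.  Must be at least 2.
#' @param ridge_lambda Ridge penalty on the per-cluster batch offsets.
#' @param theta_diversity Strength of the batch-diversity penalty.
#' @param max_iter,tol Iteration control (`tol` is the fraction of cells
#'   changing cluster).
#' @param seed Integer seed (k-means initialization).
#' @return List with `embedding` (corrected), `membership` (argmax cluster),
#'   `iterations` and `converged`.
#' @export
integrate_embedding <- function(Z, batch, k_clusters = NULL,
                                ridge_lambda = 1, theta_diversity = 1,
                                max_iter = 30, tol = 1e-3, seed = 1L) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  batch <- factor(batch)
  B <- nlevels(batch)
  if (is.null(k_clusters)) k_clusters <- max(5, round(sqrt(n) / 10))
  if (k_clusters < 2) stop("k_clusters must be at least 2")
  k <- min(k_clusters, n)
  pi_b <- as.numeric(table(batch)) / n
  Bmat <- vapply(levels(batch), function(l) as.numeric(batch == l),
                 numeric(n))                           # n x B indicator
  # global (cluster-independent) ridge-shrunk batch centering first; the
  # per-cluster loop below then only refines what a constant shift misses
  Zc <- Z
  gm <- colMeans(Zc)
  for (b in seq_len(B)) {
    in_b <- Bmat[, b] == 1
    delta <- colSums(Zc[in_b, , drop = FALSE] - matrix(gm, sum(in_b), ncol(Z), byrow = TRUE)) /
      (sum(in_b) + ridge_lambda)
    Zc[in_b, ] <- Zc[in_b, ] - matrix(delta, sum(in_b), ncol(Z), byrow = TRUE)
  }
  set.seed(seed)
  km <- kmeans(Zc, centers = k, nstart = 5, iter.max = 50)
  mu <- km$centers
  sigma2 <- max(mean(km$withinss / pmax(km$size, 1)), 1e-8)
  member_old <- km$cluster
  iterations <- 0L; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    d2 <- .dist2(Zc, mu)
    logit <- -d2 / sigma2
    if (iter > 1) {
      O <- crossprod(Bmat, Rsoft) + 1e-8               # B x k co-occurrence
      E <- outer(pi_b, colSums(Rsoft)) + 1e-8
      pen <- log(E / O)                                # upweights mixed clusters
      logit <- logit + theta_diversity * pen[as.integer(batch), , drop = FALSE]
    }
    logit <- logit - apply(logit, 1, max)
    Rsoft <- exp(logit)
    Rsoft <- Rsoft / rowSums(Rsoft)
    member <- max.col(Rsoft, ties.method = "first")
    wsum <- colSums(Rsoft)
    mu <- crossprod(Rsoft, Zc) / pmax(wsum, 1e-8)
    # per-cluster ridge batch offsets, subtracted from the embedding
    corr <- matrix(0, n, ncol(Z))
    for (c in seq_len(k)) {
      resid_c <- Zc - matrix(mu[c, ], n, ncol(Z), byrow = TRUE)
      w_c <- Rsoft[, c]
      for (b in seq_len(B)) {
        in_b <- Bmat[, b] == 1
        w_cb <- w_c[in_b]
        s <- sum(w_cb)
        if (s > 0) {
          delta <- colSums(resid_c[in_b, , drop = FALSE] * w_cb) / (s + ridge_lambda)
          corr[in_b, ] <- corr[in_b, ] + outer(w_cb, delta)
        }
      }
    }
    Zc <- Zc - corr
    changed <- mean(member != member_old)
    member_old <- member
    if (changed < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("integration did not converge after ", max_iter,
            " iterations; returning last iterate")
  list(embedding = Zc, membership = member_old,
       iterations = iterations, converged = converged)
}

#' Integrate one regional/reference dataset pair
#'
#' Jointly normalizes the shared genes of the pair to Pearson residuals,
#' computes a PCA embedding on the top anchor HVGs, corrects it for the
#' dataset (batch) effect with [integrate_embedding()], and extracts the
#' pair's anchor-gene ranking: all shared genes ordered by descending
#' residual variance on the concatenated pair, truncated to
#' `min(n_anchor_hvgs, n shared genes)`.
#'
#' @param regional,reference `ExpressionDataset`s (at least 50 shared genes).
#' @param n_anchor_hvgs Anchor ranking length cap (default 2000).
#' @param d Embedding dimensionality (default 30).
#' @param k_clusters,ridge_lambda,max_iter Passed to [integrate_embedding()].
#' @param theta Pearson-residual overdispersion.
#' @param seed Integer seed.
#' @return An `IntegrationPair` list: ids, corrected and uncorrected
#'   embeddings, batch vector, `anchor_ranking`, and convergence info.
#' @export
integrate_pair <- function(regional, reference, n_anchor_hvgs = 2000, d = 30,
                           k_clusters = NULL, ridge_lambda = 1,
                           max_iter = 30, theta = 100, seed = 1L) {
  shared <- intersect(regional$gene_table$gene_id, reference$gene_table$gene_id)
  if (length(shared) < 50) stop("fewer than 50 shared genes")
  pair_col <- list(subset_dataset(regional, genes = shared),
                   subset_dataset(reference, genes = shared))
  joint <- concat_datasets(pair_col, "intersection")
  joint <- pearson_residuals(joint, theta = theta)
  ranking <- select_hvgs(joint, n = min(n_anchor_hvgs, length(shared)))
  hvg_idx <- match(ranking, joint$gene_table$gene_id)
  emb0 <- .rsvd_scores(joint$norm_layer[, hvg_idx, drop = FALSE],
                       d = d, seed = seed)
  batch <- joint$cell_table$dataset_id
  fit <- integrate_embedding(emb0, batch, k_clusters = k_clusters,
                             ridge_lambda = ridge_lambda,
                             max_iter = max_iter, seed = seed)
  structure(list(regional_id = regional$cell_table$dataset_id[1],
                 reference_id = reference$cell_table$dataset_id[1],
                 embedding = fit$embedding, embedding_uncorrected = emb0,
                 batch = batch, anchor_ranking = ranking,
                 convergence = list(iterations = fit$iterations,
                                    converged = fit$converged)),
            class = "IntegrationPair")
}

#' Anchor-gene ranking of an integrated pair
#' @param pair An `IntegrationPair`.
#' @return Character vector of gene ids, most variable first.
#' @export
extract_anchor_ranking <- function(pair) {
  stopifnot(inherits(pair, "IntegrationPair"))
  pair$anchor_ranking
}

#' Robust rank aggregation of ranked gene lists
#'
#' Each list contributes a normalized rank `r = position / universe_size`
#' per gene; genes absent from a list get the worst rank 1.  With the `m`
#' normalized ranks of a gene in ascending order `r_(1) <= ... <= r_(m)`,
#' the score is `rho = min_k Beta(r_(k); k, m - k + 1)` -- the probability
#' that the k-th smallest of m independent uniforms is as small as
#' observed, minimized over k.  The reported `score` is the
#' Bonferroni-style `min(1, m * rho)`.
#'
#' @param ranked_lists List of character vectors (best gene first), over a
#'   shared universe.
#' @param universe Character vector of all gene ids (the normalization
#'   denominator is its length).
#' @param level Tag stored on the result (`"per_reference"` or `"global"`).
#' @return An `AggregatedSignature` data.frame (gene, rho, score, rank),
#'   sorted ascending by rho with ties broken by gene id.
#' @export
rra_score <- function(ranked_lists, universe, level = "global") {
  if (length(universe) == 0) stop("empty universe")
  m <- length(ranked_lists)
  if (m < 1) stop("need at least one ranked list")
  N <- length(universe)
  rmat <- matrix(1, N, m, dimnames = list(universe, NULL))
  for (j in seq_len(m)) {
    lst <- ranked_lists[[j]]
    idx <- match(lst, universe)
    keep <- !is.na(idx)
    rmat[idx[keep], j] <- which(keep) / N
  }
  rho <- vapply(seq_len(N), function(g) {
    r <- sort(rmat[g, ])
    min(pbeta(r, seq_len(m), m - seq_len(m) + 1))
  }, numeric(1))
  out <- data.frame(gene = universe, rho = rho,
                    score = pmin(1, m * rho), stringsAsFactors = FALSE)
  out <- out[order(out$rho, out$gene), , drop = FALSE]
  out$rank <- seq_len(N)
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("AggregatedSignature", class(out))
  out
}

#' Build the global shared functional-state signature
#'
#' Integrates every regional x reference pair, then aggregates anchor
#' rankings in two stages: per reference dataset, a robust rank aggregation
#' over that reference's regional-pair rankings; then a second aggregation
#' over the per-reference orderings into the global signature.  Genes near
#' the top of the global signature vary strongly in every pairing --
#' the shared (state-associated) programs to be walked back.
#'
#' @param collection A `DatasetCollection` with at least one regional and
#'   one reference dataset.
#' @param n_anchor_hvgs,d,theta,seed Passed to [integrate_pair()].
#' @param pairs Optional precomputed list of `IntegrationPair`s (overrides
#'   integration).
#' @return List with `global` (the `AggregatedSignature`), `per_reference`
#'   (list of per-reference signatures) and `pairs`.
#' @export
build_shared_signature <- function(collection, n_anchor_hvgs = 2000, d = 30,
                                   theta = 100, seed = 1L, pairs = NULL) {
  reg_idx <- regional_indices(collection)
  ref_idx <- reference_indices(collection)
  if (length(reg_idx) == 0 || length(ref_idx) == 0)
    stop("collection needs at least one regional and one reference dataset")
  universe <- Reduce(intersect,
                     lapply(collection$datasets, function(d) d$gene_table$gene_id))
  if (is.null(pairs)) {
    pairs <- list()
    for (j in ref_idx) for (i in reg_idx) {
      pairs[[length(pairs) + 1L]] <- integrate_pair(
        collection$datasets[[i]], collection$datasets[[j]],
        n_anchor_hvgs = n_anchor_hvgs, d = d, theta = theta,
        seed = .derive_seed(seed, paste0("pair", i, "_", j)))
    }
  }
  ref_ids <- vapply(pairs, function(p) p$reference_id, character(1))
  per_reference <- list()
  for (rid in unique(ref_ids)) {
    lists <- lapply(pairs[ref_ids == rid], extract_anchor_ranking)
    if (length(lists) == 0) { warning("reference ", rid, " has no pairs; excluded"); next }
    per_reference[[rid]] <- rra_score(lists, universe, level = "per_reference")
  }
  if (length(per_reference) == 0) stop("no reference with integrated pairs")
  global <- rra_score(lapply(per_reference, function(sig) sig$gene),
                      universe, level = "global")
  list(global = global, per_reference = per_reference, pairs = pairs)
}

#' Subtract a shared signature from a dataset
#'
#' Removes the top-`T` signature genes (the core) plus every remaining gene
#' whose absolute Pearson correlation with any core gene, computed on the
#' dataset's normalized layer, exceeds `corr_threshold`.  Returns the
#' reduced dataset ready for re-integration.
#'
#' @param dataset An `ExpressionDataset` (Pearson residuals are computed if
#'   no `norm_layer` is present).
#' @param signature An `AggregatedSignature` (or any data.frame with a
#'   `gene` column ordered best-first).
#' @param T Number of core genes to remove (0 removes nothing; must not
#'   exceed the signature length).  Typical choices: 100, 250, 500.
#' @param corr_threshold Absolute-correlation removal threshold (default 0.5).
#' @return A `SubtractionResult` list: `removed_core`, `removed_correlated`,
#'   `retained`, and `dataset` (the reduced dataset).
#' @export
subtract_signature <- function(dataset, signature, T = 100,
                               corr_threshold = 0.5) {
  genes <- dataset$gene_table$gene_id
  sig_genes <- signature$gene
  if (T > length(sig_genes)) stop("T exceeds the signature length")
  if (T == 0) {
    return(structure(list(removed_core = character(0),
                          removed_correlated = character(0),
                          retained = genes, dataset = dataset),
                     class = "SubtractionResult"))
  }
  core <- intersect(sig_genes[seq_len(T)], genes)
  if (is.null(dataset$norm_layer)) dataset <- pearson_residuals(dataset)
  R <- as.matrix(dataset$norm_layer)
  others <- setdiff(genes, core)
  removed_corr <- character(0)
  if (length(core) > 0 && length(others) > 0) {
    cc <- suppressWarnings(
      cor(R[, match(others, genes), drop = FALSE],
          R[, match(core, genes), drop = FALSE]))
    cc[is.na(cc)] <- 0
    removed_corr <- others[apply(abs(cc) > corr_threshold, 1, any)]
  }
  retained <- setdiff(genes, c(core, removed_corr))
  reduced <- subset_dataset(dataset, genes = retained)
  structure(list(removed_core = core, removed_correlated = removed_corr,
                 retained = retained, dataset = reduced),
            class = "SubtractionResult")
}

#' Write an aggregated signature as TSV
#' @param signature An `AggregatedSignature`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_signature <- function(signature, path) {
  write.table(as.data.frame(signature)[, c("gene", "rho", "score", "rank")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
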