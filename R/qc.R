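# ---------------------------------------------------------------------------
# Per-cell QC metrics, mitochondrial mixture-model filtering, doublet
# scoring, gene-set scoring, over-representation analysis, marker-panel cell
# selection and the train/test split rule.
# ---------------------------------------------------------------------------

#' Compute per-cell QC metrics
#'
#' Appends `n_umi`, `n_genes_detected`, `pct_mito`, `pct_ribo`,
#' `pct_hemoglobin` (percent units) and `complexity =
#' log10(genes)/log10(UMI)` to the cell table.  Cells with zero UMI are
#' dropped (with a logged count) before metric computation; complexity is
#' `NA` for cells with fewer than 2 UMI.
#'
#' @param dataset An `ExpressionDataset` with gene flags present.
#' @return The dataset with QC columns appended to `cell_table`.
#' @export
compute_qc_metrics <- function(dataset) {
  validate_dataset(dataset)
  n_umi <- Matrix::rowSums(dataset$counts)
  dropped <- sum(n_umi == 0)
  if (dropped > 0) {
    message("compute_qc_metrics: dropping ", dropped, " cells with zero UMI")
    dataset <- subset_dataset(dataset, cells = n_umi > 0)
    n_umi <- n_umi[n_umi > 0]
    if (nrow(dataset$counts) == 0) {
      warning("all cells had zero UMI; returning empty dataset")
      return(add_provenance(dataset, "compute_qc_metrics",
                            list(dropped_zero_umi = dropped)))
    }
  }
  gt <- dataset$gene_table
  if (!any(gt$is_mito) && !any(gt$is_ribo) && !any(gt$is_hemoglobin))
    warning("no mito/ribo/hemoglobin flagged genes; percentages will be 0")
  pct <- function(flag) {
    if (!any(flag)) return(rep(0, nrow(dataset$counts)))
    100 * Matrix::rowSums(dataset$counts[, flag, drop = FALSE]) / n_umi
  }
  n_det <- Matrix::rowSums(dataset$counts > 0)
  ct <- dataset$cell_table
  ct$n_umi <- n_umi
  ct$n_genes_detected <- n_det
  ct$pct_mito <- pct(gt$is_mito)
  ct$pct_ribo <- pct(gt$is_ribo)
  ct$pct_hemoglobin <- pct(gt$is_hemoglobin)
  ct$complexity <- ifelse(n_umi >= 2 & n_det >= 1,
                          log10(n_det) / log10(n_umi), NA_real_)
  dataset$cell_table <- ct
  add_provenance(dataset, "compute_qc_metrics", list(dropped_zero_umi = dropped))
}

#' Mixture-model filter on mitochondrial content
#'
#' Fits a two-component linear-regression mixture
#' `pct_mito = a_k + b_k * covariate + eps_k` by EM.  The component with the
#' larger intercept is labeled "compromised" (dying cells leak cytoplasmic
#' RNA, inflating the mitochondrial fraction at a given gene-detection
#' level); cells whose posterior probability of belonging to it reaches
#' `posterior_cutoff` are removed.  With `spline = TRUE` the linear term is
#' replaced by a natural cubic spline basis (3 df) on the covariate.
#'
#' @param qc_table Cell table containing `pct_mito` and the covariate column.
#' @param covariate Name of the covariate column (default `n_genes_detected`).
#' @param posterior_cutoff Keep cells with posterior(compromised) strictly
#'   below this value (1.0 keeps everything).
#' @param spline Use a natural-cubic-spline basis (3 df) instead of a line.
#' @param max_iter,tol EM iteration control.
#' @return List with `keep` (logical mask), `posterior` (compromised-component
#'   posterior per cell), `fit` (component coefficients, sigmas, mixing
#'   weights) and `converged`.
#' @export
fit_mito_mixture <- function(qc_table, covariate = "n_genes_detected",
                             posterior_cutoff = 0.95, spline = FALSE,
                             max_iter = 200, tol = 1e-6) {
  y <- qc_table$pct_mito
  x <- qc_table[[covariate]]
  n <- length(y)
  if (n < 50) stop("fit_mito_mixture needs at least 50 cells")
  if (var(y) < 1e-12) {
    return(list(keep = rep(TRUE, n), posterior = rep(0, n),
                fit = NULL, converged = TRUE))
  }
  X <- if (spline) cbind(1, splines::ns(x, df = 3)) else cbind(1, x)
  fit0 <- lm.fit(X, y)
  res <- fit0$residuals
  assign_hi <- res > 0 & res >= quantile(res, 0.5)
  post <- cbind(ifelse(assign_hi, 0.1, 0.9), ifelse(assign_hi, 0.9, 0.1))
  beta <- matrix(0, ncol(X), 2); sigma <- c(1, 1); pi_k <- c(0.5, 0.5)
  loglik_old <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    for (k in 1:2) {
      w <- pmax(post[, k], 1e-10)
      wf <- lm.wfit(X, y, w)
      beta[, k] <- wf$coefficients
      sigma[k] <- sqrt(max(sum(w * wf$residuals^2) / sum(w), 1e-8))
      pi_k[k] <- mean(post[, k])
    }
    dens <- vapply(1:2, function(k)
      pi_k[k] * stats::dnorm(y, X %*% beta[, k], sigma[k]), numeric(n))
    tot <- pmax(rowSums(dens), 1e-300)
    post <- dens / tot
    loglik <- sum(log(tot))
    if (abs(loglik - loglik_old) < tol * (1 + abs(loglik))) { converged <- TRUE; break }
    loglik_old <- loglik
  }
  if (!converged) {
    warning("mito mixture EM did not converge; keeping all cells")
    return(list(keep = rep(TRUE, n), posterior = rep(0, n),
                fit = NULL, converged = FALSE))
  }
  # compromised component: larger intercept (larger mean fit for splines)
  comp <- if (spline) which.max(colMeans(X %*% beta)) else which.max(beta[1, ])
  p_comp <- post[, comp]
  # a cutoff of 1 keeps everything even where the posterior saturates at 1
  keep <- if (posterior_cutoff >= 1) rep(TRUE, n) else p_comp < posterior_cutoff
  list(keep = keep, posterior = p_comp,
       fit = list(beta = beta, sigma = sigma, pi = pi_k,
                  compromised = comp, spline = spline),
       converged = TRUE)
}

#' Score cells for doublet likelihood with simulated doublets
#'
#' Simulates synthetic doublets by summing the counts of random cell pairs,
#' embeds real and simulated cells jointly by PCA of log-normalized counts,
#' and scores each real cell by the fraction of simulated doublets among its
#' `k_nn` nearest neighbors.  The raw fraction is converted to a posterior-
#' style score `(f/rho) / (f/rho + (1-f)/(1-rho))` with `rho` the simulated
#' fraction of the joint set, so scores are comparable across simulation
#' sizes.  Calls are the top `expected_rate` fraction of cells by score.
#'
#' @param dataset An `ExpressionDataset` with at least 2 cells.
#' @param expected_rate Expected doublet rate in `[0, 1)`.
#' @param k_nn Neighborhood size.
#' @param seed Integer seed (pair sampling and the randomized PCA).
#' @param n_sim Number of simulated doublets (default: one per real cell).
#' @param n_pcs Embedding dimensionality.
#' @return List with `score` (per cell, in `[0, 1]`) and `call` (logical).
#' @export
doublet_score <- function(dataset, expected_rate = 0.05, k_nn = 30, seed = 1L,
                          n_sim = NULL, n_pcs = 30) {
  validate_dataset(dataset)
  n <- nrow(dataset$counts)
  if (n < 2) stop("doublet_score needs at least 2 cells")
  if (expected_rate < 0 || expected_rate >= 1)
    stop("expected_rate must be in [0, 1)")
  if (is.null(n_sim)) n_sim <- n
  set.seed(seed)
  i1 <- sample.int(n, n_sim, replace = TRUE)
  i2 <- sample.int(n, n_sim, replace = TRUE)
  clash <- i1 == i2
  while (any(clash)) {
    i2[clash] <- sample.int(n, sum(clash), replace = TRUE)
    clash <- i1 == i2
  }
  sim <- dataset$counts[i1, , drop = FALSE] + dataset$counts[i2, , drop = FALSE]
  joint <- rbind(dataset$counts, sim)
  lib <- Matrix::rowSums(joint)
  lib[lib == 0] <- 1
  norm <- log1p(joint / lib * stats::median(lib))
  emb <- .rsvd_scores(as.matrix(norm), d = min(n_pcs, ncol(norm) - 1L, n - 1L),
                      seed = seed + 1L)
  k <- min(k_nn, n + n_sim - 1L)
  nn <- .knn_index(emb, k)$index
  is_sim <- c(rep(FALSE, n), rep(TRUE, n_sim))
  f <- rowMeans(matrix(is_sim[nn[seq_len(n), , drop = FALSE]], n, k))
  rho <- n_sim / (n + n_sim - 1)
  score <- (f / rho) / (f / rho + (1 - f) / (1 - rho))
  n_call <- round(expected_rate * n)
  call <- rep(FALSE, n)
  if (n_call > 0) call[order(score, decreasing = TRUE)[seq_len(n_call)]] <- TRUE
  list(score = score, call = call)
}

#' Score a gene set against expression-matched controls
#'
#' The per-cell score is the mean normalized expression of the set minus the
#' mean of control genes drawn from expression-matched bins (genes are
#' binned by mean expression into `n_bins` bins; `n_ctrl` controls are drawn
#' per set gene from the same bin).  Used e.g. for cell-cycle program
#' scoring.
#'
#' @param dataset An `ExpressionDataset`; uses `norm_layer` when present,
#'   otherwise log1p library-size-normalized counts.
#' @param gene_set Character vector of gene ids.
#' @param n_bins,n_ctrl Binning and control-draw parameters.
#' @param seed Seed for the control draws.
#' @return Numeric per-cell score.
#' @export
score_gene_set <- function(dataset, gene_set, n_bins = 25, n_ctrl = 50,
                           seed = 1L) {
  if (length(gene_set) == 0) stop("empty gene set")
  gidx <- match(gene_set, dataset$gene_table$gene_id)
  gidx <- gidx[!is.na(gidx)]
  if (length(gidx) == 0) stop("no gene-set genes found in the gene universe")
  X <- if (!is.null(dataset$norm_layer)) dataset$norm_layer else {
    lib <- Matrix::rowSums(dataset$counts)
    lib[lib == 0] <- 1
    as.matrix(log1p(dataset$counts / lib * stats::median(lib)))
  }
  X <- as.matrix(X)
  gmeans <- colMeans(X)
  bins <- cut(rank(gmeans, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  set.seed(seed)
  ctrl <- unlist(lapply(gidx, function(g) {
    pool <- setdiff(which(bins == bins[g]), gidx)
    if (length(pool) == 0) pool <- setdiff(seq_along(bins), gidx)
    pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
  }))
  rowMeans(X[, gidx, drop = FALSE]) - rowMeans(X[, ctrl, drop = FALSE])
}

#' Over-representation analysis by hypergeometric test
#'
#' @param query_genes Character vector, must lie inside `universe`.
#' @param reference_sets Named list of character vectors.
#' @param universe Character vector defining the gene universe.
#' @return `data.frame` with per-set overlap, hypergeometric upper-tail
#'   p-value and BH-adjusted FDR.
#' @export
ora_enrichment <- function(query_genes, reference_sets, universe) {
  if (!all(query_genes %in% universe))
    stop("query genes must be a subset of the universe")
  N <- length(universe); n <- length(unique(query_genes))
  res <- lapply(names(reference_sets), function(nm) {
    ref <- intersect(reference_sets[[nm]], universe)
    if (length(reference_sets[[nm]]) > N)
      stop("reference set '", nm, "' larger than the universe")
    K <- length(ref)
    k <- length(intersect(query_genes, ref))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Construct a marker panel
#'
#' A panel of inclusion markers (cell-type positive markers; 22 by default in
#' the shipped example panels) and exclusion markers (markers of other major
#' cell types; 59 by default).  A cell passes when it detects at least
#' `min_inclusion` inclusion genes and at most `max_exclusion` exclusion
#' genes ("detected" means raw count > 0).
#'
#' @param inclusion_genes,exclusion_genes Character vectors (disjoint).
#' @param min_inclusion,max_exclusion Integer thresholds.
#' @return A `MarkerPanel`.
#' @export
marker_panel <- function(inclusion_genes, exclusion_genes,
                         min_inclusion = 7, max_exclusion = 2) {
  if (length(intersect(inclusion_genes, exclusion_genes)) > 0)
    stop("inclusion and exclusion lists must be disjoint")
  if (min_inclusion > length(inclusion_genes))
    stop("min_inclusion exceeds inclusion list length")
  if (max_exclusion > length(exclusion_genes))
    stop("max_exclusion exceeds exclusion list length")
  structure(list(inclusion_genes = inclusion_genes,
                 exclusion_genes = exclusion_genes,
                 min_inclusion = min_inclusion,
                 max_exclusion = max_exclusion),
            class = "MarkerPanel")
}

#' Read a marker panel from one-gene-per-line text files
#'
#' @param inclusion_path,exclusion_path Paths to plain-text gene lists.
#' @param min_inclusion,max_exclusion Thresholds, see [marker_panel()].
#' @return A `MarkerPanel`.
#' @export
read_marker_panel <- function(inclusion_path, exclusion_path,
                              min_inclusion = 7, max_exclusion = 2) {
  inc <- readLines(inclusion_path)
  exc <- readLines(exclusion_path)
  marker_panel(inc[nzchar(inc)], exc[nzchar(exc)],
               min_inclusion, max_exclusion)
}

#' Select cells by marker panel
#'
#' @param dataset An `ExpressionDataset`.
#' @param panel A `MarkerPanel`.
#' @return Logical mask over cells: `TRUE` iff the cell detects at least
#'   `min_inclusion` inclusion genes and at most `max_exclusion` exclusion
#'   genes.
#' @export
select_astrocytes <- function(dataset, panel) {
  stopifnot(inherits(panel, "MarkerPanel"))
  universe <- dataset$gene_table$gene_id
  inc <- match(panel$inclusion_genes, universe)
  exc <- match(panel$exclusion_genes, universe)
  n_panel <- length(inc) + length(exc)
  n_missing <- sum(is.na(inc)) + sum(is.na(exc))
  if (n_missing > 0)
    message("select_astrocytes: ", n_missing, "/", n_panel,
            " panel genes missing from the gene universe")
  if (n_missing > n_panel / 2)
    stop("more than 50% of panel genes missing from the gene universe")
  det_inc <- Matrix::rowSums(dataset$counts[, inc[!is.na(inc)], drop = FALSE] > 0)
  det_exc <- Matrix::rowSums(dataset$counts[, exc[!is.na(exc)], drop = FALSE] > 0)
  unname(det_inc >= panel$min_inclusion & det_exc <= panel$max_exclusion)
}

#' Split cells into train and test sets
#'
#' Each cell enters the training set independently with probability
#' `p = min(1, max(0.9, 1000/N))`: 90% by default, inflated for small
#' datasets so that training sets keep roughly 1,000 cells.  For `N <= 1000`
#' the rule yields `p = 1` and the test set is empty (with a loud warning).
#'
#' @param dataset An `ExpressionDataset`, or an integer cell count.
#' @param seed Integer seed.
#' @return List of logical masks `train` and `test` (disjoint, exhaustive).
#' @export
train_test_split <- function(dataset, seed = 1L) {
  N <- if (inherits(dataset, "ExpressionDataset")) nrow(dataset$counts)
       else as.integer(dataset)
  if (N < 1) stop("need at least one cell")
  p <- min(1, max(0.9, 1000 / N))
  set.seed(seed)
  train <- runif(N) < p
  if (all(train) || p >= 1) {
    if (p >= 1) {
      train <- rep(TRUE, N)
      warning("train probability reached 1 (N = ", N,
              "); test set is empty")
    }
  }
  list(train = train, test = !train)
}
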