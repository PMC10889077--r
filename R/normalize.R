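# ---------------------------------------------------------------------------
# Analytic Pearson-residual normalization, highly variable gene selection,
# covariate regression and a permutation test for significant PCs.
# ---------------------------------------------------------------------------

#' Analytic Pearson residuals
#'
#' Normalizes counts to residuals under a negative-binomial null with fixed
#' overdispersion:
#' `r_cg = (x_cg - mu_cg) / sqrt(mu_cg + mu_cg^2 / theta)` with
#' `mu_cg = n_c * g_g / T` (cell total times gene total over grand total).
#' Residuals are clipped to `±sqrt(n_cells)` (the analytic-residual
#' convention); all-zero genes get residual 0 rather than NaN.
#'
#' @param dataset An `ExpressionDataset`.
#' @param theta Overdispersion parameter of the null (default 100).
#' @param clip Clipping bound; default `sqrt(n_cells)`.
#' @return The dataset with `norm_layer` set to the residual matrix.
#' @export
pearson_residuals <- function(dataset, theta = 100, clip = NULL) {
  stopifnot(theta > 0)
  X <- as.matrix(dataset$counts)
  n <- nrow(X)
  if (is.null(clip)) clip <- sqrt(n)
  stopifnot(clip > 0)
  n_c <- rowSums(X)
  g_g <- colSums(X)
  total <- sum(n_c)
  if (total == 0) {
    dataset$norm_layer <- matrix(0, n, ncol(X))
    return(add_provenance(dataset, "pearson_residuals", list(theta = theta)))
  }
  mu <- outer(n_c, g_g) / total
  denom <- sqrt(mu + mu^2 / theta)
  r <- (X - mu) / denom
  r[denom == 0] <- 0
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  dimnames(r) <- dimnames(dataset$counts)
  dataset$norm_layer <- r
  add_provenance(dataset, "pearson_residuals",
                 list(theta = theta, clip = clip))
}

#' Select highly variable genes by residual variance
#'
#' Ranks genes by the variance of their Pearson residuals, descending, with
#' ties broken by lexical gene id so the ordering is stable across runs.
#'
#' @param dataset An `ExpressionDataset` with `norm_layer` computed, or a
#'   plain residual matrix with gene-id column names.
#' @param n Number of genes to return (default 3000, capped at the universe
#'   size with a warning).
#' @return Character vector of gene ids, most variable first.
#' @export
select_hvgs <- function(dataset, n = 3000) {
  R <- if (inherits(dataset, "ExpressionDataset")) {
    if (is.null(dataset$norm_layer)) stop("norm_layer missing; run pearson_residuals first")
    dataset$norm_layer
  } else dataset
  R <- as.matrix(R)
  gene_ids <- colnames(R)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(ncol(R)))
  v <- apply(R, 2, var)
  if (n > length(v)) {
    warning("n exceeds the gene universe; returning all genes")
    n <- length(v)
  }
  ord <- order(-v, gene_ids)
  gene_ids[ord][seq_len(n)]
}

#' Regress covariates out of a residual matrix
#'
#' Per-gene ordinary least squares on the supplied covariates (plus an
#' intercept); returns the fit residuals.  Collinear covariate columns are
#' dropped with a warning.
#'
#' @param residuals Cells-by-genes numeric matrix.
#' @param covariates Numeric vector, matrix or data.frame with one row per
#'   cell (e.g. complexity, cell-cycle scores).
#' @return Adjusted residual matrix, orthogonal to the design columns.
#' @export
regress_covariates <- function(residuals, covariates) {
  R <- as.matrix(residuals)
  C <- as.matrix(covariates)
  stopifnot(nrow(C) == nrow(R))
  X <- cbind(intercept = 1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping ", ncol(X) - qrX$rank, " collinear design column(s)")
    qrX <- qr(X[, keep, drop = FALSE])
  }
  out <- qr.resid(qrX, R)
  dimnames(out) <- dimnames(R)
  out
}

#' Permutation test for significant principal components
#'
#' Draws `n_samples` random row-subsamples of size `frac * N`; for each,
#' compares the subsample's per-PC explained-variance proportions against
#' those of column-permuted copies (which destroy all inter-gene
#' correlation).  A PC is retained when the empirical probability of the
#' permuted explained variance reaching the observed one is below `alpha`.
#' The total number of permutation draws is `n_iter` (spread over the
#' subsamples).
#'
#' @param X Cells-by-genes numeric matrix (at least 50 rows).
#' @param n_samples Number of row-subsamples (default 100).
#' @param frac Subsample fraction (default 0.02).
#' @param n_iter Total permutation draws (default 1000).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param max_pcs Largest PC index tested.
#' @return Integer vector of retained PC indices (possibly empty).
#' @export
significant_pcs <- function(X, n_samples = 100, frac = 0.02, n_iter = 1000,
                            alpha = 0.05, seed = 1L, max_pcs = 20) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 50) stop("significant_pcs needs at least 50 cells")
  m <- ceiling(frac * N)
  if (m < 3) stop("frac * N < 3; increase frac or the sample size")
  perms_per_sample <- max(1L, ceiling(n_iter / n_samples))
  K <- min(m - 1L, ncol(X), max_pcs)
  set.seed(seed)
  hits <- numeric(K); draws <- 0L
  ev_prop <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    d2 <- svd(M, nu = 0, nv = 0)$d^2
    (d2 / sum(d2))[seq_len(K)]
  }
  for (s in seq_len(n_samples)) {
    rows <- sample.int(N, m)
    sub <- X[rows, , drop = FALSE]
    obs <- ev_prop(sub)
    for (t in seq_len(perms_per_sample)) {
      perm <- apply(sub, 2, sample)
      hits <- hits + as.numeric(ev_prop(perm) >= obs)
      draws <- draws + 1L
    }
  }
  p <- hits / draws
  which(p < alpha)
}
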