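# ---------------------------------------------------------------------------
# Evaluation metrics and statistical machinery: multiclass MCC (Gorodkin
# form) and weighted F, the corrected resampled t-test and its Bayesian
# analogue, marker and hurdle differential-expression tests, DEG rank
# aggregation, and the 2x2 contingency chi-square.
# ---------------------------------------------------------------------------

#' Classification metrics report
#'
#' Computes the confusion matrix, the multiclass Matthews correlation
#' coefficient in its confusion-matrix (Gorodkin) generalization, the
#' support-weighted F-measure, and per-class precision/recall.  The
#' zero-denominator convention for MCC is 0 (e.g. a constant predictor).
#'
#' @param y_true,y_pred Equal-length label vectors (non-empty).
#' @return An `EvaluationReport` list: `confusion`, `mcc`, `weighted_f`,
#'   `per_class` (precision/recall/F1/support), `n`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(as.character(y_true), levels = lev)
  yp <- factor(as.character(y_pred), levels = lev)
  cm <- table(true = yt, pred = yp)
  s <- sum(cm)
  c_diag <- sum(diag(cm))
  t_k <- rowSums(cm)                 # true-class supports
  p_k <- colSums(cm)                 # predicted-class totals
  num <- c_diag * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den
  prec <- ifelse(p_k > 0, diag(cm) / p_k, 0)
  rec <- ifelse(t_k > 0, diag(cm) / t_k, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wf <- if (s > 0) sum(f1 * t_k) / s else 0
  structure(list(confusion = cm, mcc = mcc, weighted_f = wf,
                 per_class = data.frame(class = lev, precision = as.numeric(prec),
                                        recall = as.numeric(rec),
                                        f1 = as.numeric(f1),
                                        support = as.numeric(t_k)),
                 n = s),
            class = "EvaluationReport")
}

#' Corrected resampled t-test for classifier comparison
#'
#' Paired t-test on per-fold score differences with the resampling variance
#' correction: `t = mean(d) / sqrt((1/J + n_test/n_train) * var(d))`,
#' `df = J - 1`.  The correction inflates the naive variance to account for
#' the overlap between training sets of different folds; with `n_test = 0`
#' it reduces exactly to the standard paired t statistic.  The p-value is
#' right-tailed (null: the second model performs at least as well).
#'
#' @param diffs Per-fold score differences (model1 - model2), length J >= 2.
#' @param n_train,n_test Per-fold training and test sizes.
#' @return A list: `t`, `df`, `p_value`, `mean_diff`, `var_diff`,
#'   `correction` (the variance multiplier), `degenerate` flag.
#' @export
corrected_t_test <- function(diffs, n_train, n_test) {
  J <- length(diffs)
  if (J < 2) stop("need at least 2 fold differences")
  if (n_train <= 0) stop("n_train must be positive")
  dbar <- mean(diffs)
  s2 <- var(diffs)
  mult <- 1 / J + n_test / n_train
  degenerate <- FALSE
  if (s2 == 0) {
    if (dbar == 0) t_stat <- 0
    else { t_stat <- sign(dbar) * Inf; degenerate <- TRUE }
  } else t_stat <- dbar / sqrt(mult * s2)
  p <- pt(t_stat, df = J - 1, lower.tail = FALSE)
  list(t = t_stat, df = J - 1, p_value = p, mean_diff = dbar,
       var_diff = s2, correction = mult, degenerate = degenerate)
}

#' Bayesian comparison of two classifiers over CV folds
#'
#' Under a normal-gamma prior conjugate to a normal likelihood, the
#' marginal posterior of the mean score difference is Student-t with
#' `df = J - 1`, location `mean(d)` and scale
#' `sqrt((1/J + n_test/n_train) * var(d))` (the same corrected variance as
#' the frequentist test).  Reports the posterior probabilities that the
#' first model is better, worse, or practically equivalent within the
#' region of practical equivalence `[-rope, rope]`.
#'
#' @param diffs Per-fold score differences, length J >= 2.
#' @param n_train,n_test Per-fold training and test sizes.
#' @param rope Half-width of the region of practical equivalence
#'   (non-negative; default 0.01 on the MCC scale).
#' @return A list with `p_better`, `p_worse`, `p_rope` (summing to 1),
#'   `location`, `scale`, `df`.
#' @export
bayes_compare <- function(diffs, n_train, n_test, rope = 0.01) {
  if (rope < 0) stop("rope must be non-negative")
  J <- length(diffs)
  if (J < 2) stop("need at least 2 fold differences")
  dbar <- mean(diffs)
  scale <- sqrt((1 / J + n_test / n_train) * var(diffs))
  df <- J - 1
  if (scale == 0) {
    p_better <- as.numeric(dbar > rope)
    p_worse <- as.numeric(dbar < -rope)
    p_rope <- 1 - p_better - p_worse
  } else {
    p_worse <- pt((-rope - dbar) / scale, df)
    p_better <- pt((rope - dbar) / scale, df, lower.tail = FALSE)
    p_rope <- 1 - p_better - p_worse
  }
  list(p_better = p_better, p_worse = p_worse, p_rope = p_rope,
       location = dbar, scale = scale, df = df)
}

# logistic log-likelihood helper for the marker LR test
.logistic_lrt <- function(x, yb) {
  n1 <- sum(yb); n <- length(yb)
  p0 <- n1 / n
  ll0 <- n1 * log(max(p0, 1e-300)) + (n - n1) * log(max(1 - p0, 1e-300))
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), yb,
                                         family = stats::binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 25)
  if (separated) {
    # mild data augmentation stabilizes complete separation
    xa <- c(x, mean(x), mean(x)); ya <- c(yb, 0, 1)
    w <- c(rep(1, n), 0.5, 0.5)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, xa), ya, weights = w,
                                           family = stats::binomial()))
  }
  ll1 <- -fit$deviance / 2
  list(lr = max(0, 2 * (ll1 - ll0)), separated = separated)
}

#' Marker genes by logistic-regression likelihood-ratio test
#'
#' For every cluster and gene, tests cluster membership ~ gene expression
#' against the intercept-only model; BH correction is applied per cluster
#' and genes with FDR below `fdr_threshold` are flagged as markers.
#' Complete separation triggers a stabilized refit (flagged in the output).
#'
#' @param norm_matrix Cells-by-genes normalized expression matrix.
#' @param cluster_labels Cluster label per cell (at least 2 clusters).
#' @param fdr_threshold Marker FDR cutoff (default 0.001).
#' @return `data.frame` with gene, cluster, lr, p_value, fdr, marker,
#'   separated.
#' @export
logreg_markers <- function(norm_matrix, cluster_labels, fdr_threshold = 0.001) {
  M <- as.matrix(norm_matrix)
  cl <- factor(cluster_labels)
  if (nlevels(cl) < 2) stop("need at least 2 clusters")
  genes <- colnames(M)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(ncol(M)))
  out <- list()
  for (k in levels(cl)) {
    yb <- as.numeric(cl == k)
    res <- lapply(seq_len(ncol(M)), function(g) .logistic_lrt(M[, g], yb))
    lr <- vapply(res, `[[`, numeric(1), "lr")
    sep <- vapply(res, `[[`, logical(1), "separated")
    p <- pchisq(lr, df = 1, lower.tail = FALSE)
    out[[k]] <- data.frame(gene = genes, cluster = k, lr = lr, p_value = p,
                           fdr = p.adjust(p, "BH"), separated = sep,
                           stringsAsFactors = FALSE)
    out[[k]]$marker <- out[[k]]$fdr < fdr_threshold
  }
  do.call(rbind, out)
}

#' Two-part (hurdle) differential expression test
#'
#' Combines a logistic detection component (gene detected yes/no ~ group;
#' a 2x2 likelihood-ratio G-test) with a Gaussian component on the values
#' of detected cells; the combined statistic is their sum, referred to a
#' chi-square with 2 degrees of freedom.  The log2 fold change is the
#' difference of group means on the supplied log-normalized values
#' (pseudocount-1 convention).
#'
#' @param norm_matrix Cells-by-genes log-normalized matrix.
#' @param group_labels Two-group label vector (each group >= 3 cells).
#' @param covariates Optional per-cell covariate vector/matrix (e.g. the
#'   cellular detection rate) adjusted for in both model parts; the default
#'   NULL gives the plain two-part test.
#' @return `data.frame` with gene, stat_detection, stat_continuous, stat
#'   (their sum), p_value, log2fc, excluded flag (genes undetected in all
#'   cells are excluded from testing).
#' @export
hurdle_test <- function(norm_matrix, group_labels, covariates = NULL) {
  M <- as.matrix(norm_matrix)
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 3)) stop("each group needs at least 3 cells")
  genes <- colnames(M)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(ncol(M)))
  g1 <- g == levels(g)[1]
  CV <- if (is.null(covariates)) NULL else as.matrix(covariates)
  res <- lapply(seq_len(ncol(M)), function(j) {
    x <- M[, j]
    det <- x > 0
    if (!any(det))
      return(data.frame(gene = genes[j], stat_detection = NA, stat_continuous = NA,
                        stat = NA, p_value = NA, log2fc = NA, excluded = TRUE))
    if (is.null(CV)) {
      # detection part: G-test on the 2x2 detected-by-group table
      tab <- table(factor(det, levels = c(FALSE, TRUE)), g)
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      nz <- tab > 0
      s_det <- 2 * sum(tab[nz] * log(tab[nz] / expd[nz]))
    } else {
      f0 <- suppressWarnings(stats::glm.fit(cbind(1, CV), as.numeric(det),
                                            family = stats::binomial()))
      f1 <- suppressWarnings(stats::glm.fit(cbind(1, CV, g1), as.numeric(det),
                                            family = stats::binomial()))
      s_det <- max(0, f0$deviance - f1$deviance)
    }
    # continuous part: Gaussian LR on detected values
    s_cont <- 0
    xd <- x[det]; gd <- g[det]
    if (length(unique(gd)) == 2 && length(xd) >= 4) {
      if (is.null(CV)) {
        rss1 <- sum(tapply(xd, gd, function(v) sum((v - mean(v))^2)))
        rss0 <- sum((xd - mean(xd))^2)
      } else {
        cvd <- CV[det, , drop = FALSE]
        rss0 <- sum(qr.resid(qr(cbind(1, cvd)), xd)^2)
        rss1 <- sum(qr.resid(qr(cbind(1, cvd, gd == levels(g)[1])), xd)^2)
      }
      if (rss1 > 0) s_cont <- length(xd) * log(rss0 / rss1)
      else if (rss0 > 0) s_cont <- Inf
    }
    stat <- s_det + s_cont
    data.frame(gene = genes[j], stat_detection = s_det,
               stat_continuous = s_cont, stat = stat,
               p_value = pchisq(stat, df = 2, lower.tail = FALSE),
               log2fc = mean(x[g1]) - mean(x[!g1]), excluded = FALSE)
  })
  do.call(rbind, res)
}

#' Aggregate per-dataset marker tables into specificity/magnitude scores
#'
#' Runs robust rank aggregation twice over the per-dataset differential
#' expression tables: on p-value ranks (ascending) for the specificity
#' score and on log2 fold-change ranks (descending) for the magnitude
#' score.  Genes missing from a table receive the worst rank.
#'
#' @param tables List of `data.frame`s with columns `gene`, `p_value`,
#'   `log2fc`.
#' @param universe Optional gene universe (default: the union of the
#'   tables' genes); genes absent from every table score 1.
#' @return List of two `AggregatedSignature`s: `specificity`, `magnitude`.
#' @export
aggregate_marker_lists <- function(tables, universe = NULL) {
  if (length(tables) == 0 || any(vapply(tables, nrow, 1L) == 0))
    stop("empty tables")
  if (is.null(universe))
    universe <- sort(Reduce(union, lapply(tables, function(t) t$gene)))
  by_p <- lapply(tables, function(t) t$gene[order(t$p_value, t$gene)])
  by_fc <- lapply(tables, function(t) t$gene[order(-t$log2fc, t$gene)])
  list(specificity = rra_score(by_p, universe, level = "global"),
       magnitude = rra_score(by_fc, universe, level = "global"))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1, no continuity
#' correction.
#'
#' @param tab 2x2 matrix of non-negative counts with all margins positive.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
chi2_contingency <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin")
  n <- sum(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  chi2 <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(chi2 = chi2, df = 1, p_value = pchisq(chi2, 1, lower.tail = FALSE))
}
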