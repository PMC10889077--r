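# ---------------------------------------------------------------------------
# Two-stage feature selection and the region classifier: filter-score
# prefilter (chi2 / ANOVA F / mutual information union), model-based
# selection (L1 logistic or boosted trees) feeding an RBF SVM, grouped
# cross-validation scored by the Matthews correlation coefficient, ad hoc
# refit against unlabeled reference data, and prediction.
# ---------------------------------------------------------------------------

# --- scalers ---------------------------------------------------------------

.scale_minmax <- function(X) {
  mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
  rng <- maxs - mins
  rng[rng == 0] <- 1
  out <- sweep(sweep(X, 2, mins), 2, rng, "/")
  out[, maxs == mins] <- 0
  out
}

.robust_stats <- function(X) {
  center <- apply(X, 2, median)
  iqr <- apply(X, 2, function(v) diff(quantile(v, c(0.25, 0.75))))
  iqr[iqr == 0] <- 1
  list(center = center, scale = iqr)
}

.scale_robust <- function(X, stats) {
  sweep(sweep(X, 2, stats$center), 2, stats$scale, "/")
}

# --- filter scores ---------------------------------------------------------

# chi-square score on a non-negative (min-max scaled) matrix:
# per-class feature sums against class-probability expectations.
.score_chi2 <- function(X, y) {
  y <- factor(y)
  obs <- t(rowsum(X, y))                       # genes x classes
  ftot <- colSums(X)
  prob <- as.numeric(table(y)) / length(y)
  expd <- outer(ftot, prob)
  term <- (obs - expd)^2 / expd
  term[expd == 0] <- 0
  rowSums(term)
}

# one-way ANOVA F per column.
.score_f <- function(X, y) {
  y <- factor(y)
  n <- nrow(X); k <- nlevels(y)
  gm <- colMeans(X)
  cm <- rowsum(X, y) / as.numeric(table(y))    # classes x genes
  cn <- as.numeric(table(y))
  ssb <- colSums(cn * (t(t(cm) - gm))^2)
  sst <- colSums(X^2) - n * gm^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f)] <- 0
  f
}

# mutual information between a continuous feature and a discrete label,
# nearest-neighbor (Ross) estimator with k neighbors; a tiny seeded jitter
# breaks the ties that UMI-derived values are full of.
.score_mi <- function(X, y, k = 3, seed = 1L) {
  y <- factor(y)
  n <- nrow(X)
  n_c <- as.numeric(table(y))
  set.seed(seed)
  psi_n <- digamma(n)
  psi_k <- digamma(k)
  psi_nc <- digamma(n_c)[as.integer(y)]
  vapply(seq_len(ncol(X)), function(g) {
    x <- X[, g]
    if (var(x) == 0) return(0)
    x <- x + rnorm(n, 0, (sd(x) + 1e-12) * 1e-9)
    ord <- order(x)
    xs <- x[ord]; ys <- as.integer(y)[ord]
    radius <- numeric(n)
    ok <- rep(TRUE, n)
    for (cl in seq_along(n_c)) {
      pos <- which(ys == cl)
      nc <- length(pos)
      if (nc < 2) { ok[pos] <- FALSE; next }
      kk <- min(k, nc - 1)
      v <- pos_v <- xs[pos]
      cand <- matrix(Inf, nc, 2 * kk)
      for (t in seq_len(kk)) {
        cand[(t + 1):nc, t] <- v[(t + 1):nc] - v[seq_len(nc - t)]
        cand[seq_len(nc - t), kk + t] <- v[(t + 1):nc] - v[seq_len(nc - t)]
      }
      # k-th smallest per row via the rank-count trick
      counts <- matrix(0L, nc, 2 * kk)
      for (a in seq_len(2 * kk))
        for (b in seq_len(2 * kk))
          counts[, a] <- counts[, a] + (cand[, b] <= cand[, a])
      sel <- cand
      sel[counts < kk] <- Inf
      radius[pos] <- do.call(pmin, as.data.frame(sel))
    }
    idx <- which(ok & is.finite(radius))
    r <- radius[idx] * (1 - 1e-9)
    m <- findInterval(xs[idx] + r, xs) - findInterval(xs[idx] - r, xs) - 1L
    mi <- psi_n + psi_k - mean(psi_nc[ord][idx]) - mean(digamma(pmax(m, 1)))
    max(mi, 0)
  }, numeric(1))
}

.filter_score <- function(X, y, score_fn, seed = 1L) {
  switch(score_fn,
         chi2 = .score_chi2(X, y),
         anova_f = .score_f(X, y),
         mutual_info = .score_mi(X, y, seed = seed),
         stop("unknown score_fn: ", score_fn))
}

# --- CV fold builders ------------------------------------------------------

# stratified k-fold: shuffle within class, deal round-robin.
.stratified_folds <- function(y, n_folds, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# stratified grouped k-fold: every group lands in exactly one fold; groups
# are assigned greedily (largest first) to the fold whose class profile is
# furthest below target.
.stratified_group_folds <- function(y, groups, n_folds, seed = 1L) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < n_folds) {
    warning("fewer groups (", length(gl), ") than folds; reducing folds")
    n_folds <- length(gl)
  }
  y <- factor(y)
  gmat <- vapply(gl, function(g) {
    as.numeric(table(y[groups == g]))
  }, numeric(nlevels(y)))
  gmat <- t(matrix(gmat, nrow = nlevels(y)))
  set.seed(seed)
  ord <- order(-rowSums(gmat), runif(length(gl)))
  fold_counts <- matrix(0, n_folds, nlevels(y))
  gfold <- integer(length(gl))
  total <- colSums(gmat)
  for (g in ord) {
    dev <- vapply(seq_len(n_folds), function(f) {
      after <- fold_counts
      after[f, ] <- after[f, ] + gmat[g, ]
      sum((after[f, ] - total / n_folds)^2) + sum(after[f, ])^2 * 1e-9
    }, numeric(1))
    f <- which.min(dev)
    gfold[g] <- f
    fold_counts[f, ] <- fold_counts[f, ] + gmat[g, ]
  }
  list(fold = gfold[match(groups, gl)], n_folds = n_folds)
}

# --- grids -----------------------------------------------------------------

#' Prefilter grid specification
#'
#' @param score_fns Filter score functions to combine.
#' @param K Candidate feature counts.
#' @param C Candidate SVM fit strengths.
#' @param n_folds,n_repeats Repeated stratified CV shape.
#' @return A `PrefilterGrid` list.
#' @export
prefilter_grid <- function(score_fns = c("chi2", "anova_f", "mutual_info"),
                           K = c(2000, 1000, 500, 250),
                           C = c(1, 10, 100, 1000),
                           n_folds = 10, n_repeats = 10) {
  stopifnot(all(K > 0), length(K) > 0, length(C) > 0)
  structure(list(score_fns = score_fns, K = K, C = C,
                 n_folds = n_folds, n_repeats = n_repeats),
            class = "PrefilterGrid")
}

#' Model-selection grid specification
#'
#' @param selectors Model-based selectors to try.
#' @param n_feature_fracs Fractions of the prefiltered universe to keep
#'   (rounded).
#' @param C Candidate SVM fit strengths.
#' @param learning_rate,max_depth,n_rounds Boosted-tree selector parameters.
#' @param n_folds Grouped CV folds.
#' @return A `ModelGrid` list.
#' @export
model_grid <- function(selectors = c("l1_logistic_ovr", "boosted_trees"),
                       n_feature_fracs = c(1/3, 1/4, 1/8, 1/10, 1/20),
                       C = c(1, 10, 100, 200),
                       learning_rate = c(0.1, 0.3, 0.5),
                       max_depth = c(3, 5, 7),
                       n_rounds = c(100, 250, 500),
                       n_folds = 10) {
  structure(list(selectors = selectors, n_feature_fracs = n_feature_fracs,
                 C = C, learning_rate = learning_rate, max_depth = max_depth,
                 n_rounds = n_rounds, n_folds = n_folds),
            class = "ModelGrid")
}

# --- prefilter -------------------------------------------------------------

#' Prefilter features by the union of three selection criteria
#'
#' For each score function (chi-square, ANOVA F, nearest-neighbor mutual
#' information) the `(K, C)` grid is searched by repeated stratified k-fold
#' cross-validation of an RBF SVM on the top-K features, scored by weighted
#' F-measure; the winner's K features are kept and the three winners'
#' feature sets are unioned.  Scores are computed on the min-max scaled
#' matrix (the chi-square branch requires non-negative input).
#'
#' @param X Cells-by-genes numeric matrix (gene ids as column names).
#' @param y Region labels (at least 2 classes).
#' @param grid A `PrefilterGrid`.
#' @param seed Integer seed.
#' @return Character vector: the union of selected gene ids, with the
#'   per-score-function winners attached as the `"winners"` attribute.
#' @export
prefilter_features <- function(X, y, grid = prefilter_grid(), seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  genes <- colnames(X)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(ncol(X)))
  Xs <- .scale_minmax(X)
  Ks <- pmin(grid$K, ncol(X))
  winners <- list()
  for (fn in grid$score_fns) {
    score <- .filter_score(Xs, y, fn, seed = .derive_seed(seed, fn))
    ranking <- order(-score, genes)
    best <- NULL
    for (K in sort(unique(Ks), decreasing = TRUE)) for (C in grid$C) {
      sel <- ranking[seq_len(K)]
      fvals <- numeric(0)
      for (rep in seq_len(grid$n_repeats)) {
        fold <- .stratified_folds(y, grid$n_folds,
                                  seed = .derive_seed(seed, paste0(fn, rep)))
        for (f in seq_len(grid$n_folds)) {
          tr <- fold != f
          if (length(unique(y[tr])) < 2 || !any(!tr)) next
          fit <- e1071::svm(Xs[tr, sel, drop = FALSE], droplevels(y[tr]),
                            type = "C-classification", kernel = "radial",
                            cost = C, scale = FALSE)
          pred <- predict(fit, Xs[!tr, sel, drop = FALSE])
          fvals <- c(fvals,
                     classification_metrics(y[!tr], pred)$weighted_f)
        }
      }
      cand <- list(K = K, C = C, f = mean(fvals))
      if (is.null(best) || cand$f > best$f + 1e-12 ||
          (abs(cand$f - best$f) <= 1e-12 &&
           (cand$K < best$K || (cand$K == best$K && cand$C < best$C))))
        best <- cand
    }
    winners[[fn]] <- genes[ranking[seq_len(best$K)]]
  }
  out <- Reduce(union, winners)
  attr(out, "winners") <- winners
  out
}

# --- model-based selection + SVM ------------------------------------------

.importance_l1 <- function(Xs, y, seed = 1L) {
  y <- factor(y)
  p <- ncol(Xs)
  imp <- rep(0, p)
  for (cl in levels(y)) {
    yb <- as.numeric(y == cl)
    fit <- glmnet::glmnet(Xs, yb, family = "binomial", alpha = 1,
                          nlambda = 50, standardize = FALSE)
    beta <- abs(fit$beta[, ncol(fit$beta)])   # densest end of the path
    imp <- pmax(imp, beta)
  }
  imp
}

.importance_xgb <- function(Xs, y, eta, max_depth, nrounds, seed = 1L) {
  y <- factor(y)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(Xs, label = as.integer(y) - 1L)
  fit <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = nlevels(y),
                  eta = eta, max_depth = max_depth, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  it <- xgboost::xgb.importance(model = fit)
  imp <- rep(0, ncol(Xs))
  idx <- match(it$Feature, colnames(Xs))
  imp[idx[!is.na(idx)]] <- it$Gain[!is.na(idx)]
  imp
}

.svm_gamma <- function(X) {
  v <- var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

.fit_svm <- function(X, y, C) {
  y <- droplevels(factor(y))
  wts <- 1 / as.numeric(table(y))
  wts <- wts / sum(wts) * nlevels(y)
  names(wts) <- levels(y)
  e1071::svm(X, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = .svm_gamma(X), class.weights = wts,
             scale = FALSE)
}

#' Fit the region classifier under grouped cross-validation
#'
#' Pipeline per grid configuration: robust scaling, model-based gene ranking
#' (L1 one-vs-rest logistic coefficients or boosted-tree gain importance),
#' top-N selection, RBF SVM with scaled gamma and inverse-frequency class
#' weights.  Configurations are compared by stratified grouped k-fold CV
#' (each microcluster group lands in exactly one fold) scored by multiclass
#' MCC; the winner is refit on the full training set.  Ties go to the
#' smallest feature count, then the smallest C.
#'
#' @param X Cells-by-genes training matrix (prefiltered universe).
#' @param y Region labels.
#' @param groups Group ids per cell (microcluster labels).
#' @param grid A `ModelGrid`.
#' @param seed Integer seed.
#' @return A `RegionClassifierModel` with the CV report in `$cv_table`.
#' @export
fit_region_classifier <- function(X, y, groups, grid = model_grid(),
                                  seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  genes <- colnames(X)
  if (is.null(genes)) { genes <- sprintf("g%04d", seq_len(ncol(X))); colnames(X) <- genes }
  stats <- .robust_stats(X)
  Xs <- .scale_robust(X, stats)
  fd <- .stratified_group_folds(y, groups, grid$n_folds, seed = seed)
  fold <- fd$fold; n_folds <- fd$n_folds
  n_feats <- unique(pmax(1, pmin(round(ncol(X) * grid$n_feature_fracs), ncol(X))))

  configs <- list()
  for (selector in grid$selectors) {
    if (selector == "l1_logistic_ovr") {
      for (N in n_feats) for (C in grid$C)
        configs[[length(configs) + 1]] <- list(selector = selector, N = N, C = C)
    } else if (selector == "boosted_trees") {
      for (eta in grid$learning_rate) for (depth in grid$max_depth)
        for (nr in grid$n_rounds) for (N in n_feats) for (C in grid$C)
          configs[[length(configs) + 1]] <- list(selector = selector, N = N,
                                                 C = C, eta = eta,
                                                 depth = depth, nrounds = nr)
    } else stop("unknown selector: ", selector)
  }

  imp_cache <- new.env()
  importance_for <- function(rows, cfg, tag) {
    key <- paste(tag, cfg$selector, cfg$eta, cfg$depth, cfg$nrounds)
    if (!is.null(imp_cache[[key]])) return(imp_cache[[key]])
    imp <- if (cfg$selector == "l1_logistic_ovr")
      .importance_l1(Xs[rows, , drop = FALSE], y[rows], seed = seed)
    else
      .importance_xgb(Xs[rows, , drop = FALSE], y[rows],
                      cfg$eta, cfg$depth, cfg$nrounds, seed = seed)
    imp_cache[[key]] <- imp
    imp
  }

  cv_rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    mccs <- numeric(0)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (!any(!tr)) next
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      imp <- importance_for(which(tr), cfg, paste0("fold", f))
      sel <- order(-imp, genes)[seq_len(cfg$N)]
      fit <- .fit_svm(Xs[tr, sel, drop = FALSE], y[tr], cfg$C)
      pred <- predict(fit, Xs[!tr, sel, drop = FALSE])
      mccs <- c(mccs, classification_metrics(y[!tr], pred)$mcc)
    }
    cv_rows[[ci]] <- data.frame(config = ci, selector = cfg$selector,
                                N = cfg$N, C = cfg$C,
                                eta = cfg$eta %||% NA,
                                depth = cfg$depth %||% NA,
                                nrounds = cfg$nrounds %||% NA,
                                mean_mcc = mean(mccs), n_folds = length(mccs))
  }
  cv_table <- do.call(rbind, cv_rows)
  ord <- order(-cv_table$mean_mcc, cv_table$N, cv_table$C)
  best_cfg <- configs[[cv_table$config[ord[1]]]]

  imp_full <- importance_for(seq_len(nrow(Xs)), best_cfg, "full")
  sel <- order(-imp_full, genes)[seq_len(best_cfg$N)]
  svm_fit <- .fit_svm(Xs[, sel, drop = FALSE], y, best_cfg$C)

  structure(list(scaler = stats, genes = genes,
                 selected_genes = genes[sel], config = best_cfg,
                 svm = svm_fit, classes = levels(y), cv_table = cv_table,
                 grid = grid, seed = seed,
                 training = list(X = X, y = y, groups = groups)),
            class = "RegionClassifierModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ad hoc refit against unlabeled reference data
#'
#' Restricts the training universe to genes expressed (count > 0) in more
#' than 10 cells in *every* reference dataset (strictly more than 10),
#' intersected with the model's training universe, then re-runs selection
#' and fitting on that subset so the model only relies on genes observable
#' in the data it will be projected onto.
#'
#' @param model A fitted `RegionClassifierModel` (keeps its training data).
#' @param reference_collection A `DatasetCollection` (its reference
#'   datasets are used) or plain list of `ExpressionDataset`s.
#' @param grid Optional `ModelGrid` (defaults to the model's own grid).
#' @param min_cells Expression threshold (default 10; strict inequality).
#' @return A refit `RegionClassifierModel`.
#' @export
adhoc_refit <- function(model, reference_collection, grid = NULL,
                        min_cells = 10) {
  refs <- if (inherits(reference_collection, "DatasetCollection"))
    reference_collection$datasets[reference_indices(reference_collection)]
  else reference_collection
  if (length(refs) < 1) stop("need at least one reference dataset")
  per_ref <- lapply(refs, function(d) {
    ncells <- Matrix::colSums(d$counts > 0)
    d$gene_table$gene_id[ncells > min_cells]
  })
  universe <- intersect(Reduce(intersect, per_ref), model$genes)
  if (length(universe) == 0) stop("empty gene universe after intersection")
  keep <- match(universe, model$genes)
  fit_region_classifier(model$training$X[, keep, drop = FALSE],
                        model$training$y, model$training$groups,
                        grid = grid %||% model$grid, seed = model$seed)
}

#' Predict regional origin for a dataset
#'
#' @param model A `RegionClassifierModel`.
#' @param dataset An `ExpressionDataset` (its `norm_layer` is used; Pearson
#'   residuals are computed when absent) or a plain cells-by-genes matrix.
#' @param missing_gene_policy `"error"` lists missing model genes and stops;
#'   `"zero_fill"` proceeds with zeros and a warning.
#' @return List with `labels` (drawn from the model's class set) and
#'   `scores` (per-class one-vs-one vote fractions).
#' @export
predict_regions <- function(model, dataset,
                            missing_gene_policy = c("error", "zero_fill")) {
  missing_gene_policy <- match.arg(missing_gene_policy)
  if (inherits(dataset, "ExpressionDataset")) {
    if (is.null(dataset$norm_layer)) dataset <- pearson_residuals(dataset)
    M <- as.matrix(dataset$norm_layer)
    colnames(M) <- dataset$gene_table$gene_id
  } else M <- as.matrix(dataset)
  sel <- model$selected_genes
  missing <- setdiff(sel, colnames(M))
  if (length(missing)) {
    if (missing_gene_policy == "error")
      stop("missing model genes: ", paste(missing, collapse = ", "))
    warning("zero-filling ", length(missing), " missing model gene(s)")
    M <- cbind(M, matrix(0, nrow(M), length(missing),
                         dimnames = list(NULL, missing)))
  }
  Xp <- M[, sel, drop = FALSE]
  idx <- match(sel, model$genes)
  stats_sel <- list(center = model$scaler$center[idx],
                    scale = model$scaler$scale[idx])
  Xp <- .scale_robust(Xp, stats_sel)
  pred <- predict(model$svm, Xp, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  classes <- model$classes
  votes <- matrix(0, nrow(Xp), length(classes),
                  dimnames = list(NULL, classes))
  pairs <- strsplit(colnames(dv), "/")
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    pos <- dv[, j] > 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
  }
  votes <- votes / max(1, ncol(dv))
  list(labels = as.character(pred), scores = votes)
}

#' Serialize / load a region classifier model
#'
#' Writes a human-readable JSON manifest (genes, classes, hyperparameters,
#' CV table) next to a binary sidecar holding the numeric payload (scaler
#' statistics, SVM support data, training matrix), so the model
#' round-trips losslessly.
#'
#' @param model A `RegionClassifierModel`.
#' @param path Basename path; `<path>.json` and `<path>.rds` are written.
#' @return The manifest path, invisibly.
#' @export
write_region_model <- function(model, path) {
  manifest <- list(classes = model$classes,
                   selected_genes = model$selected_genes,
                   n_genes_universe = length(model$genes),
                   config = model$config[!vapply(model$config, is.null, TRUE)],
                   cv_table = model$cv_table)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(model, paste0(path, ".rds"))
  invisible(paste0(path, ".json"))
}

#' @rdname write_region_model
#' @export
read_region_model <- function(path) {
  readRDS(paste0(path, ".rds"))
}
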