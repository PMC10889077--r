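test_that("classification metrics match hand-computed binary MCC", {
  # TP=40, TN=30, FP=10, FN=20
  yt <- c(rep("pos", 60), rep("neg", 40))
  yp <- c(rep("pos", 40), rep("neg", 20), rep("pos", 10), rep("neg", 30))
  ev <- classification_metrics(yt, yp)
  expect_equal(ev$mcc, (40 * 30 - 10 * 20) / sqrt(50 * 60 * 40 * 50),
               tolerance = 1e-12)
  expect_equal(ev$n, 100)
  # perfect predictions
  evp <- classification_metrics(yt, yt)
  expect_equal(evp$mcc, 1)
  expect_equal(evp$weighted_f, 1)
  # constant predictor: 0/0 convention
  expect_equal(classification_metrics(yt, rep("pos", 100))$mcc, 0)
  expect_error(classification_metrics(character(0), character(0)), "empty")
})

test_that("MCC and weighted F match brute-force oracles on random matrices", {
  # independent oracle: explicit element-wise Gorodkin sums and per-class
  # F1 loops, written against the confusion matrix directly
  oracle <- function(cm) {
    K <- nrow(cm); s <- sum(cm)
    corr <- sum(diag(cm))
    num <- 0; st2 <- 0; sp2 <- 0
    for (k in 1:K) {
      tk <- sum(cm[k, ]); pk <- sum(cm[, k])
      num <- num + tk * pk
      st2 <- st2 + tk^2; sp2 <- sp2 + pk^2
    }
    den <- sqrt(s^2 - sp2) * sqrt(s^2 - st2)
    mcc <- if (den == 0) 0 else (corr * s - num) / den
    f <- 0
    for (k in 1:K) {
      tk <- sum(cm[k, ]); pk <- sum(cm[, k])
      prec <- if (pk > 0) cm[k, k] / pk else 0
      rec <- if (tk > 0) cm[k, k] / tk else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      f <- f + f1 * tk / s
    }
    c(mcc = mcc, f = f)
  }
  set.seed(15)
  for (trial in 1:1000) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 3), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    labs <- expand_confusion(cm)
    ev <- classification_metrics(labs$y_true, labs$y_pred)
    ora <- oracle(cm)
    expect_equal(ev$mcc, unname(ora["mcc"]), tolerance = 1e-12)
    expect_equal(ev$weighted_f, unname(ora["f"]), tolerance = 1e-12)
  }
})

test_that("corrected t-test reduces to the paired t when n_test = 0", {
  set.seed(16)
  d <- rnorm(10, 0.05, 0.1)
  ct <- corrected_t_test(d, n_train = 100, n_test = 0)
  ref <- t.test(d, alternative = "greater")
  expect_lt(abs(ct$t - unname(ref$statistic)), 1e-12)
  expect_lt(abs(ct$p_value - ref$p.value), 1e-12)
  # worked vector against an independent step-by-step computation
  ct2 <- corrected_t_test(d, n_train = 90, n_test = 10)
  manual <- mean(d) / sqrt((1 / 10 + 10 / 90) * sum((d - mean(d))^2) / 9)
  expect_lt(abs(ct2$t - manual), 1e-12)
  # degenerate cases
  z <- corrected_t_test(rep(0, 5), 90, 10)
  expect_equal(z$t, 0); expect_equal(z$p_value, 0.5)
  inf <- corrected_t_test(rep(0.2, 5), 90, 10)
  expect_true(is.infinite(inf$t) && inf$degenerate)
})

test_that("corrected t-test controls type-I error under correlated folds", {
  # correlated-folds null: per-replicate differences share a fold-overlap
  # component with variance fraction n_test / (n_train + n_test)
  J <- 10; n_train <- 90; n_test <- 10
  rho <- n_test / (n_train + n_test)
  set.seed(17)
  rejections <- vapply(seq_len(2000), function(i) {
    shared <- rnorm(1, 0, sqrt(rho / (1 - rho)))
    d <- shared + rnorm(J)
    corrected_t_test(d, n_train, n_test)$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.07)
})

test_that("Bayesian comparison is symmetric, proper, and matches sampling", {
  set.seed(18)
  d <- rnorm(10, 0.03, 0.05)
  bc <- bayes_compare(d, 90, 10, rope = 0.01)
  expect_equal(bc$p_better + bc$p_worse + bc$p_rope, 1, tolerance = 1e-12)
  # d-bar = 0, rope = 0: exact symmetry
  d0 <- c(-0.1, 0.1, -0.2, 0.2)
  b0 <- bayes_compare(d0, 90, 10, rope = 0)
  expect_equal(b0$p_better, 0.5, tolerance = 1e-12)
  expect_equal(b0$p_worse, 0.5, tolerance = 1e-12)
  # Monte-Carlo check of the posterior Student-t tail probabilities
  draws <- bc$location + bc$scale * rt(1e6, df = bc$df)
  expect_lt(abs(mean(draws > 0.01) - bc$p_better), 0.005)
  expect_lt(abs(mean(draws < -0.01) - bc$p_worse), 0.005)
  expect_error(bayes_compare(d, 90, 10, rope = -1), "non-negative")
})

test_that("logistic marker test flags planted markers and only those", {
  set.seed(19)
  n <- 150
  cl <- rep(c("c1", "c2", "c3"), each = n / 3)
  M <- matrix(rnorm(n * 20), n, 20)
  M[cl == "c1", 1] <- M[cl == "c1", 1] + 3       # marker of c1
  colnames(M) <- sprintf("g%02d", 1:20)
  res <- logreg_markers(M, cl)
  r1 <- res[res$cluster == "c1", ]
  expect_true(r1$marker[r1$gene == "g01"])
  expect_lt(mean(r1$marker[r1$gene != "g01"]), 0.2)
  # identical gene across clusters: not a marker anywhere
  flat <- res[res$gene == "g10", ]
  expect_false(any(flat$marker))
  # BH adjustment is monotone in raw p
  ord <- order(r1$p_value)
  expect_true(all(diff(r1$fdr[ord]) >= -1e-12))
  expect_error(logreg_markers(M, rep("c1", n)), "2 clusters")
})

test_that("hurdle statistic decomposes additively and is null-calibrated", {
  set.seed(20)
  n <- 120
  g <- rep(c("a", "b"), each = n / 2)
  M <- matrix(rexp(n * 40) * rbinom(n * 40, 1, 0.6), n, 40)
  M <- cbind(M, 0)                     # an all-zero gene
  colnames(M) <- sprintf("g%02d", seq_len(ncol(M)))
  res <- hurdle_test(M, g)
  expect_true(res$excluded[41])
  ok <- !res$excluded
  expect_equal(res$stat[ok],
               res$stat_detection[ok] + res$stat_continuous[ok])
  # label-permutation null: median statistic below the chi2(2) median
  expect_lte(median(res$stat[ok]), qchisq(0.5, 2) * 1.5)
  expect_error(hurdle_test(M, rep("a", n)), "two groups")
  # planted difference is detected
  M2 <- M[, 1:10]
  M2[g == "a", 1] <- M2[g == "a", 1] + 2
  res2 <- hurdle_test(M2, g)
  expect_lt(res2$p_value[1], 1e-4)
  expect_gt(res2$log2fc[1], 0)
})

test_that("marker-list aggregation rewards consistent top genes", {
  mk_table <- function(seed) {
    set.seed(seed)
    genes <- sprintf("g%02d", 1:30)
    data.frame(gene = genes,
               p_value = ifelse(genes == "g01", 1e-8, runif(30)),
               log2fc = ifelse(genes == "g01", 5, rnorm(30)))
  }
  tabs <- lapply(1:4, mk_table)
  agg <- aggregate_marker_lists(tabs)
  expect_equal(agg$specificity$gene[1], "g01")
  expect_equal(agg$magnitude$gene[1], "g01")
  expect_true(all(diff(agg$specificity$rho) >= -1e-15))
  # a gene absent from all tables scores 1
  tabs2 <- lapply(tabs, function(t) t[t$gene != "g30", ])
  agg2 <- aggregate_marker_lists(tabs2, universe = sprintf("g%02d", 1:30))
  expect_equal(agg2$specificity$rho[agg2$specificity$gene == "g30"], 1)
  expect_error(aggregate_marker_lists(list()), "empty")
})

test_that("2x2 chi-square matches the closed form", {
  even <- chi2_contingency(matrix(10, 2, 2))
  expect_equal(even$chi2, 0)
  expect_equal(even$p_value, 1)
  skew <- chi2_contingency(matrix(c(30, 10, 10, 30), 2, 2))
  expect_equal(skew$chi2, 20, tolerance = 1e-12)
  # agreement with the standard implementation, no continuity correction
  tab <- matrix(c(12, 5, 7, 20), 2, 2)
  expect_equal(chi2_contingency(tab)$chi2,
               unname(chisq.test(tab, correct = FALSE)$statistic),
               tolerance = 1e-12)
  # invariance under simultaneous row and column swap
  expect_equal(chi2_contingency(tab)$chi2,
               chi2_contingency(tab[2:1, 2:1])$chi2)
  expect_error(chi2_contingency(matrix(c(-1, 2, 3, 4), 2, 2)), "negative")
  expect_error(chi2_contingency(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("hurdle covariate adjustment absorbs detection-rate confounding", {
  set.seed(21)
  n <- 160
  g <- rep(c("a", "b"), each = n / 2)
  cdr <- c(runif(n / 2, 0.2, 0.5), runif(n / 2, 0.5, 0.8))  # confounded
  M <- matrix(rbinom(n * 30, 1, cdr) * rexp(n * 30), n, 30)
  plain <- hurdle_test(M, g)
  adj <- hurdle_test(M, g, covariates = cdr)
  # adjusting for the confounder shrinks the typical null statistic
  expect_lt(median(adj$stat, na.rm = TRUE),
            median(plain$stat, na.rm = TRUE))
})
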