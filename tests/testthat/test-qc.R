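test_that("QC metrics match hand computation", {
  # cell 1: 100 UMI over 10 genes -> complexity = 1/2; all counts on
  # mito-flagged genes -> pct_mito = 100
  counts <- rbind(c(rep(10, 10), rep(0, 10)),
                  c(rep(0, 10), rep(3, 10)))
  genes <- c(sprintf("mt-%d", 1:10), sprintf("Actb%d", 1:10))
  ds <- ExpressionDataset(counts,
                          data.frame(cell_id = c("a", "b")),
                          data.frame(gene_id = genes, symbol = genes))
  ds <- compute_qc_metrics(ds)
  ct <- ds$cell_table
  expect_equal(ct$complexity[1], log10(10) / log10(100))
  expect_equal(ct$pct_mito[1], 100)
  expect_equal(ct$pct_mito[2], 0)
  expect_equal(ct$n_umi, c(100, 30))
})

test_that("zero-UMI cells are dropped and all-zero input empties with warning", {
  counts <- rbind(c(1, 2), c(0, 0))
  ds <- ExpressionDataset(counts, data.frame(cell_id = c("a", "b")),
                          data.frame(gene_id = c("mt-1", "g2")))
  expect_message(out <- compute_qc_metrics(ds), "dropping 1")
  expect_equal(nrow(out$counts), 1)
  zeros <- ExpressionDataset(matrix(0, 3, 2),
                             data.frame(cell_id = c("a", "b", "c")),
                             data.frame(gene_id = c("mt-1", "g2")))
  expect_warning(suppressMessages(out2 <- compute_qc_metrics(zeros)),
                 "zero UMI")
  expect_equal(nrow(out2$counts), 0)
})

test_that("mito mixture separates planted bands and honors cutoff edge cases", {
  set.seed(11)
  n <- 500
  ng <- sample(500:4000, n, replace = TRUE)
  bad <- rbinom(n, 1, 0.3) == 1
  pm <- ifelse(bad, 25 + 0.002 * ng + rnorm(n, 0, 2),
               2 + 0.001 * ng + rnorm(n, 0, 1))
  qct <- data.frame(pct_mito = pmax(pm, 0), n_genes_detected = ng)
  mm <- fit_mito_mixture(qct, posterior_cutoff = 0.75)
  expect_gte(mean(!mm$keep[bad]), 0.9)     # sensitivity
  expect_gte(mean(mm$keep[!bad]), 0.9)     # specificity
  # cutoff 1.0 keeps everything (posterior < 1 always)
  mm1 <- fit_mito_mixture(qct, posterior_cutoff = 1.0)
  expect_true(all(mm1$keep))
  # all-zero mito content: everything kept
  mm0 <- fit_mito_mixture(data.frame(pct_mito = rep(0, 100),
                                     n_genes_detected = seq_len(100)))
  expect_true(all(mm0$keep))
})

test_that("doublet scoring finds planted doublets and is seed-stable", {
  sim <- small_sim(seed = 21, doublet_rate = 0.1,
                   cells_per_regional = 800, n_genes = 400)
  ds <- sim$collection$datasets[[1]]
  truth <- sim$truth$cells[sim$truth$cells$dataset_id ==
                             ds$cell_table$dataset_id[1], ]
  sc <- doublet_score(ds, expected_rate = 0.1, seed = 4)
  expect_gte(auroc(sc$score, truth$is_doublet), 0.9)
  sc2 <- doublet_score(ds, expected_rate = 0.1, seed = 4)
  expect_identical(sc$score, sc2$score)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # zero expected rate means zero calls
  sc0 <- doublet_score(ds, expected_rate = 0, seed = 4)
  expect_false(any(sc0$call))
  expect_error(doublet_score(ds, expected_rate = 1.2), "expected_rate")
})

test_that("gene-set scores separate a shifted population", {
  sim <- small_sim(seed = 31)
  ds <- pearson_residuals(sim$collection$datasets[[1]])
  set_genes <- ds$gene_table$gene_id[1:10]
  # constant matrix: score 0 for any set
  flat <- ds
  flat$norm_layer <- matrix(1, nrow(ds$counts), ncol(ds$counts))
  expect_equal(unique(score_gene_set(flat, set_genes, seed = 2)), 0)
  # planted shift in half the cells
  half <- seq_len(nrow(ds$counts)) <= nrow(ds$counts) / 2
  shifted <- ds
  shifted$norm_layer[half, 1:10] <- shifted$norm_layer[half, 1:10] + 3
  sc <- score_gene_set(shifted, set_genes, seed = 2)
  expect_lt(wilcox.test(sc[half], sc[!half], alternative = "greater")$p.value,
            0.01)
  expect_identical(sc, score_gene_set(shifted, set_genes, seed = 2))
  expect_error(score_gene_set(ds, character(0)), "empty")
})

test_that("hypergeometric enrichment matches the exact tail", {
  universe <- sprintf("g%03d", 1:100)
  ref <- list(hit = universe[1:10], none = universe[90:95])
  res <- ora_enrichment(universe[1:5], ref, universe)
  # all 5 query genes inside the 10-gene set
  expect_equal(res$p_value[res$set == "hit"],
               choose(10, 5) / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "none"], 1)
  # query = universe forces overlap, p = 1
  res2 <- ora_enrichment(universe, ref["hit"], universe)
  expect_equal(res2$p_value, 1)
  expect_error(ora_enrichment(universe[1:5],
                              list(big = c(universe, "extra")), universe),
               "larger than the universe")
})

test_that("ORA p-values match brute-force enumeration on small universes", {
  # enumerate all query draws of size n from a universe of N with K marked:
  # P(overlap >= k_obs) by complete enumeration of combinations
  universe <- letters[1:12]
  ref <- list(s = letters[1:4])
  for (qsize in c(2, 4)) {
    combs <- combn(12, qsize)
    for (trial in 1:5) {
      set.seed(trial)
      q <- sample(universe, qsize)
      k_obs <- length(intersect(q, ref$s))
      if (k_obs == 0) next
      overlaps <- apply(combs, 2, function(ix) sum(universe[ix] %in% ref$s))
      p_brute <- mean(overlaps >= k_obs)
      p_pkg <- ora_enrichment(q, ref, universe)$p_value
      expect_equal(p_pkg, p_brute, tolerance = 1e-12)
    }
  }
})

test_that("marker-panel selection applies both thresholds and is monotone", {
  n_genes <- 30
  genes <- sprintf("g%02d", 1:n_genes)
  panel <- marker_panel(genes[1:22], genes[23:30],
                        min_inclusion = 7, max_exclusion = 2)
  mk_cell <- function(n_inc, n_exc) {
    x <- numeric(n_genes)
    if (n_inc > 0) x[seq_len(n_inc)] <- 1
    if (n_exc > 0) x[22 + seq_len(n_exc)] <- 1
    x
  }
  counts <- rbind(mk_cell(7, 2),    # exactly at both thresholds: pass
                  mk_cell(6, 0),    # one inclusion short: fail
                  mk_cell(10, 3),   # one exclusion over: fail
                  mk_cell(22, 0))   # all inclusion: pass
  ds <- ExpressionDataset(counts,
                          data.frame(cell_id = sprintf("c%d", 1:4)),
                          data.frame(gene_id = genes))
  expect_equal(select_astrocytes(ds, panel), c(TRUE, FALSE, FALSE, TRUE))
  # monotonicity: adding detected inclusion genes never flips pass -> fail
  for (extra in 1:5) {
    more <- rbind(mk_cell(7 + extra, 2))
    ds2 <- ExpressionDataset(more, data.frame(cell_id = "c"),
                             data.frame(gene_id = genes))
    expect_true(select_astrocytes(ds2, panel))
  }
  expect_error(marker_panel(genes[1:5], genes[c(3, 6)]), "disjoint")
})

test_that("panel files round-trip and missing genes are policed", {
  dir <- withr::local_tempdir()
  inc <- file.path(dir, "inc.txt"); exc <- file.path(dir, "exc.txt")
  writeLines(sprintf("g%02d", 1:22), inc)
  writeLines(sprintf("g%02d", 23:81), exc)
  panel <- read_marker_panel(inc, exc)
  expect_length(panel$inclusion_genes, 22)
  expect_length(panel$exclusion_genes, 59)
  ds <- toy_dataset()       # 3 unrelated genes: >50% of panel missing
  expect_error(suppressMessages(select_astrocytes(ds, panel)), "50%")
})

test_that("train/test split follows the stated probability rule", {
  set.seed(1)
  sp <- train_test_split(10000, seed = 8)
  expect_equal(mean(sp$train), 0.9, tolerance = 0.02)
  expect_true(all(xor(sp$train, sp$test)))
  # N = 1050: p = 1000/1050
  sp2 <- train_test_split(1050, seed = 8)
  expect_equal(mean(sp2$train), 1000 / 1050, tolerance = 0.04)
  # N <= 1000: p = 1, empty test set with a warning
  expect_warning(sp3 <- train_test_split(800, seed = 8), "empty")
  expect_true(all(sp3$train))
  expect_identical(suppressWarnings(train_test_split(500, seed = 3)$train),
                   suppressWarnings(train_test_split(500, seed = 3)$train))
})
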