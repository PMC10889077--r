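test_that("duplicated batches need no correction and stay untouched", {
  set.seed(1)
  Z <- matrix(rnorm(150 * 6), 150, 6)
  fit <- integrate_embedding(rbind(Z, Z), rep(c("a", "b"), each = 150),
                             k_clusters = 5, seed = 2)
  expect_lt(max(abs(fit$embedding - rbind(Z, Z))), 1e-6)
})

test_that("a constant batch offset is almost entirely removed", {
  set.seed(2)
  Z <- matrix(rnorm(200 * 6), 200, 6)
  Z2 <- rbind(Z, Z + 1.5)
  b <- rep(c("a", "b"), each = 200)
  pre <- sqrt(sum((colMeans(Z2[1:200, ]) - colMeans(Z2[201:400, ]))^2))
  fit <- integrate_embedding(Z2, b, k_clusters = 5, seed = 2)
  post <- sqrt(sum((colMeans(fit$embedding[1:200, ]) -
                      colMeans(fit$embedding[201:400, ]))^2))
  expect_lt(post / pre, 0.1)
  # determinism
  fit2 <- integrate_embedding(Z2, b, k_clusters = 5, seed = 2)
  expect_identical(fit$embedding, fit2$embedding)
  expect_error(integrate_embedding(Z2, b, k_clusters = 1), "at least 2")
})

test_that("pair integration yields ranking of the right length and determinism", {
  sim <- small_sim(seed = 17)
  reg <- sim$collection$datasets[[1]]
  ref <- sim$collection$datasets[[4]]
  pair <- integrate_pair(reg, ref, n_anchor_hvgs = 150, d = 10, seed = 5)
  expect_s3_class(pair, "IntegrationPair")
  expect_length(pair$anchor_ranking, 150)          # min(150, 300 shared)
  expect_false(anyDuplicated(pair$anchor_ranking) > 0)
  expect_equal(nrow(pair$embedding), nrow(reg$counts) + nrow(ref$counts))
  pair2 <- integrate_pair(reg, ref, n_anchor_hvgs = 150, d = 10, seed = 5)
  expect_identical(pair$embedding, pair2$embedding)
  expect_identical(extract_anchor_ranking(pair), extract_anchor_ranking(pair2))
  # more genes requested than shared: capped at the universe
  pair3 <- integrate_pair(reg, ref, n_anchor_hvgs = 1000, d = 10, seed = 5)
  expect_length(pair3$anchor_ranking, 300)
})

test_that("planted state genes crowd the top of the anchor ranking", {
  sim <- small_sim(seed = 19)
  pair <- integrate_pair(sim$collection$datasets[[1]],
                         sim$collection$datasets[[4]],
                         n_anchor_hvgs = 300, d = 10, seed = 5)
  prog <- sim$truth$gene_programs
  state_genes <- prog$gene_id[startsWith(prog$program, "state:")]
  top <- pair$anchor_ranking[seq_along(state_genes)]
  expect_gte(mean(state_genes %in% top), 0.9)
})

test_that("RRA beta-tail scores match the stated formula on edge cases", {
  universe <- letters[1:10]
  # gene absent from all lists -> rho = 1
  sig <- rra_score(list(c("a")), universe)
  expect_equal(sig$rho[sig$gene == "z" | sig$gene == "j"], 1)
  # gene ranked 1st of 10 in all 3 lists: rho = (1/10)^3
  sig3 <- rra_score(list(c("a", "b"), c("a", "c"), c("a", "d")), universe)
  expect_equal(sig3$rho[sig3$gene == "a"], 1e-3, tolerance = 1e-12)
  expect_equal(sig3$score[sig3$gene == "a"], 3e-3, tolerance = 1e-12)
  # invariance to list order
  sigR <- rra_score(list(c("a", "d"), c("a", "b"), c("a", "c")), universe)
  expect_equal(sig3$rho, sigR$rho)
  expect_error(rra_score(list(c("a")), character(0)), "empty universe")
})

test_that("RRA equals brute-force binomial-tail enumeration", {
  # oracle: P(at least k of m uniforms <= x) via binomial tail, minimized
  brute_rho <- function(ranks) {
    m <- length(ranks)
    r <- sort(ranks)
    min(vapply(seq_len(m), function(k)
      sum(vapply(k:m, function(j)
        choose(m, j) * r[k]^j * (1 - r[k])^(m - j), numeric(1))),
      numeric(1)))
  }
  set.seed(8)
  for (trial in 1:20) {
    m <- sample(1:5, 1)
    N <- sample(5:20, 1)
    universe <- sprintf("u%02d", seq_len(N))
    lists <- lapply(seq_len(m), function(i)
      sample(universe, sample.int(N, 1)))
    sig <- rra_score(lists, universe)
    for (g in universe) {
      ranks <- vapply(lists, function(l) {
        p <- match(g, l)
        if (is.na(p)) 1 else p / N
      }, numeric(1))
      expect_lt(abs(sig$rho[sig$gene == g] - brute_rho(ranks)), 1e-9)
    }
  }
})

test_that("rho is monotone: improving a rank never increases it", {
  universe <- sprintf("u%02d", 1:20)
  base_lists <- list(sample(universe), sample(universe), sample(universe))
  g <- "u05"
  rho_at <- function(pos) {
    lists <- lapply(base_lists, function(l) {
      l <- setdiff(l, g)
      append(l, g, after = pos - 1)
    })
    sig <- rra_score(lists, universe)
    sig$rho[sig$gene == g]
  }
  rhos <- vapply(c(1, 5, 10, 20), rho_at, numeric(1))
  expect_true(all(diff(rhos) >= -1e-15))
})

test_that("single-pair signature reduces to the anchor ranking order", {
  sim <- small_sim(seed = 23, n_regional_datasets = 1,
                   n_reference_datasets = 1)
  sig <- build_shared_signature(sim$collection, n_anchor_hvgs = 300,
                                d = 8, seed = 4)
  pair <- sig$pairs[[1]]
  expect_equal(sig$global$gene[seq_len(50)], pair$anchor_ranking[seq_len(50)])
})

test_that("subtraction removes core plus correlated genes and partitions", {
  sim <- small_sim(seed = 29, n_regional_datasets = 1,
                   n_reference_datasets = 1)
  ds <- pearson_residuals(sim$collection$datasets[[1]])
  # plant 3 exact duplicates of the first signature gene
  sig <- build_shared_signature(sim$collection, n_anchor_hvgs = 300,
                                d = 8, seed = 4)$global
  core1 <- match(sig$gene[1], ds$gene_table$gene_id)
  dupes <- match(sig$gene[200:202], ds$gene_table$gene_id)
  ds$norm_layer[, dupes] <- ds$norm_layer[, core1]
  res <- subtract_signature(ds, sig, T = 5, corr_threshold = 0.5)
  expect_true(all(ds$gene_table$gene_id[dupes] %in% res$removed_correlated))
  expect_length(intersect(res$removed_core, res$removed_correlated), 0)
  expect_setequal(c(res$removed_core, res$removed_correlated, res$retained),
                  ds$gene_table$gene_id)
  # T = 0 removes nothing
  res0 <- subtract_signature(ds, sig, T = 0)
  expect_length(res0$removed_core, 0)
  expect_equal(ncol(res0$dataset$counts), ncol(ds$counts))
  expect_error(subtract_signature(ds, sig, T = nrow(sig) + 1), "exceeds")
})

test_that("subtraction shifts residual variance from state to region programs", {
  sim <- small_sim(seed = 31, batch_sd = 0.1)
  sig <- build_shared_signature(sim$collection, n_anchor_hvgs = 300,
                                d = 8, seed = 4)$global
  reg <- concat_datasets(
    DatasetCollection(sim$collection$datasets[1:3],
                      sim$collection$roles[1:3]), "intersection")
  reg <- pearson_residuals(reg)
  prog <- sim$truth$gene_programs
  frac_var <- function(gene_ids, prog_tag) {
    v <- apply(reg$norm_layer[, match(gene_ids, reg$gene_table$gene_id),
                              drop = FALSE], 2, var)
    tags <- prog$program[match(gene_ids, prog$gene_id)]
    sum(v[startsWith(tags, prog_tag)]) / sum(v)
  }
  res <- subtract_signature(reg, sig, T = 60, corr_threshold = 0.5)
  before_state <- frac_var(reg$gene_table$gene_id, "state:")
  after_state <- frac_var(res$retained, "state:")
  before_region <- frac_var(reg$gene_table$gene_id, "region:")
  after_region <- frac_var(res$retained, "region:")
  expect_lt(after_state, before_state)
  expect_gt(after_region, before_region)
})
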