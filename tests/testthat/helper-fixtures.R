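# Small in-code fixtures shared across test files.

# a tiny dataset with known counts
toy_dataset <- function(counts = matrix(c(1, 0, 2, 0, 3, 4), 2, 3),
                        gene_ids = c("mt-Nd1", "Rps1", "Actb")) {
  ExpressionDataset(counts,
                    data.frame(cell_id = sprintf("c%d", seq_len(nrow(counts)))),
                    data.frame(gene_id = gene_ids, symbol = gene_ids))
}

# small simulated collection (fast defaults for unit tests)
small_sim <- function(seed = 1, ...) {
  args <- list(n_regions = 3, n_regional_datasets = 3, n_reference_datasets = 1,
               cells_per_regional = 120, cells_per_reference = 200,
               n_genes = 300, m_region = 15, m_state = 30,
               doublet_rate = 0, ambient_fraction = 0, batch_sd = 0,
               seed = seed)
  args[names(list(...))] <- list(...)
  simulate_collection(do.call(simulation_spec, args))
}

# random labeled confusion-matrix expansion into label vectors
expand_confusion <- function(cm) {
  lev <- seq_len(nrow(cm))
  yt <- rep(rep(lev, ncol(cm)), as.vector(cm))
  yp <- rep(rep(lev, each = nrow(cm)), as.vector(cm))
  list(y_true = yt, y_pred = yp)
}

# rank-based AUROC
auroc <- function(score, label) {
  r <- rank(score)
  (mean(r[label]) - (sum(label) + 1) / 2) / sum(!label)
}
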