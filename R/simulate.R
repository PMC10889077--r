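# ---------------------------------------------------------------------------
# Synthetic multi-dataset single-cell counts with planted regional and
# functional-state gene programs.  The generator emulates the data regime the
# pipeline targets: several "regional" datasets (one spatial origin each, as
# with individual hypothalamic nuclei) plus whole-organ reference datasets
# mixing all regions, where per-cell state programs dominate variance and
# regional programs are faint, on top of batch effects, library-size
# variation, doublets and ambient contamination.
# ---------------------------------------------------------------------------

#' Specify a synthetic benchmark collection
#'
#' Counts are drawn from a negative binomial:
#' `x_cg ~ NB(mean = L_c * b_g * 2^(f * activity) * batch_dg * (1 - a)
#'            + a * A_g * L_c, dispersion theta_sim)`,
#' where `L_c` is the cell's library size (log-normal), `b_g` the baseline
#' relative abundance (log-normal, normalized to proportions), `activity`
#' indicates whether gene `g` belongs to the cell's region or state program,
#' `batch_dg` a per-dataset per-gene log-normal factor, and `A_g` the ambient
#' pseudo-bulk profile (the library-size-normalized baseline mean).
#'
#' The default benchmark plants 4 regions (25 genes each at log2 fold-change
#' 1.0) and 3 state programs (60 genes each at log2 fold-change 2.5), so
#' state programs dominate cross-cell variance: the regime in which naive
#' clustering recovers states, not regions.
#'
#' @param n_regions Number of regions R.
#' @param n_regional_datasets Number of single-region datasets (regions are
#'   assigned round-robin when this exceeds `n_regions`).
#' @param n_reference_datasets Number of whole-organ datasets mixing regions.
#' @param cells_per_regional,cells_per_reference Cells per dataset.
#' @param n_genes Gene universe size G.
#' @param m_region,f_region Genes per region program and its log2 fold-change.
#' @param n_states,m_state,f_state State program count, size, log2 fold-change.
#' @param state_probs Per-cell state probabilities (independent of region);
#'   default uniform over states.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline gene abundances before normalization.
#' @param libsize_meanlog,libsize_sdlog Log-normal parameters of per-cell
#'   library size (defaults give a median of ~5,000 UMI).
#' @param batch_sd Per-dataset per-gene log-normal sd of batch factors.
#' @param theta_sim Negative-binomial dispersion (size) parameter.
#' @param doublet_rate Fraction of droplets containing two cells.
#' @param ambient_fraction Ambient contamination fraction `a` in [0, 1).
#' @param seed Integer seed; the whole collection is deterministic under it.
#' @return A `SimulationSpec` list.
#' @export
simulation_spec <- function(n_regions = 4,
                            n_regional_datasets = 4,
                            n_reference_datasets = 2,
                            cells_per_regional = 1200,
                            cells_per_reference = 2500,
                            n_genes = 2000,
                            m_region = 25, f_region = 1.0,
                            n_states = 3, m_state = 60, f_state = 2.5,
                            state_probs = NULL,
                            baseline_meanlog = 0, baseline_sdlog = 1,
                            libsize_meanlog = log(5000), libsize_sdlog = 0.3,
                            batch_sd = 0.1,
                            theta_sim = 10,
                            doublet_rate = 0.05,
                            ambient_fraction = 0.05,
                            seed = 1L) {
  if (is.null(state_probs)) state_probs <- rep(1 / n_states, n_states)
  spec <- list(n_regions = n_regions,
               n_regional_datasets = n_regional_datasets,
               n_reference_datasets = n_reference_datasets,
               cells_per_regional = cells_per_regional,
               cells_per_reference = cells_per_reference,
               n_genes = n_genes, m_region = m_region, f_region = f_region,
               n_states = n_states, m_state = m_state, f_state = f_state,
               state_probs = state_probs,
               baseline_meanlog = baseline_meanlog,
               baseline_sdlog = baseline_sdlog,
               libsize_meanlog = libsize_meanlog,
               libsize_sdlog = libsize_sdlog,
               batch_sd = batch_sd, theta_sim = theta_sim,
               doublet_rate = doublet_rate,
               ambient_fraction = ambient_fraction, seed = as.integer(seed))
  class(spec) <- "SimulationSpec"
  n_prog <- n_regions * m_region + n_states * m_state
  if (n_prog > n_genes)
    stop("program gene sets (", n_prog, ") exceed the gene universe (", n_genes, ")")
  if (doublet_rate < 0 || doublet_rate >= 1) stop("doublet_rate must be in [0, 1)")
  if (ambient_fraction < 0 || ambient_fraction >= 1)
    stop("ambient_fraction must be in [0, 1)")
  if (abs(sum(state_probs) - 1) > 1e-8 || length(state_probs) != n_states)
    stop("state_probs must be a length-n_states probability vector")
  spec
}

#' Simulate a DatasetCollection with ground truth
#'
#' Regional datasets draw every cell from one region; reference datasets mix
#' cells from all regions uniformly.  Doublets are formed by summing the
#' counts of two random cells of the same dataset (the doublet keeps the
#' region label of its first parent: doublets are meant to be removed, not
#' classified).  Output is bitwise-deterministic under the spec seed.
#'
#' @param spec A `SimulationSpec` (see [simulation_spec()]).
#' @return List with `collection` (a `DatasetCollection`) and `truth`
#'   (a `GroundTruth` list: per-cell `cells` table with region/state/doublet
#'   labels, `gene_programs` map, and per-dataset `batch_factors`).
#' @export
simulate_collection <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  gene_ids <- sprintf("g%04d", seq_len(G))

  # disjoint program gene sets
  perm <- sample.int(G)
  take <- 0L
  region_sets <- lapply(seq_len(spec$n_regions), function(r) {
    idx <- perm[take + seq_len(spec$m_region)]; take <<- take + spec$m_region; idx
  })
  state_sets <- lapply(seq_len(spec$n_states), function(s) {
    idx <- perm[take + seq_len(spec$m_state)]; take <<- take + spec$m_state; idx
  })

  b <- rlnorm(G, spec$baseline_meanlog, spec$baseline_sdlog)
  b <- b / sum(b)
  ambient <- b   # pseudo-bulk of baseline means, library-size normalized

  region_names <- sprintf("region%d", seq_len(spec$n_regions))
  state_names <- sprintf("state%d", seq_len(spec$n_states))
  n_ds <- spec$n_regional_datasets + spec$n_reference_datasets
  ds_region <- c(rep_len(seq_len(spec$n_regions), spec$n_regional_datasets),
                 rep(NA_integer_, spec$n_reference_datasets))
  roles <- ifelse(is.na(ds_region), "reference",
                  paste0("regional:", region_names[ds_region]))
  ds_ids <- ifelse(is.na(ds_region),
                   sprintf("ref%02d", cumsum(is.na(ds_region))),
                   sprintf("reg%02d_%s", seq_len(n_ds),
                           region_names[pmax(ds_region, 1L)]))

  datasets <- vector("list", n_ds)
  truth_cells <- vector("list", n_ds)
  batch_factors <- vector("list", n_ds)
  a <- spec$ambient_fraction

  for (d in seq_len(n_ds)) {
    n <- if (is.na(ds_region[d])) spec$cells_per_reference else spec$cells_per_regional
    batch <- if (spec$batch_sd > 0) rlnorm(G, 0, spec$batch_sd) else rep(1, G)
    batch_factors[[d]] <- batch
    region <- if (is.na(ds_region[d])) sample.int(spec$n_regions, n, replace = TRUE)
              else rep(ds_region[d], n)
    state <- sample.int(spec$n_states, n, replace = TRUE, prob = spec$state_probs)
    L <- rlnorm(n, spec$libsize_meanlog, spec$libsize_sdlog)

    fold <- matrix(1, n, G)
    for (r in seq_len(spec$n_regions)) {
      hit <- region == r
      if (any(hit)) fold[hit, region_sets[[r]]] <- 2^spec$f_region
    }
    for (s in seq_len(spec$n_states)) {
      hit <- state == s
      if (any(hit)) fold[hit, state_sets[[s]]] <- fold[hit, state_sets[[s]]] * 2^spec$f_state
    }
    base_g <- b * batch
    mu <- (L * fold) * rep(base_g, each = n)            # n x G, col-major
    mu <- (1 - a) * mu + a * outer(L, ambient)
    x <- matrix(rnbinom(n * G, mu = as.vector(mu), size = spec$theta_sim), n, G)

    is_doublet <- rep(FALSE, n)
    n_doub <- round(spec$doublet_rate * n)
    if (n_doub > 0) {
      hosts <- sample.int(n, n_doub)
      partners <- sample.int(n, n_doub, replace = TRUE)
      same <- partners == hosts
      while (any(same)) {       # a doublet needs two distinct parents
        partners[same] <- sample.int(n, sum(same), replace = TRUE)
        same <- partners == hosts
      }
      x[hosts, ] <- x[hosts, , drop = FALSE] + x[partners, , drop = FALSE]
      is_doublet[hosts] <- TRUE
    }

    cell_ids <- sprintf("%s_c%05d", ds_ids[d], seq_len(n))
    cell_table <- data.frame(cell_id = cell_ids, dataset_id = ds_ids[d],
                             region_label = if (is.na(ds_region[d])) "unknown"
                                            else region_names[ds_region[d]],
                             condition = "unknown",
                             stringsAsFactors = FALSE)
    gene_table <- data.frame(gene_id = gene_ids, symbol = gene_ids,
                             is_mito = FALSE, is_ribo = FALSE,
                             is_hemoglobin = FALSE, stringsAsFactors = FALSE)
    datasets[[d]] <- ExpressionDataset(Matrix::Matrix(x, sparse = TRUE),
                                       cell_table, gene_table)
    datasets[[d]] <- add_provenance(datasets[[d]], "simulate_collection",
                                    list(dataset_id = ds_ids[d], seed = spec$seed))
    truth_cells[[d]] <- data.frame(cell_id = cell_ids, dataset_id = ds_ids[d],
                                   region = region_names[region],
                                   state = state_names[state],
                                   is_doublet = is_doublet,
                                   stringsAsFactors = FALSE)
  }

  program <- rep("baseline", G)
  for (r in seq_len(spec$n_regions)) program[region_sets[[r]]] <- paste0("region:", region_names[r])
  for (s in seq_len(spec$n_states)) program[state_sets[[s]]] <- paste0("state:", state_names[s])
  names(batch_factors) <- ds_ids

  truth <- structure(
    list(cells = do.call(rbind, truth_cells),
         gene_programs = data.frame(gene_id = gene_ids, program = program,
                                    stringsAsFactors = FALSE),
         batch_factors = batch_factors,
         spec = spec),
    class = "GroundTruth")
  list(collection = DatasetCollection(datasets, roles), truth = truth)
}

#' Summarize a GroundTruth object
#'
#' @param gt A `GroundTruth`.
#' @return List of summary tables: cells per region, per state, per dataset,
#'   doublet counts, and program sizes.  Counts sum to the total cell number.
#' @export
ground_truth_report <- function(gt) {
  stopifnot(inherits(gt, "GroundTruth"))
  cells <- gt$cells
  if (is.null(cells) || nrow(cells) == 0) {
    empty <- table(character(0))
    return(list(by_region = empty, by_state = empty, by_dataset = empty,
                doublets = empty, program_sizes = table(character(0))))
  }
  list(by_region = table(cells$region),
       by_state = table(cells$state),
       by_dataset = table(cells$dataset_id),
       doublets = table(cells$is_doublet),
       program_sizes = table(gt$gene_programs$program))
}
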