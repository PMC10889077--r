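#' @importFrom methods as is new
#' @importFrom stats coef cor dist lm.fit median p.adjust pbeta pchisq phyper
#'   pnorm prcomp predict pt quantile rbinom rlnorm rmultinom rnbinom rnorm
#'   runif sd setNames var kmeans qt
#' @importFrom utils head read.csv read.delim write.csv
NULL

# ---------------------------------------------------------------------------
# ExpressionDataset: sparse cell x gene UMI counts plus per-cell / per-gene
# metadata, an optional normalized layer, and an ordered provenance log.
# Cells are rows, genes are columns, everywhere in this package.
# ---------------------------------------------------------------------------

#' Construct an ExpressionDataset
#'
#' The universal data container of the package: a sparse cells-by-genes UMI
#' count matrix, a per-cell metadata table, a per-gene metadata table, an
#' optional normalized layer of the same shape, and an ordered provenance log
#' that records every operation applied to the object.
#'
#' @param counts Sparse (or dense) non-negative integer matrix, cells as rows,
#'   genes as columns. Coerced to `dgCMatrix`.
#' @param cell_table `data.frame` with one row per cell. Must contain
#'   `cell_id`; `dataset_id`, `region_label` and `condition` are created with
#'   the sentinel `"unknown"` when absent, so unlabeled reference datasets
#'   flow through the pipeline.
#' @param gene_table `data.frame` with one row per gene. Must contain
#'   `gene_id`; `symbol` defaults to `gene_id`; boolean flags `is_mito`,
#'   `is_ribo`, `is_hemoglobin` are derived from symbol prefixes
#'   (`mt-`/`Rps`/`Rpl`/`Hb`, case-insensitive) when absent.
#' @param norm_layer Optional numeric matrix of the same shape as `counts`
#'   (a normalized/residual layer).
#' @param provenance List of operation descriptors (each a list with at least
#'   `op` and `time`).
#'
#' @return An object of class `ExpressionDataset`.
#' @export
ExpressionDataset <- function(counts, cell_table, gene_table,
                              norm_layer = NULL, provenance = list()) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  cell_table <- as.data.frame(cell_table, stringsAsFactors = FALSE)
  gene_table <- as.data.frame(gene_table, stringsAsFactors = FALSE)
  cell_table <- .complete_cell_table(cell_table)
  gene_table <- .complete_gene_table(gene_table)
  rownames(counts) <- cell_table$cell_id
  colnames(counts) <- gene_table$gene_id
  ds <- structure(
    list(counts = counts, cell_table = cell_table, gene_table = gene_table,
         norm_layer = norm_layer, provenance = provenance),
    class = "ExpressionDataset")
  validate_dataset(ds)
  ds
}

.complete_cell_table <- function(ct) {
  if (is.null(ct$cell_id)) stop("cell_table must contain 'cell_id'")
  ct$cell_id <- as.character(ct$cell_id)
  for (col in c("dataset_id", "region_label", "condition")) {
    if (is.null(ct[[col]])) ct[[col]] <- "unknown"
  }
  ct
}

.complete_gene_table <- function(gt) {
  if (is.null(gt$gene_id)) stop("gene_table must contain 'gene_id'")
  gt$gene_id <- as.character(gt$gene_id)
  if (is.null(gt$symbol)) gt$symbol <- gt$gene_id
  if (is.null(gt$is_mito)) gt$is_mito <- grepl("^mt-", gt$symbol, ignore.case = TRUE)
  if (is.null(gt$is_ribo)) gt$is_ribo <- grepl("^Rp[sl]", gt$symbol, ignore.case = TRUE)
  if (is.null(gt$is_hemoglobin)) gt$is_hemoglobin <- grepl("^Hb", gt$symbol, ignore.case = TRUE)
  gt
}

#' Validate an ExpressionDataset
#'
#' Checks the container invariants: non-negative integral counts, metadata
#' tables aligned with the matrix dimensions, unique cell and gene
#' identifiers, and (when present) a norm layer of matching shape.
#' Duplicate gene ids are an error rather than being collapsed: silent
#' summation would corrupt downstream gene signatures.
#'
#' @param ds An `ExpressionDataset`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  x <- ds$counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  if (nrow(ds$cell_table) != nrow(ds$counts))
    stop("cell_table rows (", nrow(ds$cell_table), ") do not match matrix rows (",
         nrow(ds$counts), ")")
  if (nrow(ds$gene_table) != ncol(ds$counts))
    stop("gene_table rows (", nrow(ds$gene_table), ") do not match matrix columns (",
         ncol(ds$counts), ")")
  if (anyDuplicated(ds$cell_table$cell_id))
    stop("duplicate cell_id within dataset")
  if (anyDuplicated(ds$gene_table$gene_id))
    stop("duplicate gene_id (duplicates are an error, not collapsed)")
  if (!is.null(ds$norm_layer) &&
      !identical(dim(ds$norm_layer), dim(ds$counts)))
    stop("norm_layer shape does not match counts")
  invisible(TRUE)
}

#' @exportS3Method base::print
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  datasets: %s\n",
              paste(unique(x$cell_table$dataset_id), collapse = ", ")))
  cat(sprintf("  norm_layer: %s; provenance records: %d\n",
              if (is.null(x$norm_layer)) "none" else "present",
              length(x$provenance)))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Number of cells / genes in a dataset
#' @param ds An `ExpressionDataset`.
#' @return Integer count.
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$counts)

#' Append a provenance record
#'
#' @param ds An `ExpressionDataset`.
#' @param op Character scalar naming the operation.
#' @param params Named list of parameters worth auditing.
#' @return The dataset with one more provenance record.
#' @export
add_provenance <- function(ds, op, params = list()) {
  ds$provenance <- c(ds$provenance,
                     list(list(op = op, params = params,
                               time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))))
  ds
}

#' Subset an ExpressionDataset
#'
#' @param ds An `ExpressionDataset`.
#' @param cells Row index (logical, integer or cell_id character) or NULL.
#' @param genes Column index (logical, integer or gene_id character) or NULL.
#' @return The subsetted dataset, with a provenance record appended.
#' @export
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) seq_len(nrow(ds$counts)) else cells
  gi <- if (is.null(genes)) seq_len(ncol(ds$counts)) else genes
  if (is.character(ci)) ci <- match(ci, ds$cell_table$cell_id)
  if (is.character(gi)) gi <- match(gi, ds$gene_table$gene_id)
  out <- ds
  out$counts <- ds$counts[ci, gi, drop = FALSE]
  out$cell_table <- ds$cell_table[ci, , drop = FALSE]
  rownames(out$cell_table) <- NULL
  out$gene_table <- ds$gene_table[gi, , drop = FALSE]
  rownames(out$gene_table) <- NULL
  if (!is.null(ds$norm_layer))
    out$norm_layer <- ds$norm_layer[ci, gi, drop = FALSE]
  validate_dataset(out)
  add_provenance(out, "subset_dataset",
                 list(n_cells = nrow(out$counts), n_genes = ncol(out$counts)))
}

# ---------------------------------------------------------------------------
# DatasetCollection
# ---------------------------------------------------------------------------

#' Construct a DatasetCollection
#'
#' An ordered set of `ExpressionDataset`s with per-dataset role tags.
#' Regional datasets carry `"regional:<region_name>"` roles (one spatial
#' origin each, e.g. one hypothalamic nucleus); whole-organ datasets carry
#' `"reference"` roles and mix cells of all regions.  The signature workflow
#' requires at least one of each.
#'
#' @param datasets List of `ExpressionDataset`s.
#' @param roles Character vector, one per dataset: `"regional:<name>"` or
#'   `"reference"`.
#' @param ambient_variant Upstream ambient-removal tag, one of
#'   `"0.1"`, `"0.01"`, `"0.001"`, `"nc"` (nc = not corrected).
#' @return A `DatasetCollection`.
#' @export
DatasetCollection <- function(datasets, roles,
                              ambient_variant = c("nc", "0.1", "0.01", "0.001")) {
  ambient_variant <- match.arg(ambient_variant)
  stopifnot(length(datasets) == length(roles))
  ok <- grepl("^regional:.+$", roles) | roles == "reference"
  if (any(!ok)) stop("malformed role tag(s): ", paste(roles[!ok], collapse = ", "))
  structure(list(datasets = datasets, roles = roles,
                 ambient_variant = ambient_variant),
            class = "DatasetCollection")
}

#' @exportS3Method base::print
print.DatasetCollection <- function(x, ...) {
  cat(sprintf("DatasetCollection: %d datasets (ambient variant '%s')\n",
              length(x$datasets), x$ambient_variant))
  for (i in seq_along(x$datasets))
    cat(sprintf("  [%d] %-24s %6d cells x %d genes\n", i, x$roles[i],
                nrow(x$datasets[[i]]$counts), ncol(x$datasets[[i]]$counts)))
  invisible(x)
}

#' Indices of regional / reference datasets in a collection
#' @param collection A `DatasetCollection`.
#' @return Integer vector of positions.
#' @export
regional_indices <- function(collection) grep("^regional:", collection$roles)

#' @rdname regional_indices
#' @export
reference_indices <- function(collection) which(collection$roles == "reference")

#' Region name encoded in a regional role tag
#' @param collection A `DatasetCollection`.
#' @return Character vector (NA for reference datasets).
#' @export
collection_regions <- function(collection) {
  ifelse(grepl("^regional:", collection$roles),
         sub("^regional:", "", collection$roles), NA_character_)
}

# ---------------------------------------------------------------------------
# Matrix Market I/O (10x dialect)
# ---------------------------------------------------------------------------

#' Read an ExpressionDataset from Matrix Market files
#'
#' Reads a sparse count matrix with its features and barcodes TSVs (10x
#' dialect: `gene_id<TAB>symbol<TAB>type`).  The on-disk matrix may be stored
#' genes-by-cells (the common 10x convention) or cells-by-genes; orientation
#' is resolved against the features/barcodes lengths and normalized to
#' cells-as-rows.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path Path to the features TSV (one row per gene).
#' @param barcodes_path Path to the barcodes TSV (one row per cell).
#' @param metadata_path Optional CSV of per-cell metadata keyed by `cell_id`.
#' @return An `ExpressionDataset`.
#' @export
read_mtx_dataset <- function(matrix_path, features_path, barcodes_path,
                             metadata_path = NULL) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
  bcs <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)
  nf <- nrow(feats); nb <- nrow(bcs)
  if (nrow(m) == nf && ncol(m) == nb) {
    m <- Matrix::t(m)                       # 10x orientation: genes x cells
  } else if (!(nrow(m) == nb && ncol(m) == nf)) {
    stop(sprintf("matrix dimensions %dx%d match neither features (%d) x barcodes (%d) nor the transpose",
                 nrow(m), ncol(m), nf, nb))
  }
  if (length(m@x) && any(m@x != round(m@x)))
    stop("matrix contains non-integer entries")
  gene_table <- data.frame(gene_id = as.character(feats[[1]]),
                           symbol = if (ncol(feats) >= 2) as.character(feats[[2]]) else as.character(feats[[1]]),
                           stringsAsFactors = FALSE)
  cell_table <- data.frame(cell_id = as.character(bcs[[1]]),
                           stringsAsFactors = FALSE)
  if (!is.null(metadata_path) && file.exists(metadata_path)) {
    meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
    if (!is.null(meta$cell_id)) {
      idx <- match(cell_table$cell_id, meta$cell_id)
      for (col in setdiff(names(meta), "cell_id"))
        cell_table[[col]] <- meta[[col]][idx]
    }
  }
  ds <- ExpressionDataset(m, cell_table, gene_table)
  add_provenance(ds, "read_mtx_dataset", list(matrix_path = matrix_path))
}

#' Write an ExpressionDataset as Matrix Market files
#'
#' Writes `matrix.mtx` (genes-by-cells, 10x orientation), `features.tsv`,
#' `barcodes.tsv` and `metadata.csv` into `out_dir`.  When a norm layer is
#' present it is written as `norm_layer.mtx` (cells-by-genes, real-valued)
#' and flagged in the metadata header file.
#'
#' @param dataset An `ExpressionDataset`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_mtx_dataset <- function(dataset, out_dir) {
  validate_dataset(dataset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             metadata = file.path(out_dir, "metadata.csv"))
  Matrix::writeMM(Matrix::t(dataset$counts), paths["matrix"])
  gt <- dataset$gene_table
  write.table(data.frame(gt$gene_id, gt$symbol, "Gene Expression"),
              paths["features"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(dataset$cell_table$cell_id, paths["barcodes"], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.csv(dataset$cell_table, paths["metadata"], row.names = FALSE)
  if (!is.null(dataset$norm_layer)) {
    paths["norm_layer"] <- file.path(out_dir, "norm_layer.mtx")
    Matrix::writeMM(as(Matrix::Matrix(dataset$norm_layer, sparse = TRUE),
                       "generalMatrix"), paths["norm_layer"])
  }
  invisible(paths)
}

#' Concatenate the datasets of a collection into one matrix
#'
#' Cells are stacked in collection order.  Gene matching is by `gene_id`;
#' under `"intersection"` only shared genes are kept, under `"union"` genes
#' absent from a dataset are zero-filled (so total UMI is conserved exactly).
#'
#' @param collection A `DatasetCollection` (or plain list of datasets).
#' @param gene_policy `"intersection"` or `"union"`.
#' @return An `ExpressionDataset` covering all cells.
#' @export
concat_datasets <- function(collection, gene_policy = c("intersection", "union")) {
  gene_policy <- match.arg(gene_policy)
  datasets <- if (inherits(collection, "DatasetCollection"))
    collection$datasets else collection
  if (length(datasets) < 1) stop("need at least one dataset")
  gene_lists <- lapply(datasets, function(d) d$gene_table$gene_id)
  genes <- if (gene_policy == "intersection") Reduce(intersect, gene_lists)
           else Reduce(union, gene_lists)
  if (length(genes) == 0) stop("empty shared gene set under 'intersection'")
  blocks <- lapply(datasets, function(d) {
    idx <- match(genes, d$gene_table$gene_id)
    hit <- !is.na(idx)
    if (all(hit)) return(as(d$counts[, idx, drop = FALSE], "generalMatrix"))
    out <- Matrix::Matrix(0, nrow(d$counts), length(genes), sparse = TRUE)
    out[, hit] <- d$counts[, idx[hit], drop = FALSE]
    as(as(out, "CsparseMatrix"), "generalMatrix")
  })
  counts <- do.call(rbind, blocks)
  cell_tables <- lapply(seq_along(datasets), function(i) {
    ct <- datasets[[i]]$cell_table
    if (nrow(ct) > 0 && all(ct$dataset_id == "unknown"))
      ct$dataset_id <- paste0("ds", i)
    ct$cell_id <- paste(ct$dataset_id, ct$cell_id, sep = ":")
    ct
  })
  shared_cols <- Reduce(intersect, lapply(cell_tables, names))
  cell_table <- do.call(rbind, lapply(cell_tables, function(ct) ct[shared_cols]))
  ref <- datasets[[which.max(vapply(gene_lists, length, 1L))]]$gene_table
  gene_table <- ref[match(genes, ref$gene_id), , drop = FALSE]
  miss <- is.na(gene_table$gene_id)
  if (any(miss)) {           # gene ids only present in other datasets
    for (d in datasets) {
      idx <- match(genes[miss], d$gene_table$gene_id)
      found <- !is.na(idx)
      if (any(found)) {
        gene_table[which(miss)[found], ] <- d$gene_table[idx[found], names(gene_table)]
        miss <- is.na(gene_table$gene_id)
      }
      if (!any(miss)) break
    }
  }
  rownames(gene_table) <- NULL
  ds <- ExpressionDataset(counts, cell_table, gene_table)
  add_provenance(ds, "concat_datasets",
                 list(gene_policy = gene_policy, n_datasets = length(datasets)))
}
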