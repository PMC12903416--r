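# Data ingestion: MatrixMarket sparse counts with id files, delimited
# tables, marker-gene lists, and the dataset container used by the CLI.

#' Assemble a dataset container
#'
#' @param counts Cells-by-genes nonnegative integer matrix (dense or
#'   `Matrix` sparse).
#' @param cell_ids,gene_ids Unique identifiers (defaults from dimnames).
#' @param batch Optional data frame of categorical covariates per cell.
#' @param markers Named list of marker-gene symbol sets.
#' @return An object of class `curvae_dataset`.
#' @export
curvae_dataset <- function(counts, cell_ids = rownames(counts),
                           gene_ids = colnames(counts), batch = NULL,
                           markers = list()) {
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%d", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(ncol(counts)))
  if (anyDuplicated(cell_ids)) .err_invalid("cell ids must be unique")
  if (anyDuplicated(gene_ids)) .err_invalid("gene ids must be unique")
  v <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (any(v < 0) || any(abs(v - round(v)) > 1e-8))
    .err_invalid("counts must be nonnegative integers")
  if (!is.null(batch)) {
    batch <- as.data.frame(batch)
    if (nrow(batch) != nrow(counts)) .err_invalid("batch rows must match cells")
  }
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch = batch, markers = markers),
            class = "curvae_dataset")
}

#' Load a count matrix
#'
#' Supported formats: `"mtx-dir"` (a directory with `matrix.mtx` plus gene
#' and cell id files) and `"delimited"` (a TSV/CSV with cell ids in the
#' first column and genes in the header). Orientation is normalised to
#' cells x genes using the id-file lengths. HDF5 containers are not
#' supported by this build.
#'
#' @param path Directory (mtx-dir) or file (delimited).
#' @param format One of `"mtx-dir"`, `"delimited"`, `"h5-container"`.
#' @param batch_file Optional TSV of per-cell covariates (header row; rows
#'   aligned with cells).
#' @param marker_files Optional named character vector of marker-list paths.
#' @return A [curvae_dataset()].
#' @export
load_counts <- function(path, format = c("mtx-dir", "delimited", "h5-container"),
                        batch_file = NULL, marker_files = NULL) {
  format <- match.arg(format)
  if (format == "h5-container")
    .err_invalid("h5-container input is not supported by this build; export MTX instead")
  if (format == "mtx-dir") {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) .err_invalid(sprintf("missing %s", mtx))
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) .err_invalid(sprintf("malformed MTX: %s", conditionMessage(e))))
    gene_f <- Filter(file.exists, file.path(path, c("genes.tsv", "genes.txt", "features.tsv")))
    cell_f <- Filter(file.exists, file.path(path, c("barcodes.tsv", "cells.tsv", "cells.txt")))
    if (!length(gene_f) || !length(cell_f)) .err_invalid("missing gene or cell id file")
    genes <- readLines(gene_f[1]); cells <- readLines(cell_f[1])
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      # already cells x genes
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- Matrix::t(m)
    } else {
      .err_invalid(sprintf("matrix is %d x %d but ids imply %d cells x %d genes",
                           nrow(m), ncol(m), length(cells), length(genes)))
    }
    counts <- methods::as(m, "CsparseMatrix")
    dimnames(counts) <- list(cells, genes)
  } else {
    tab <- tryCatch(utils::read.delim(path, check.names = FALSE,
                                      sep = if (grepl("\\.csv$", path)) "," else "\t"),
                    error = function(e) .err_invalid(sprintf("malformed table: %s", conditionMessage(e))))
    cells <- as.character(tab[[1]])
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- cells
  }
  batch <- if (!is.null(batch_file))
    utils::read.delim(batch_file, check.names = FALSE, colClasses = "character") else NULL
  markers <- list()
  if (!is.null(marker_files)) {
    if (is.null(names(marker_files)))
      names(marker_files) <- tools::file_path_sans_ext(basename(marker_files))
    markers <- lapply(marker_files, read_marker_list)
  }
  curvae_dataset(counts, batch = batch, markers = markers)
}

#' Read a marker-gene list
#'
#' Plain text, one gene symbol per line; `#` starts a comment; blank lines
#' ignored. Symbols are case-sensitive.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_marker_list <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  unique(ln[nzchar(ln)])
}

#' Write a dataset as MatrixMarket plus id files
#'
#' Writes `matrix.mtx` (cells x genes, integer coordinate format),
#' `genes.tsv`, `barcodes.tsv`, and optionally `covariates.tsv` /
#' `truth.tsv`.
#'
#' @param dataset A [curvae_dataset()] (or list with `counts`).
#' @param dir Output directory (created).
#' @param truth Optional per-cell ground-truth data frame.
#' @return The directory, invisibly.
#' @export
write_counts_mtx <- function(dataset, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- dataset$counts
  sm <- methods::as(methods::as(Matrix::Matrix(cnt, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(dataset$gene_ids %||% colnames(cnt) %||% sprintf("gene%d", seq_len(ncol(cnt))),
             file.path(dir, "genes.tsv"))
  writeLines(dataset$cell_ids %||% rownames(cnt) %||% sprintf("cell%d", seq_len(nrow(cnt))),
             file.path(dir, "barcodes.tsv"))
  if (!is.null(dataset$batch))
    utils::write.table(dataset$batch, file.path(dir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    utils::write.table(truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add marker genes back to a highly-variable-gene selection
#'
#' Returns the union of the selected genes with every marker present in the
#' matrix, preserving the selection order; markers absent from `all_genes`
#' (when given) are dropped with a warning.
#'
#' @param selected_genes Character vector of selected (e.g. highly
#'   variable) genes.
#' @param marker_sets Character vector or list of character vectors.
#' @param all_genes Optional universe of matrix genes for validation.
#' @return Character vector: the augmented selection.
#' @export
augment_hvg_with_markers <- function(selected_genes, marker_sets, all_genes = NULL) {
  markers <- unique(unlist(marker_sets, use.names = FALSE))
  if (!is.null(all_genes)) {
    missing <- setdiff(markers, all_genes)
    if (length(missing))
      warning(sprintf("%d marker gene(s) absent from the matrix; excluded", length(missing)))
    markers <- intersect(markers, all_genes)
  }
  union(selected_genes, markers)
}
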