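#' Construct and validate a UMI count matrix
#'
#' A count matrix is a plain integer matrix with genes in rows and cells in
#' columns; row names are gene identifiers and column names are cell barcodes.
#' This constructor validates the invariants every function in the package
#' relies on: non-negative integral entries and unique gene/cell identifiers.
#'
#' @param counts numeric or integer matrix of UMI counts, genes x cells.
#' @param gene_ids optional character vector of gene identifiers; defaults to
#'   existing row names or `gene1..geneG`.
#' @param cell_ids optional character vector of cell identifiers; defaults to
#'   existing column names or `cell1..cellN`.
#' @return an integer matrix of class `count_matrix` with dimnames set.
#' @examples
#' m <- count_matrix(matrix(0:3, 2, 2))
#' cell_totals(m)
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(counts)
    if (is.null(gene_ids))
      gene_ids <- paste0("gene", seq_len(nrow(counts)), recycle0 = TRUE)
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(counts)
    if (is.null(cell_ids))
      cell_ids <- paste0("cell", seq_len(ncol(counts)), recycle0 = TRUE)
  }
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length does not match the number of rows")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length does not match the number of columns")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.double(counts)) {
    if (any(abs(counts - round(counts)) > 1e-8))
      stop("counts must be integral")
    storage.mode(counts) <- "integer"
  }
  dimnames(counts) <- list(as.character(gene_ids), as.character(cell_ids))
  class(counts) <- c("count_matrix", class(matrix()))
  counts
}

#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("count_matrix", class(matrix()))
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("UMI count matrix: %d genes x %d cells, %d non-zero entries\n",
              nrow(x), ncol(x), sum(x > 0)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  invisible(x)
}

#' Read a genes-by-cells UMI count matrix
#'
#' Supports the Cell Ranger style Matrix Market triplet layout (a `.mtx` file
#' with `genes.tsv`/`features.tsv` and `barcodes.tsv` companions in the same
#' directory) and dense delimited text (genes in rows, header row of cell
#' identifiers, first column of gene identifiers).
#'
#' @param path for `format = "mtx"`, the `.mtx` file (companions are located
#'   next to it); for `format = "dense"`, a TSV/CSV file.
#' @param format `"mtx"` or `"dense"`.
#' @param sep field separator for dense input; default tab.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("mtx", "dense"), sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    dir <- dirname(path)
    gene_file <- NULL
    for (cand in c("genes.tsv", "features.tsv")) {
      f <- file.path(dir, cand)
      if (file.exists(f)) { gene_file <- f; break }
    }
    barcode_file <- file.path(dir, "barcodes.tsv")
    if (is.null(gene_file))
      stop("missing companion gene list (genes.tsv or features.tsv) next to ", path)
    if (!file.exists(barcode_file))
      stop("missing companion barcodes.tsv next to ", path)
    m <- as.matrix(Matrix::readMM(path))
    # companion files may be 1-column (id) or multi-column (id, symbol, ...);
    # the first column is always the identifier
    genes <- utils::read.table(gene_file, sep = "\t", header = FALSE,
                               colClasses = "character")[[1L]]
    cells <- utils::read.table(barcode_file, sep = "\t", header = FALSE,
                               colClasses = "character")[[1L]]
    count_matrix(m, gene_ids = genes, cell_ids = cells)
  } else {
    tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                             check.names = FALSE)
    count_matrix(as.matrix(tab))
  }
}

#' Write a UMI count matrix
#'
#' Inverse of [read_count_matrix()]; round-trips exactly.
#'
#' @param matrix a [count_matrix()].
#' @param path output `.mtx` file (companions written alongside) or dense text
#'   file.
#' @param format `"mtx"` or `"dense"`.
#' @param sep field separator for dense output.
#' @export
write_count_matrix <- function(matrix, path, format = c("mtx", "dense"),
                               sep = "\t") {
  format <- match.arg(format)
  matrix <- count_matrix(matrix)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass(matrix), sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(matrix), file.path(dir, "genes.tsv"))
    writeLines(colnames(matrix), file.path(dir, "barcodes.tsv"))
  } else {
    df <- as.data.frame(unclass(matrix), check.names = FALSE)
    df <- cbind(gene = rownames(matrix), df)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter genes by the number of cells with a non-zero count
#'
#' Keeps genes detected (count > 0) in at least `min_nonzero_cells` cells.
#' Model selection conventionally uses a threshold of 5 ("at least five
#' non-zero cells"); the goodness-of-fit pipeline uses 6 ("more than five").
#'
#' @param matrix a [count_matrix()].
#' @param min_nonzero_cells non-negative integer threshold.
#' @return the filtered [count_matrix()], gene order preserved.
#' @export
filter_genes <- function(matrix, min_nonzero_cells = 5L) {
  stopifnot(min_nonzero_cells >= 0)
  matrix <- count_matrix(matrix)
  keep <- rowSums(matrix > 0L) >= min_nonzero_cells
  matrix[keep, , drop = FALSE]
}

#' Per-cell total UMI counts
#'
#' The column sums n_i, used as the default size factor (offset log n_i) in
#' the NBID regression.
#'
#' @param matrix a [count_matrix()].
#' @return named integer vector of per-cell totals.
#' @export
cell_totals <- function(matrix) {
  matrix <- count_matrix(matrix)
  totals <- colSums(unclass(matrix))
  storage.mode(totals) <- "integer"
  totals
}

#' Per-gene, per-group TPM-like abundance
#'
#' For UMI data, abundance is the pooled within-group count proportion scaled
#' to one million: 1e6 * sum(counts of gene in group) / sum(all counts in
#' group). No transcript-length correction is applied (3'-end UMI counting
#' measures molecules, not read coverage).
#'
#' @param matrix a [count_matrix()].
#' @param groups vector of group labels, one per cell.
#' @return numeric matrix, genes x groups, of TPM values. Groups with zero
#'   total UMIs yield `NaN` columns, with a warning.
#' @export
tpm_per_group <- function(matrix, groups) {
  matrix <- count_matrix(matrix)
  if (length(groups) != ncol(matrix))
    stop("groups must assign one label per cell")
  groups <- factor(groups)
  out <- vapply(levels(groups), function(g) {
    sub <- unclass(matrix)[, groups == g, drop = FALSE]
    tot <- sum(sub)
    1e6 * rowSums(sub) / tot
  }, numeric(nrow(matrix)))
  dim(out) <- c(nrow(matrix), nlevels(groups))
  dimnames(out) <- list(rownames(matrix), levels(groups))
  if (anyNA(out)) warning("group with zero total UMIs: abundance undefined")
  out
}

#' Write a result table as tab-delimited text
#'
#' Writes any of the package's per-gene result tables (model selection,
#' goodness of fit, differential expression) with a header row and a fixed
#' column order; numeric values keep full precision.
#'
#' @param records a data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  if (ncol(records) == 0L) stop("records must have at least one column")
  utils::write.table(format(records, digits = 15, trim = TRUE, scientific = 10),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path input path.
#' @return a data.frame.
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
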