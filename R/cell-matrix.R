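#' Segmented-cell count matrix with centroids
#'
#' Holds raw integer gene counts for segmented cells together with their
#' centroid coordinates (um). Entries can be *missing* (`NA`), which is
#' distinct from an observed zero: the marker panel varies across samples,
#' and the missingness filter ([filter_matrix()]) operates on that
#' distinction before missing values are imputed to 0.
#'
#' @param counts Integer matrix, cells x genes; `NA` marks a missing
#'   (unmeasured) entry. Column names are gene symbols.
#' @param cells Data frame with one row per cell: columns `cell` (id),
#'   `x`, `y` (centroid, um).
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cells) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix.")
  if (any(counts < 0, na.rm = TRUE)) abort("negative counts are not allowed.")
  if (any(counts != round(counts), na.rm = TRUE)) abort("counts must be integers.")
  if (is.null(colnames(counts))) abort("`counts` must have gene column names.")
  cells <- as_tibble(cells)
  if (!all(c("cell", "x", "y") %in% names(cells))) {
    abort("`cells` must have columns cell, x, y.")
  }
  if (nrow(cells) != nrow(counts)) {
    abort(sprintf("dimension mismatch: %d matrix rows vs %d cell metadata rows.",
                  nrow(counts), nrow(cells)))
  }
  rownames(counts) <- cells$cell
  structure(list(counts = counts, cells = cells), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes (%d missing entries)\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Read a segmented-cell matrix from an MTX trio
#'
#' Reads a MatrixMarket sparse count file plus gene and cell metadata.
#' Entries *absent* from the sparse file are recorded as missing (`NA`),
#' not zero; explicitly stored zeros are observed zeros. The matrix file is
#' genes x cells (the common single-cell export layout) and is transposed
#' on read.
#'
#' @param matrix_path Path to the .mtx file (genes x cells).
#' @param genes_path Path to a headerless one-column gene list (TSV).
#' @param cells_path Path to cell metadata with header `cell`, `x`, `y`
#'   (TSV; coordinates in um).
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(matrix_path, genes_path, cells_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- read.delim(genes_path, header = FALSE, colClasses = "character")[[1]]
  cells <- as_tibble(read.delim(cells_path, header = TRUE))
  if (!all(c("cell", "x", "y") %in% names(cells))) {
    abort("cell metadata must have columns cell, x, y.")
  }
  if (nrow(m) != length(genes)) {
    abort(sprintf("dimension mismatch: %d matrix rows vs %d genes.",
                  nrow(m), length(genes)))
  }
  if (ncol(m) != nrow(cells)) {
    abort(sprintf("dimension mismatch: %d matrix columns vs %d cell metadata rows.",
                  ncol(m), nrow(cells)))
  }
  m <- methods::as(m, "TsparseMatrix")
  if (any(m@x < 0)) abort("negative counts are not allowed.")
  counts <- matrix(NA_real_, nrow(cells), length(genes),
                   dimnames = list(cells$cell, genes))
  # stored entries (including explicit zeros) are observations
  counts[cbind(m@j + 1L, m@i + 1L)] <- m@x
  cell_matrix(counts, cells)
}

#' Write a segmented-cell matrix as an MTX trio
#'
#' Observed entries (including observed zeros) are stored explicitly;
#' missing (`NA`) entries are omitted, so [read_cell_matrix()] round-trips
#' the missingness pattern.
#'
#' @param cm A [cell_matrix()].
#' @param matrix_path,genes_path,cells_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_cell_matrix <- function(cm, matrix_path, genes_path, cells_path) {
  stopifnot(inherits(cm, "cell_matrix"))
  obs <- which(!is.na(cm$counts), arr.ind = TRUE)
  m <- Matrix::sparseMatrix(
    i = obs[, 2], j = obs[, 1], x = cm$counts[obs],
    dims = c(ncol(cm$counts), nrow(cm$counts)), repr = "T"
  )
  Matrix::writeMM(m, matrix_path)
  writeLines(colnames(cm$counts), genes_path)
  utils::write.table(cm$cells, cells_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(matrix_path)
}
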