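#' Layered spliced/unspliced count container
#'
#' Bundles a genes x cells spliced count matrix, a matching unspliced matrix,
#' and per-cell metadata into a single object. This is the substrate of all
#' transcriptome stages: QC filtering, embedding, velocity estimation.
#'
#' @param spliced genes x cells matrix of nonnegative integer spliced UMI
#'   counts. Rownames are gene identifiers, colnames cell identifiers.
#' @param unspliced matrix of identical shape with unspliced counts.
#' @param cell_metadata data frame with one row per cell (column `cell_id`
#'   matching the matrix colnames plus arbitrary categorical columns such as
#'   `age`, `lrc`, `timepoint`). QC columns (`total_umis`, `genes_detected`,
#'   `mito_fraction`) are computed from the spliced layer when absent;
#'   `mito_fraction` falls back to 0 when no gene id starts with "mt-".
#'
#' @return An object of class `layered_counts`: a list with elements
#'   `spliced`, `unspliced` (genes x cells matrices) and `cell_metadata`
#'   (a tibble).
#' @export
layered_counts <- function(spliced, unspliced, cell_metadata = NULL) {
  if (!all(dim(spliced) == dim(unspliced))) {
    abort("`spliced` and `unspliced` must have identical dimensions.")
  }
  if (is.null(rownames(spliced))) {
    rownames(spliced) <- paste0("gene", seq_len(nrow(spliced)))
  }
  if (is.null(colnames(spliced))) {
    colnames(spliced) <- paste0("cell", seq_len(ncol(spliced)))
  }
  dimnames(unspliced) <- dimnames(spliced)
  if (anyDuplicated(rownames(spliced))) {
    abort("duplicate gene ids in `spliced`.")
  }
  if (min(spliced) < 0 || min(unspliced) < 0) {
    abort("count layers must be nonnegative.")
  }
  if (is.null(cell_metadata)) {
    cell_metadata <- tibble(cell_id = colnames(spliced))
  }
  cell_metadata <- as_tibble(cell_metadata)
  if (!"cell_id" %in% names(cell_metadata)) {
    cell_metadata$cell_id <- colnames(spliced)
  }
  if (!identical(as.character(cell_metadata$cell_id), colnames(spliced))) {
    abort("`cell_metadata$cell_id` must match the column order of the layers.")
  }
  x <- structure(
    list(spliced = spliced, unspliced = unspliced,
         cell_metadata = cell_metadata),
    class = "layered_counts"
  )
  add_qc_columns(x)
}

add_qc_columns <- function(x) {
  md <- x$cell_metadata
  if (!"total_umis" %in% names(md)) {
    md$total_umis <- Matrix::colSums(x$spliced)
  }
  if (!"genes_detected" %in% names(md)) {
    md$genes_detected <- Matrix::colSums(x$spliced > 0)
  }
  if (!"mito_fraction" %in% names(md)) {
    mito <- grepl("^mt-", rownames(x$spliced), ignore.case = TRUE)
    tot <- Matrix::colSums(x$spliced)
    frac <- if (any(mito)) Matrix::colSums(x$spliced[mito, , drop = FALSE]) / pmax(tot, 1) else 0
    md$mito_fraction <- as.numeric(frac)
  }
  stopifnot(all(md$mito_fraction >= 0 & md$mito_fraction <= 1))
  x$cell_metadata <- md
  x
}

#' @export
print.layered_counts <- function(x, ...) {
  cat(sprintf("<layered_counts> %d genes x %d cells\n",
              nrow(x$spliced), ncol(x$spliced)))
  cat("metadata columns:", paste(names(x$cell_metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.layered_counts <- function(x) dim(x$spliced)

#' Write / read a layered count matrix as MTX + TSV
#'
#' One MatrixMarket file per layer (`spliced.mtx`, `unspliced.mtx`), gene ids
#' in `genes.tsv`, and cell metadata in `cells.tsv`.
#'
#' @param x a [layered_counts()] object.
#' @param dir directory to write to (created if missing).
#' @return `write_layered` returns `dir` invisibly; `read_layered` returns a
#'   [layered_counts()] object.
#' @export
write_layered <- function(x, dir) {
  stopifnot(inherits(x, "layered_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(x$spliced, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "spliced.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(x$unspliced, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "unspliced.mtx"))
  utils::write.table(data.frame(gene_id = rownames(x$spliced)),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(x$cell_metadata), file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_layered
#' @export
read_layered <- function(dir) {
  spliced <- as.matrix(Matrix::readMM(file.path(dir, "spliced.mtx")))
  unspliced <- as.matrix(Matrix::readMM(file.path(dir, "unspliced.mtx")))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), header = TRUE, sep = "\t")
  cells <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE, sep = "\t")
  rownames(spliced) <- genes$gene_id
  colnames(spliced) <- cells$cell_id
  layered_counts(spliced, unspliced, as_tibble(cells))
}

#' Read and write motility tracks as CSV
#'
#' Plain CSV with columns `cell_id`, `frame`, `x_um`, `y_um` (and any
#' extras, e.g. `group`).
#'
#' @param tracks a tracks tibble.
#' @param path CSV file path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a tibble.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  as_tibble(utils::read.csv(path))
}
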