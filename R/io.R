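#' Write / read an expression matrix as MatrixMarket
#'
#' Writes `<prefix>.mtx` (genes stored column-wise as written, cells as
#' rows) with sidecar `<prefix>.cells.txt` and `<prefix>.genes.txt`
#' identifier files — the plain-text exchange format for sparse count
#' matrices.
#'
#' @param matrix cells x genes matrix with dimnames.
#' @param prefix path prefix (no extension).
#' @return the prefix, invisibly.
#' @export
write_counts_mtx <- function(matrix, prefix) {
  check_count_matrix(matrix)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(matrix), "CsparseMatrix"), "generalMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(matrix), paste0(prefix, ".cells.txt"))
  writeLines(colnames(matrix), paste0(prefix, ".genes.txt"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".cells.txt"))
  colnames(m) <- readLines(paste0(prefix, ".genes.txt"))
  check_count_matrix(m)
  m
}

#' Write / read an expression matrix as dense CSV
#'
#' Cells as rows (first column `cell_id`), genes as columns; for small
#' fixtures and interchange with spreadsheet-shaped exports.
#'
#' @param matrix cells x genes matrix with dimnames.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_counts_csv <- function(matrix, path) {
  check_count_matrix(matrix)
  df <- data.frame(cell_id = rownames(matrix), matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  check_count_matrix(m)
  m
}

#' Write / read a cell annotation as 2-column TSV
#'
#' Columns `cell_id` and `type_label` (extra columns such as `group_label`
#' are preserved).
#'
#' @param annotation annotation tibble.
#' @param path TSV file path.
#' @return the path, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  stopifnot(all(c("cell_id", "type_label") %in% names(annotation)))
  utils::write.table(annotation, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
}

#' Load a real count matrix through a dataset manifest
#'
#' Optional entry point for public datasets exported as text: a
#' MatrixMarket prefix or a dense CSV, plus a label TSV. The loaded
#' matrix's zero fraction is reported and, when `expected_zero_fraction`
#' is given, validated within ±0.5 percentage points — a checksum-style
#' guard for known datasets (droplet-based sets typically sit around
#' 45–62% zeros). Real matrices arrive with their native sparsity as the
#' baseline, so dropout targets below it are warning no-ops.
#'
#' @param manifest list with `path` (MTX prefix or CSV file), `format`
#'   (`"mtx"` or `"csv"`), `labels` (TSV path), and optionally
#'   `expected_zero_fraction`.
#' @return list with `counts`, `annotation`, `zero_fraction`.
#' @export
load_counts <- function(manifest) {
  stopifnot(is.list(manifest), !is.null(manifest$path), !is.null(manifest$format))
  m <- switch(manifest$format,
    mtx = read_counts_mtx(manifest$path),
    csv = read_counts_csv(manifest$path),
    abort(sprintf("unsupported format '%s' (use mtx or csv)", manifest$format))
  )
  if (is.null(manifest$labels)) abort("manifest must name a `labels` TSV")
  ann <- read_annotation_tsv(manifest$labels)
  if (!all(rownames(m) %in% ann$cell_id)) {
    abort("label file does not cover every cell in the matrix")
  }
  ann <- ann[match(rownames(m), ann$cell_id), ]
  zf <- zero_fraction(m)
  inform(sprintf("loaded %d cells x %d genes, zero fraction %.3f",
                 nrow(m), ncol(m), zf))
  if (!is.null(manifest$expected_zero_fraction)) {
    if (abs(zf - manifest$expected_zero_fraction) > 0.005) {
      abort(sprintf(
        "zero fraction %.4f differs from expected %.4f by more than 0.005",
        zf, manifest$expected_zero_fraction))
    }
  }
  list(counts = m, annotation = ann, zero_fraction = zf)
}
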