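#' Read a UMI count matrix
#'
#' Reads a background-filtered, genes x cells UMI count matrix for a single
#' sample from either MatrixMarket sparse triplet format (with gene/barcode
#' sidecar files, CellRanger convention) or a dense CSV (first column gene
#' ids, header row of cell ids).
#'
#' @param path Path to the `.mtx` or `.csv` file.
#' @param fmt One of `"auto"` (by extension), `"mtx"`, `"csv"`.
#' @param genes_file,barcodes_file Optional explicit sidecar paths for MTX
#'   input. By default `genes.tsv`/`features.tsv` and `barcodes.tsv` next to
#'   the matrix file are used.
#' @param transpose For MTX input whose rows are cells rather than genes.
#' @return A sparse `dgCMatrix` (genes x cells) with unique row and column
#'   names, non-negative integral entries.
#' @export
read_counts <- function(path, fmt = c("auto", "mtx", "csv"),
                        genes_file = NULL, barcodes_file = NULL,
                        transpose = FALSE) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort(paste0("count file not found: ", path))
  if (fmt == "auto") {
    fmt <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  }
  if (fmt == "mtx") {
    m <- Matrix::readMM(path)
    m <- as(m * 1, "CsparseMatrix") # pattern/logical MTX -> numeric
    if (isTRUE(transpose)) m <- Matrix::t(m)
    dir <- dirname(path)
    if (is.null(genes_file)) {
      for (cand in c("genes.tsv", "features.tsv")) {
        if (file.exists(file.path(dir, cand))) {
          genes_file <- file.path(dir, cand)
          break
        }
      }
    }
    if (is.null(barcodes_file) && file.exists(file.path(dir, "barcodes.tsv"))) {
      barcodes_file <- file.path(dir, "barcodes.tsv")
    }
    if (is.null(genes_file) || is.null(barcodes_file)) {
      abort("mtx input needs gene and barcode sidecar files (genes.tsv/features.tsv, barcodes.tsv)")
    }
    genes <- utils::read.delim(genes_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(barcodes_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      abort(sprintf(
        "sidecar lengths (%d genes, %d barcodes) do not match matrix (%d x %d)",
        length(genes), length(cells), nrow(m), ncol(m)))
    }
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    num <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(num) <- "double"
    rownames(num) <- genes
    m <- as(Matrix::Matrix(num, sparse = TRUE), "CsparseMatrix")
  }
  validate_counts(m)
  m
}

#' Validate a count matrix
#'
#' Checks the count-matrix contract: non-negative integral entries and unique
#' gene/cell identifiers. Errors name the first offending entry.
#'
#' @param m A matrix or sparse Matrix, genes x cells, with dimnames.
#' @return The matrix as a `dgCMatrix`, invisibly valid.
#' @export
validate_counts <- function(m) {
  if (!inherits(m, "CsparseMatrix")) {
    m <- as(Matrix::Matrix(as.matrix(m), sparse = TRUE), "CsparseMatrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("count matrix must carry gene rownames and cell colnames")
  }
  x <- m@x
  bad <- which(x < 0 | x != floor(x))
  if (length(bad)) {
    ij <- sparse_coord(m, bad[1])
    abort(sprintf(
      "count matrix has a negative or non-integer entry %g at (gene %s, cell %s)",
      x[bad[1]], rownames(m)[ij[1]], colnames(m)[ij[2]]))
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g)) {
    abort(paste0("duplicate gene ids: ", paste(utils::head(dup_g, 5), collapse = ", ")))
  }
  dup_c <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_c)) {
    abort(paste0("duplicate cell ids: ", paste(utils::head(dup_c, 5), collapse = ", ")))
  }
  m
}

# (row, col) of the k-th stored element of a CsparseMatrix
sparse_coord <- function(m, k) {
  col <- which(m@p[-1] >= k)[1]
  row <- m@i[k] + 1L
  c(row, col)
}

#' Write a count matrix as MatrixMarket + sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` into `dir`, the layout
#' [read_counts()] reads back.
#'
#' @param m Count matrix (genes x cells) with dimnames.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(m, dir) {
  m <- validate_counts(m)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
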