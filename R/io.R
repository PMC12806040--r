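# Readers and writers for count and expression matrices.

#' Read a count matrix from CSV/TSV or MatrixMarket files
#'
#' Dense CSV/TSV files are read with the first column as row identifiers and
#' the header as column identifiers. `genes_in_rows = TRUE` (the common export
#' convention) transposes the result so the returned matrix is cells x genes.
#' For MatrixMarket input, `path` is the `.mtx` file and barcode/feature
#' sidecar files are looked up in the same directory (`barcodes.tsv` and
#' `features.tsv` or `genes.tsv`) unless given explicitly; the matrix is
#' assumed genes-in-rows as in the 10x convention.
#'
#' @param path file to read.
#' @param format one of "auto" (by extension), "csv", "tsv", "mtx".
#' @param genes_in_rows does the stored matrix have genes in rows? Default TRUE.
#' @param barcodes,features optional explicit sidecar paths for mtx input.
#' @return a cells x genes count matrix (see [count_matrix()]).
#' @export
read_counts <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                        genes_in_rows = TRUE,
                        barcodes = NULL, features = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    if (is.null(barcodes)) {
      barcodes <- file.path(dir, "barcodes.tsv")
    }
    if (is.null(features)) {
      features <- file.path(dir, "features.tsv")
      if (!file.exists(features)) features <- file.path(dir, "genes.tsv")
    }
    gene_ids <- if (file.exists(features)) {
      readLines(features)
    } else paste0("gene_", seq_len(nrow(m)))
    cell_ids <- if (file.exists(barcodes)) {
      readLines(barcodes)
    } else paste0("cell_", seq_len(ncol(m)))
    gene_ids <- vapply(strsplit(gene_ids, "\t"), `[`, "", 1L)
    cell_ids <- vapply(strsplit(cell_ids, "\t"), `[`, "", 1L)
    dimnames(m) <- list(gene_ids, cell_ids)
    return(count_matrix(t(m)))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  m <- as.matrix(df)
  if (genes_in_rows) m <- t(m)
  count_matrix(m)
}

#' Write a count matrix as MatrixMarket + sidecars
#'
#' Writes `<path>` (mtx, genes in rows per the 10x convention) plus
#' `barcodes.tsv` and `features.tsv` in the same directory.
#'
#' @param counts cells x genes count matrix.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(counts, path) {
  counts <- count_matrix(counts)
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE), path)
  dir <- dirname(path)
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  invisible(path)
}

#' Write a preprocessed expression matrix to CSV
#'
#' The applied preprocessing steps are recorded as a `# steps:` comment line
#' before the header, so the file round-trips through [read_expression()].
#'
#' @param mat expression matrix with a `steps` attribute.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  steps <- attr(mat, "steps")
  if (!is.null(steps)) {
    writeLines(paste0("# steps: ", paste(steps, collapse = ",")), con)
  }
  utils::write.csv(as.data.frame(as.matrix(mat)), con, row.names = TRUE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param path CSV path.
#' @return the matrix, with the recorded `steps` attribute restored.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1)
  steps <- NULL
  if (startsWith(first, "# steps:")) {
    steps <- strsplit(trimws(sub("# steps:", "", first)), ",")[[1]]
  }
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        comment.char = "#")
  m <- as.matrix(df)
  attr(m, "steps") <- steps
  m
}
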