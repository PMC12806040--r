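# Preprocessing: raw counts -> normalized, HVG-restricted, gene-standardized matrix.
#
# Throughout the package a count matrix is a base numeric matrix with cells in
# rows and genes in columns; rownames are cell identifiers, colnames are gene
# identifiers. Preprocessing functions carry an ordered record of the
# transforms performed in attr(x, "steps").

#' Validate and construct a cell x gene count matrix
#'
#' Checks that `values` is a non-negative integer-valued matrix and attaches
#' unique cell and gene identifiers as dimnames.
#'
#' @param values numeric matrix, cells in rows, genes in columns; entries must
#'   be non-negative integers (stored as numeric is fine).
#' @param cell_ids,gene_ids optional character vectors of unique identifiers;
#'   default to existing dimnames or generated `cell_i` / `gene_j` labels.
#' @return the validated matrix with dimnames set.
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("count matrix must be numeric")
  if (anyNA(values)) stop("count matrix contains NA")
  if (any(values < 0)) stop("count matrix has negative entries")
  if (any(values != round(values))) stop("count matrix has non-integer entries")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  }
  if (length(cell_ids) != nrow(values)) stop("cell_ids length != number of rows")
  if (length(gene_ids) != ncol(values)) stop("gene_ids length != number of columns")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  dimnames(values) <- list(cell_ids, gene_ids)
  values
}

add_step <- function(x, step) {
  attr(x, "steps") <- c(attr(x, "steps"), step)
  x
}

#' Transforms applied to a preprocessed matrix
#'
#' @param x a matrix returned by the preprocessing functions.
#' @return character vector of step tags, in the order applied.
#' @export
steps_applied <- function(x) attr(x, "steps")

#' Filter genes and cells from a raw count matrix
#'
#' Discards genes expressed (count > 0) in fewer than `min_cells` cells, then
#' cells whose total count over the retained genes is below `min_counts`.
#' Defaults implement the usual rule: drop genes seen in fewer than two cells
#' and cells with no expression at all. Survivor order is preserved, so the
#' operation is a projection (applying it twice equals applying it once).
#'
#' @param raw count matrix, cells x genes (see [count_matrix()]).
#' @param min_cells minimum number of cells a gene must be expressed in.
#' @param min_counts minimum total count a cell must retain.
#' @return the filtered count matrix with a `"filter"` step recorded.
#' @export
filter_counts <- function(raw, min_cells = 2, min_counts = 1) {
  raw <- count_matrix(raw)
  keep_genes <- colSums(raw > 0) >= min_cells
  if (!any(keep_genes)) {
    stop("degenerate input: all genes removed by the expressed-in-fewer-than-",
         min_cells, "-cells filter (gene axis empty)")
  }
  out <- raw[, keep_genes, drop = FALSE]
  keep_cells <- rowSums(out) >= min_counts
  if (!any(keep_cells)) {
    stop("degenerate input: all cells removed by the total-count filter ",
         "(cell axis empty)")
  }
  out <- out[keep_cells, , drop = FALSE]
  add_step(out, "filter")
}

#' Library-size log-normalization
#'
#' Scales each cell to the median library size and log-transforms:
#' `x_ij = ln((s_mid / s_i) * y_ij + 1)` where `s_i` is the total count of
#' cell i and `s_mid = median(s)`. Zero counts map to zero; the transform is
#' strictly increasing within each cell.
#'
#' @param filtered count matrix with every cell total positive (the output of
#'   [filter_counts()]).
#' @return list with `mat` (the log-normalized matrix, `"lognormalize"` step
#'   recorded) and `size_factors` (list with per-cell totals `s` and their
#'   median `s_mid`).
#' @export
lognormalize <- function(filtered) {
  filtered <- as.matrix(filtered)
  s <- rowSums(filtered)
  if (any(s <= 0)) {
    stop("precondition violated: cell(s) with zero total count (run ",
         "filter_counts() first): ",
         paste(utils::head(which(s <= 0), 5), collapse = ", "))
  }
  s_mid <- stats::median(s)
  mat <- log1p((s_mid / s) * filtered)
  dimnames(mat) <- dimnames(filtered)
  attr(mat, "steps") <- attr(filtered, "steps")
  list(mat = add_step(mat, "lognormalize"),
       size_factors = list(s = s, s_mid = s_mid))
}

#' Per-gene dispersion of a (log-normalized) expression matrix
#'
#' variance / mean of each gene across cells; genes with non-positive mean get
#' dispersion -Inf so they rank last.
#'
#' @param mat expression matrix, cells x genes.
#' @return numeric vector of dispersions, one per gene.
#' @export
gene_dispersion <- function(mat) {
  mu <- colMeans(mat)
  v <- colMeans(mat^2) - mu^2
  d <- ifelse(mu > 0, v / mu, -Inf)
  names(d) <- colnames(mat)
  d
}

#' Select highly variable genes
#'
#' Keeps the `n_hvg` genes with the highest dispersion, in descending rank
#' order; ties are broken by original column index (lower index wins). When
#' fewer genes exist the matrix is returned reordered with a warning.
#'
#' @param mat expression matrix (typically log-normalized), cells x genes.
#' @param n_hvg number of genes to retain (default 2000).
#' @param dispersion_fun statistic used for ranking; a function of the matrix
#'   returning one value per gene. Defaults to [gene_dispersion()].
#' @return the column-subset matrix with an `"hvg"` step and `n_hvg` recorded.
#' @export
select_hvg <- function(mat, n_hvg = 2000, dispersion_fun = gene_dispersion) {
  stopifnot(n_hvg >= 1)
  disp <- dispersion_fun(mat)
  if (length(disp) != ncol(mat)) stop("dispersion_fun must return one value per gene")
  if (n_hvg > ncol(mat)) {
    warning("n_hvg (", n_hvg, ") exceeds available genes (", ncol(mat),
            "); keeping all genes")
    n_hvg <- ncol(mat)
  }
  ord <- order(-disp, seq_along(disp))[seq_len(n_hvg)]
  out <- mat[, ord, drop = FALSE]
  attr(out, "steps") <- attr(mat, "steps")
  attr(out, "n_hvg") <- n_hvg
  add_step(out, "hvg")
}

#' Standardize genes to zero mean and unit variance
#'
#' Centers and scales each gene across cells using the population variance
#' (denominator m, not m - 1), so that after the transform every column has
#' mean exactly 0 and population variance exactly 1.
#'
#' @param mat expression matrix, cells x genes.
#' @param drop_zero_var if TRUE, genes with zero variance are dropped with a
#'   warning; if FALSE (default) they raise an error instructing removal.
#' @return the standardized matrix with a `"zscore"` step recorded.
#' @export
zscore_genes <- function(mat, drop_zero_var = FALSE) {
  m <- nrow(mat)
  mu <- colMeans(mat)
  v <- colMeans(mat^2) - mu^2
  v <- pmax(v, 0)  # guard tiny negative from cancellation
  zero <- v < .Machine$double.eps * 100
  if (any(zero)) {
    if (!drop_zero_var) {
      stop("cannot standardize constant gene(s): ",
           paste(utils::head(colnames(mat)[zero], 5), collapse = ", "),
           " -- remove them (or set drop_zero_var = TRUE)")
    }
    warning("dropping ", sum(zero), " zero-variance gene(s) before z-scoring")
    mat <- mat[, !zero, drop = FALSE]
    mu <- mu[!zero]
    v <- v[!zero]
  }
  out <- sweep(sweep(mat, 2, mu, "-"), 2, sqrt(v), "/")
  attr(out, "steps") <- attr(mat, "steps")
  attr(out, "n_hvg") <- attr(mat, "n_hvg")
  attr(out, "gene_center") <- mu
  attr(out, "gene_scale") <- sqrt(v)
  add_step(out, "zscore")
}

#' Full preprocessing pipeline
#'
#' Composition filter -> log-normalize -> HVG selection -> per-gene z-score,
#' in that order. Deterministic: no randomness is involved at any stage.
#'
#' @param raw count matrix, cells x genes.
#' @param n_hvg number of highly variable genes to keep (default 2000).
#' @param min_cells,min_counts filtering thresholds, see [filter_counts()].
#' @return the preprocessed expression matrix; `steps_applied()` returns
#'   `c("filter", "lognormalize", "hvg", "zscore")` and attributes
#'   `size_factors`, `gene_center`, `gene_scale` record the fitted transform.
#' @export
preprocess_counts <- function(raw, n_hvg = 2000, min_cells = 2, min_counts = 1) {
  f <- filter_counts(raw, min_cells = min_cells, min_counts = min_counts)
  ln <- lognormalize(f)
  hv <- select_hvg(ln$mat, n_hvg = n_hvg)
  z <- zscore_genes(hv, drop_zero_var = TRUE)
  attr(z, "size_factors") <- ln$size_factors
  z
}
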