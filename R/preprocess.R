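#' Expression matrix container
#'
#' A light S3 container for a cells x genes expression matrix with cell and
#' gene identifiers and optional ground-truth cell-type labels. All pipeline
#' stages consume and produce this class.
#'
#' @param values numeric matrix, cells as rows.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `cell_0`, `cell_1`, ...).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `gene_0`, ...).
#' @param labels optional integer vector of cell class ids, one per cell.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  if (n < 2L) stop("ExpressionMatrix needs at least 2 cells")
  if (m < 1L) stop("ExpressionMatrix needs at least 1 gene")
  if (!all(is.finite(values))) stop("ExpressionMatrix values must be finite")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n) - 1L)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m) - 1L)
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n) stop("cell_ids length must equal cell count")
  if (length(gene_ids) != m) stop("gene_ids length must equal gene count")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels length must equal cell count")
  }
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 labels = labels),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(" (%d labelled classes)", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

guess_format <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  if (grepl("\\.mtx$", p)) return("mtx")
  if (grepl("\\.csv$", p)) return("csv")
  if (grepl("\\.tsv$|\\.txt$", p)) return("tsv")
  if (grepl("\\.h5ad$", p)) return("h5ad")
  stop("cannot guess format from extension of ", path)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  ids <- readLines(con, warn = FALSE)
  ids[nzchar(ids)]
}

load_mtx <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  mat <- as.matrix(Matrix::readMM(con))
  stem <- sub("\\.gz$", "", path)
  stem <- sub("\\.mtx$", "", stem)
  rows <- read_sidecar(paste0(stem, "_barcodes.tsv"))
  if (is.null(rows)) rows <- read_sidecar(paste0(stem, "_barcodes.tsv.gz"))
  cols <- read_sidecar(paste0(stem, "_genes.tsv"))
  if (is.null(cols)) cols <- read_sidecar(paste0(stem, "_genes.tsv.gz"))
  list(values = mat, row_ids = rows, col_ids = cols)
}

load_delim <- function(path, sep) {
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
    error = function(e) stop("load_expression: failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (ncol(dt) < 2L) stop("load_expression: need an id column plus data")
  ids <- as.character(dt[[1L]])
  mat <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("load_expression: non-numeric entries in ", path)
  list(values = mat, row_ids = ids, col_ids = colnames(dt)[-1L])
}

load_h5ad <- function(path) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("load_expression: h5ad input needs `python` with anndata on PATH")
  out_dir <- tempfile("h5ad_")
  dir.create(out_dir)
  script <- file.path(out_dir, "convert.py")
  writeLines(c(
    "import sys, numpy as np, anndata as ad",
    "a = ad.read_h5ad(sys.argv[1])",
    "X = a.X",
    "X = np.asarray(X.todense()) if hasattr(X, 'todense') else np.asarray(X)",
    "np.savetxt(sys.argv[2] + '/X.tsv', X, delimiter='\\t')",
    "open(sys.argv[2] + '/obs.txt', 'w').write('\\n'.join(map(str, a.obs_names)))",
    "open(sys.argv[2] + '/var.txt', 'w').write('\\n'.join(map(str, a.var_names)))"
  ), script)
  st <- system2(py, c(script, shQuote(path), shQuote(out_dir)),
                stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(st, "status")) && attr(st, "status") != 0)
    stop("load_expression: h5ad conversion failed: ",
         paste(st, collapse = "\n"))
  vals <- as.matrix(data.table::fread(file.path(out_dir, "X.tsv"),
                                      header = FALSE, data.table = FALSE))
  list(values = vals,
       row_ids = readLines(file.path(out_dir, "obs.txt"), warn = FALSE),
       col_ids = readLines(file.path(out_dir, "var.txt"), warn = FALSE))
}

#' Load an expression matrix from disk
#'
#' Reads Matrix Market (with optional `*_barcodes.tsv` / `*_genes.tsv` sidecar
#' id files), delimited text with one header row and one id column, or AnnData
#' `.h5ad` (main matrix taken from the `X` slot, converted through the
#' `anndata` Python package). Gzipped text is accepted. The returned matrix
#' always has cells as rows, regardless of on-disk orientation.
#'
#' @param path input file.
#' @param fmt one of `"mtx"`, `"csv"`, `"tsv"`, `"h5ad"`; guessed from the
#'   extension when `NULL`.
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"`; the
#'   latter is transposed on load.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, fmt = NULL,
                            orientation = c("cells_by_genes", "genes_by_cells")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("load_expression: file not found: ", path)
  if (is.null(fmt)) fmt <- guess_format(path)
  fmt <- match.arg(fmt, c("mtx", "csv", "tsv", "h5ad"))
  raw <- switch(fmt,
    mtx = load_mtx(path),
    csv = load_delim(path, ","),
    tsv = load_delim(path, "\t"),
    h5ad = load_h5ad(path))
  vals <- raw$values
  rows <- raw$row_ids
  cols <- raw$col_ids
  if (orientation == "genes_by_cells") {
    vals <- t(vals)
    tmp <- rows; rows <- cols; cols <- tmp
  }
  if (!is.null(rows) && length(rows) != nrow(vals)) rows <- NULL
  if (!is.null(cols) && length(cols) != ncol(vals)) cols <- NULL
  expression_matrix(vals, cell_ids = rows, gene_ids = cols)
}

#' Write an expression matrix to disk
#'
#' Counterpart of [load_expression()], used by the simulator and for
#' round-trip checks. Matrix Market output writes `*_barcodes.tsv` and
#' `*_genes.tsv` sidecars next to the `.mtx` file; h5ad goes through the
#' Python `anndata` package.
#'
#' @param X an [expression_matrix()].
#' @param path output file; the extension selects nothing, `fmt` rules.
#' @param fmt one of `"mtx"`, `"csv"`, `"tsv"`, `"h5ad"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, fmt = c("mtx", "csv", "tsv", "h5ad")) {
  fmt <- match.arg(fmt)
  if (fmt == "mtx") {
    Matrix::writeMM(Matrix::Matrix(X$values, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(X$cell_ids, paste0(stem, "_barcodes.tsv"))
    writeLines(X$gene_ids, paste0(stem, "_genes.tsv"))
  } else if (fmt %in% c("csv", "tsv")) {
    df <- data.frame(cell_id = X$cell_ids, X$values, check.names = FALSE)
    colnames(df) <- c("cell_id", X$gene_ids)
    data.table::fwrite(df, path, sep = if (fmt == "csv") "," else "\t")
  } else {
    py <- Sys.which("python")
    if (!nzchar(py)) stop("write_expression: h5ad output needs `python` with anndata on PATH")
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    write_expression(X, tmp, fmt = "tsv")
    script <- tempfile(fileext = ".py")
    on.exit(unlink(script), add = TRUE)
    writeLines(c(
      "import sys, pandas as pd, anndata as ad",
      "df = pd.read_csv(sys.argv[1], sep='\\t', index_col=0)",
      "a = ad.AnnData(X=df.to_numpy(dtype='float64'))",
      "a.obs_names = df.index.astype(str); a.var_names = df.columns.astype(str)",
      "a.write_h5ad(sys.argv[2])"
    ), script)
    st <- system2(py, c(script, shQuote(tmp), shQuote(path)),
                  stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(st, "status")) && attr(st, "status") != 0)
      stop("write_expression: h5ad conversion failed: ",
           paste(st, collapse = "\n"))
  }
  invisible(path)
}

#' Remove genes dominated by zeros
#'
#' Drops every gene whose fraction of zero-valued cells is at or above the
#' threshold; with the default 0.95 a gene zero in 95% or more of cells is
#' deleted. Survivor order is preserved.
#'
#' @param X an [expression_matrix()].
#' @param zero_fraction_threshold real in (0, 1]; inclusive boundary.
#' @return Filtered [expression_matrix()].
#' @export
filter_genes <- function(X, zero_fraction_threshold = 0.95) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (!is.numeric(zero_fraction_threshold) || zero_fraction_threshold <= 0 ||
      zero_fraction_threshold > 1)
    stop("zero_fraction_threshold must lie in (0, 1]")
  zf <- colMeans(X$values == 0)
  keep <- zf < zero_fraction_threshold
  if (!any(keep))
    stop(sprintf(
      "filter_genes: all genes are zero in >= %.3g of cells; nothing left",
      zero_fraction_threshold))
  expression_matrix(X$values[, keep, drop = FALSE], X$cell_ids,
                    X$gene_ids[keep], X$labels)
}

#' Standardize genes to zero mean and unit variance
#'
#' Per-gene z-scoring with the population (divide-by-N) variance. Constant
#' genes become all-zero columns rather than NaN. Idempotent within floating
#' tolerance.
#'
#' @param X an [expression_matrix()].
#' @return Standardized [expression_matrix()].
#' @export
standardize <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  v <- X$values
  mu <- colMeans(v)
  sdev <- sqrt(colMeans(sweep(v, 2L, mu, "-")^2))
  out <- sweep(v, 2L, mu, "-")
  nz <- sdev > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sdev[nz], "/")
  out[, !nz] <- 0
  expression_matrix(out, X$cell_ids, X$gene_ids, X$labels)
}
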