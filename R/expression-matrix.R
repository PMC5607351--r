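#' Expression matrix with a declared unit
#'
#' A genes x cells numeric matrix that carries its measurement unit
#' (`"counts"`, `"tpm"`, `"scaled"` or `"log2"` for log2(TPM+1)-style
#' values) so downstream steps can refuse inputs on the wrong scale.
#' Gene symbols are row names, cell ids are column names; both must be
#' unique and non-empty.
#'
#' @param values numeric matrix, genes in rows, cells in columns, with
#'   row and column names set.
#' @param unit one of `"counts"`, `"tpm"`, `"scaled"`, `"log2"`.
#' @return an `expr_matrix` object.
#' @export
expression_matrix <- function(values, unit = c("counts", "tpm", "scaled", "log2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  # fully-filtered (0-cell) matrices are legal; R drops empty dimnames
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have gene row names and cell column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in row names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell ids in column names")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, unit = %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Cell ids and gene symbols of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector.
#' @export
em_cells <- function(x) colnames(x$values)

#' @rdname em_cells
#' @export
em_genes <- function(x) rownames(x$values)

#' Subset an expression matrix by genes and/or cells
#'
#' @param x an `expr_matrix`.
#' @param genes,cells character vectors (or NULL to keep all). Unknown
#'   labels are an error.
#' @export
em_subset <- function(x, genes = NULL, cells = NULL) {
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) > 0)
      stop("unknown genes: ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(v))
    if (length(missing) > 0)
      stop("unknown cells: ", paste(missing, collapse = ", "))
    v <- v[, cells, drop = FALSE]
  }
  expression_matrix(v, x$unit)
}

#' Rescale columns to TPM (each cell sums to 1e6)
#'
#' All synthetic genes share unit effective length, so TPM is proportional
#' to counts-per-million; this is a pure per-cell rescaling.
#'
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` with unit `"tpm"`.
#' @export
as_tpm <- function(x) {
  totals <- colSums(x$values)
  if (any(totals == 0)) stop("cannot rescale all-zero cells to TPM")
  expression_matrix(sweep(x$values, 2, totals / 1e6, "/"), "tpm")
}

#' log2(x + 1) transform
#'
#' @param x an `expr_matrix` (any non-log unit).
#' @return an `expr_matrix` with unit `"log2"`.
#' @export
log2p1 <- function(x) {
  if (x$unit == "log2") stop("matrix is already log-transformed")
  expression_matrix(log2(x$values + 1), "log2")
}
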