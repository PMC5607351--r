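#' Write an expression matrix to disk
#'
#' Either MatrixMarket triplet format (`matrix.mtx` + `genes.txt` +
#' `cells.txt`) or a single dense TSV with genes in rows. A small JSON
#' sidecar records the unit.
#'
#' @param x an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @param format `"mtx"` or `"tsv"`.
#' @param name stem for the TSV / MTX files.
#' @return the directory, invisibly.
#' @export
write_matrix <- function(x, dir, format = c("mtx", "tsv"),
                         name = "matrix") {
  stopifnot(inherits(x, "expr_matrix"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE),
                    file.path(dir, paste0(name, ".mtx")))
    writeLines(rownames(x$values), file.path(dir, "genes.txt"))
    writeLines(colnames(x$values), file.path(dir, "cells.txt"))
  } else {
    df <- data.frame(gene = rownames(x$values), x$values,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(unit = x$unit, format = format),
                       file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read an expression matrix written by [write_matrix()]
#'
#' Also reads any MTX triplet + `genes.txt`/`cells.txt` trio or dense
#' TSV with a leading `gene` column, with the unit supplied explicitly
#' when no JSON sidecar is present.
#'
#' @param dir directory holding the files.
#' @param format `"mtx"` or `"tsv"`.
#' @param name file stem used when writing.
#' @param unit overrides/supplies the unit tag.
#' @return an [expression_matrix()].
#' @export
read_matrix <- function(dir, format = c("mtx", "tsv"), name = "matrix",
                        unit = NULL) {
  format <- match.arg(format)
  sidecar <- file.path(dir, paste0(name, ".json"))
  if (is.null(unit)) {
    if (!file.exists(sidecar))
      stop("no unit sidecar found; pass `unit` explicitly")
    unit <- jsonlite::read_json(sidecar)$unit
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(file.path(dir, paste0(name, ".mtx"))))
    rownames(m) <- readLines(file.path(dir, "genes.txt"))
    colnames(m) <- readLines(file.path(dir, "cells.txt"))
  } else {
    df <- utils::read.table(file.path(dir, paste0(name, ".tsv")),
                            sep = "\t", header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
  }
  expression_matrix(m, unit)
}

#' Write generator ground truth and spec snapshot
#'
#' `ground_truth.tsv` holds cell, cluster, gate and any engineered QC
#' failures (semicolon-separated); `spec.json` is a faithful echo of the
#' generator parameterization.
#'
#' @param truth,spec the `truth` element of [generate_dataset()] and the
#'   [synthetic_spec()] that produced it.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_ground_truth <- function(truth, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- truth$cells
  fails <- vapply(df$cell, function(cell)
    paste(truth$engineered_failures[[cell]] %||% character(0),
          collapse = ";"), character(1))
  df$engineered_failures <- unname(fails)
  utils::write.table(df, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a QC report and retained-cell list
#'
#' @param qc result of [qc_filter()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_qc_report <- function(qc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(qc$report),
                     file.path(dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(qc$retained_cells, file.path(dir, "retained_cells.txt"))
  invisible(dir)
}
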