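#' Names of the six cell-exclusion criteria
#'
#' @return character vector `criterion_1` ... `criterion_6`:
#'   (1) fewer than 2000 expressed genes, (2) low mean housekeeping
#'   expression, (3) outlier number of expressed genes (top 1%),
#'   (4) R26-Tom reporter, (5) Ptprc (CD45), (6) Pecam1 (CD31).
#' @export
qc_criteria <- function() sprintf("criterion_%d", 1:6)

#' Thresholds and directions of the six-criterion exclusion cascade
#'
#' The printed thresholds are: expressed genes below 2000; housekeeping
#' panel mean TPM below 1.5; top 1% outlier expressed-gene counts;
#' R26-Tom TPM vs 32; Ptprc TPM vs 1; Pecam1 TPM vs 1. The printed
#' directions of criteria (4)-(6) are internally inconsistent with the
#' sorted populations (Tom+ cells were deliberately sorted; CD45-/CD31-
#' cells were selected), so two modes are offered:
#'
#' * `"coherent"` (default): cells are retained when Ptprc < 1 and
#'   Pecam1 < 1 (excluded at or above 1); the Tom criterion excludes
#'   Tom-gated (Lgr5) cells whose Tom TPM is at or below 32 (reporter
#'   too low for a sorted cell) and is skipped when no gate labels are
#'   available.
#' * `"literal"`: the directions exactly as printed — exclude if
#'   Tom > 32, exclude if Ptprc < 1, exclude if Pecam1 < 1.
#'
#' The report always records the mode that was applied.
#'
#' @param min_expressed_genes criterion 1 threshold (strict: fail below).
#' @param min_housekeeping_mean_tpm criterion 2 threshold (strict: fail
#'   below).
#' @param outlier_gene_fraction criterion 3 fraction in (0, 1).
#' @param tom_tpm_threshold,ptprc_tpm_threshold,pecam1_tpm_threshold TPM
#'   thresholds of criteria 4-6.
#' @param mode `"coherent"` or `"literal"` (see above).
#' @param enabled named logical vector switching individual criteria off;
#'   names in [qc_criteria()].
#' @return a `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_expressed_genes = 2000,
                          min_housekeeping_mean_tpm = 1.5,
                          outlier_gene_fraction = 0.01,
                          tom_tpm_threshold = 32,
                          ptprc_tpm_threshold = 1,
                          pecam1_tpm_threshold = 1,
                          mode = c("coherent", "literal"),
                          enabled = NULL) {
  mode <- match.arg(mode)
  th <- list(min_expressed_genes = min_expressed_genes,
             min_housekeeping_mean_tpm = min_housekeeping_mean_tpm,
             outlier_gene_fraction = outlier_gene_fraction,
             tom_tpm_threshold = tom_tpm_threshold,
             pecam1_tpm_threshold = pecam1_tpm_threshold,
             ptprc_tpm_threshold = ptprc_tpm_threshold,
             mode = mode,
             enabled = stats::setNames(rep(TRUE, 6), qc_criteria()))
  if (!is.null(enabled)) {
    stopifnot(all(names(enabled) %in% qc_criteria()))
    th$enabled[names(enabled)] <- enabled
  }
  nums <- unlist(th[1:6])
  if (any(nums < 0)) stop("thresholds must be >= 0")
  if (outlier_gene_fraction <= 0 || outlier_gene_fraction >= 1)
    stop("outlier_gene_fraction must lie in (0, 1)")
  structure(th, class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' Computes, for each cell of a TPM matrix: the expressed-gene count
#' (genes with TPM strictly > 0), the arithmetic mean TPM over the
#' housekeeping panel, and the TPM of the three reporter genes, copied
#' verbatim. Thresholds are applied separately by [apply_exclusion()].
#'
#' @param tpm an [expression_matrix()] with unit `"tpm"`.
#' @param housekeeping_panel character vector of panel genes (must be
#'   rows of the matrix).
#' @param reporters named vector mapping `tom`, `ptprc`, `pecam1` to gene
#'   symbols; a missing row is allowed (its metric is `NA`) but the
#'   corresponding criterion must then be disabled at exclusion time.
#' @param gate optional named character vector cell -> sort gate label.
#' @return data.frame, one row per cell: `cell`, `expressed_genes`,
#'   `housekeeping_mean_tpm`, `tom_tpm`, `ptprc_tpm`, `pecam1_tpm`,
#'   `gate`.
#' @export
compute_cell_metrics <- function(tpm, housekeeping_panel,
                                 reporters = c(tom = "R26-Tom",
                                               ptprc = "Ptprc",
                                               pecam1 = "Pecam1"),
                                 gate = NULL) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$unit != "tpm")
    stop("QC thresholds are stated in TPM; got unit '", tpm$unit, "'")
  if (length(housekeeping_panel) == 0)
    stop("empty housekeeping panel")
  missing_hk <- setdiff(housekeeping_panel, em_genes(tpm))
  if (length(missing_hk) > 0)
    stop("housekeeping genes absent from matrix: ",
         paste(missing_hk, collapse = ", "))
  v <- tpm$values
  cells <- colnames(v)
  reporter_tpm <- function(role) {
    g <- reporters[[role]]
    if (is.null(g) || !(g %in% rownames(v))) rep(NA_real_, ncol(v))
    else v[g, ]
  }
  gate_col <- if (is.null(gate)) rep(NA_character_, length(cells)) else {
    missing <- setdiff(cells, names(gate))
    if (length(missing) > 0)
      stop("gate labels missing for cells: ", paste(missing, collapse = ", "))
    unname(gate[cells])
  }
  data.frame(
    cell = cells,
    expressed_genes = colSums(v > 0),
    housekeeping_mean_tpm =
      colMeans(v[housekeeping_panel, , drop = FALSE]),
    tom_tpm = reporter_tpm("tom"),
    ptprc_tpm = reporter_tpm("ptprc"),
    pecam1_tpm = reporter_tpm("pecam1"),
    gate = gate_col,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Apply the six-criterion exclusion cascade
#'
#' Criteria are a union of exclusions: a cell is retained iff it fails
#' none. Criterion 3 is computed once on the full input population: the
#' cutoff is the expressed-gene count at nearest rank
#' `n - ceiling(f * n)` and cells strictly above it are flagged, so that
#' with distinct counts exactly `ceiling(f * n)` cells fall (ties are
#' retained). The cutoff used is recorded in the report attributes.
#'
#' @param metrics data.frame from [compute_cell_metrics()].
#' @param thresholds a [qc_thresholds()].
#' @param outlier_cutoff optional frozen criterion-3 cutoff (an
#'   expressed-gene count); when supplied the quantile is not recomputed,
#'   which makes re-filtering a retained set idempotent.
#' @return a `qc_report`: the metrics data.frame with one logical flag
#'   column per criterion plus `retained`, carrying the thresholds and
#'   the realized criterion-3 cutoff as attributes.
#' @export
apply_exclusion <- function(metrics, thresholds = qc_thresholds(),
                            outlier_cutoff = NULL) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n <- nrow(metrics)
  if (n == 0) {
    warning("empty input: empty QC report")
    metrics$retained <- logical(0)
    return(structure(metrics, class = c("qc_report", "data.frame"),
                     thresholds = thresholds, outlier_cutoff = NA_real_))
  }
  en <- thresholds$enabled
  need <- function(col, crit) {
    if (en[[crit]] && anyNA(metrics[[col]]))
      stop("metric '", col, "' unavailable but ", crit, " is enabled")
  }
  need("housekeeping_mean_tpm", "criterion_2")
  need("ptprc_tpm", "criterion_5")
  need("pecam1_tpm", "criterion_6")

  flag <- matrix(FALSE, nrow = n, ncol = 6,
                 dimnames = list(NULL, qc_criteria()))
  flag[, "criterion_1"] <-
    metrics$expressed_genes < thresholds$min_expressed_genes
  flag[, "criterion_2"] <-
    metrics$housekeeping_mean_tpm < thresholds$min_housekeeping_mean_tpm

  cutoff <- if (!is.null(outlier_cutoff)) outlier_cutoff else {
    k <- n - ceiling(thresholds$outlier_gene_fraction * n)
    if (k >= 1) nearest_rank(metrics$expressed_genes, k) else -Inf
  }
  flag[, "criterion_3"] <- metrics$expressed_genes > cutoff

  if (thresholds$mode == "literal") {
    if (en[["criterion_4"]] && !anyNA(metrics$tom_tpm))
      flag[, "criterion_4"] <- metrics$tom_tpm > thresholds$tom_tpm_threshold
    flag[, "criterion_5"] <- metrics$ptprc_tpm < thresholds$ptprc_tpm_threshold
    flag[, "criterion_6"] <-
      metrics$pecam1_tpm < thresholds$pecam1_tpm_threshold
  } else {
    if (en[["criterion_4"]] && !all(is.na(metrics$gate)) &&
        !anyNA(metrics$tom_tpm)) {
      tom_gated <- !is.na(metrics$gate) & metrics$gate == "Lgr5"
      flag[, "criterion_4"] <-
        tom_gated & metrics$tom_tpm <= thresholds$tom_tpm_threshold
    }
    flag[, "criterion_5"] <-
      metrics$ptprc_tpm >= thresholds$ptprc_tpm_threshold
    flag[, "criterion_6"] <-
      metrics$pecam1_tpm >= thresholds$pecam1_tpm_threshold
  }
  flag[, !en] <- FALSE

  out <- cbind(metrics, as.data.frame(flag))
  out$retained <- rowSums(flag) == 0
  structure(out, class = c("qc_report", "data.frame"),
            thresholds = thresholds, outlier_cutoff = cutoff)
}

#' @export
print.qc_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("<qc_report> %d cells, %d retained (mode = %s)\n",
              nrow(x), sum(x$retained),
              if (is.null(th)) "?" else th$mode))
  print.data.frame(x, ...)
  invisible(x)
}

#' One-call QC: metrics, exclusion and the filtered matrix
#'
#' @inheritParams compute_cell_metrics
#' @inheritParams apply_exclusion
#' @return list: `report` (a `qc_report`), `retained_cells` (character),
#'   `tpm` (the input matrix restricted to retained cells).
#' @export
qc_filter <- function(tpm, housekeeping_panel,
                      reporters = c(tom = "R26-Tom", ptprc = "Ptprc",
                                    pecam1 = "Pecam1"),
                      gate = NULL, thresholds = qc_thresholds()) {
  metrics <- compute_cell_metrics(tpm, housekeeping_panel, reporters, gate)
  report <- apply_exclusion(metrics, thresholds)
  keep <- report$cell[report$retained]
  list(report = report, retained_cells = keep,
       tpm = em_subset(tpm, cells = keep))
}
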