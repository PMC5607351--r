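#' Per-gene dispersion table for variable-gene selection
#'
#' Reimplements the classic binned mean/dispersion standardization used
#' for highly-variable-gene selection, following the convention of the
#' referenced mean-variance routine: the raw dispersion is the
#' variance-to-mean ratio of the un-logged expression (0/0 defined as
#' 0) — on the linear scale a negative-binomial background gives
#' dispersion ~ 1 + mu/theta, so differential genes stand out within a
#' mean bin — and the log of that dispersion is z-scored within
#' `n_bins` equal-frequency bins of mean expression (a bin standard
#' deviation of 0, or a single-gene bin, gives score 0).
#'
#' @param expr an [expression_matrix()] with unit `"log2"` (log2(TPM+1)
#'   values; un-logged internally) and at least two cells.
#' @param n_bins equal-frequency mean-expression bins (default 20);
#'   reduced with a warning when there are fewer genes than bins.
#' @return data.frame, one row per gene: `gene`, `mean_expr` (mean
#'   log2(x+1)), `dispersion_raw` (linear-scale variance/mean),
#'   `dispersion_scored` (binned z-score of log dispersion).
#' @export
compute_dispersion <- function(expr, n_bins = 20) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$unit != "log2")
    stop("dispersion is computed from log2(x+1) input; got unit '",
         expr$unit, "'")
  if (ncol(expr$values) < 2) stop("need at least 2 cells")
  lin <- 2^expr$values - 1
  means <- rowMeans(lin)
  vars <- row_vars(lin)
  disp <- ifelse(means > 0, vars / means, 0)
  log_disp <- log(disp + 1e-12)

  n_genes <- length(means)
  if (n_genes < n_bins) {
    warning("fewer genes (", n_genes, ") than bins (", n_bins,
            "); reducing bins")
    n_bins <- max(1, n_genes)
  }
  # equal-frequency bins on the mean, stable under ties via first-rank
  bin <- ceiling(rank(means, ties.method = "first") * n_bins / n_genes)
  scored <- numeric(n_genes)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    s <- stats::sd(log_disp[idx])
    scored[idx] <- if (length(idx) < 2 || is.na(s) || s == 0) 0 else
      (log_disp[idx] - mean(log_disp[idx])) / s
  }
  data.frame(gene = rownames(expr$values), mean_expr = rowMeans(expr$values),
             dispersion_raw = disp, dispersion_scored = scored,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select genes with elevated dispersion
#'
#' Strict inequality against the threshold (default > 0.5), applied to
#' the bin-standardized dispersion by default; the raw variance/mean
#' dispersion is available via `use = "raw"`. Returns symbols sorted
#' lexicographically for determinism.
#'
#' @param table data.frame from [compute_dispersion()].
#' @param threshold dispersion cutoff, default 0.5.
#' @param use `"scored"` (default) or `"raw"`.
#' @return character vector of selected gene symbols.
#' @export
select_genes <- function(table, threshold = 0.5,
                         use = c("scored", "raw")) {
  use <- match.arg(use)
  col <- if (use == "scored") table$dispersion_scored else
    table$dispersion_raw
  genes <- sort(table$gene[col > threshold])
  if (length(genes) == 0)
    stop("no genes selected; review the dispersion threshold (",
         threshold, ")")
  genes
}
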