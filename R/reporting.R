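#' Per-cluster relative average expression of marker genes
#'
#' Arithmetic mean log2(TPM+1) per cluster, then per-gene relative
#' scaling across clusters: z-score by default (rows with zero standard
#' deviation are set to 0), or min-max to \[0, 1\]. The scaling mode is
#' recorded on the result, since "relative average expression" admits
#' both readings.
#'
#' @param expr an [expression_matrix()] with unit `"log2"`.
#' @param assignment a `cluster_assignment` (or a named label vector)
#'   covering every cell of `expr`.
#' @param genes marker genes to tabulate; all must be present.
#' @param mode `"zscore"` (default) or `"minmax"`.
#' @return gene x cluster numeric matrix with attribute `mode`.
#' @export
cluster_mean_expression <- function(expr, assignment, genes,
                                    mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$unit != "log2")
    stop("expected log2(TPM+1) values; got unit '", expr$unit, "'")
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  cells <- em_cells(expr)
  if (!all(cells %in% names(labels)))
    stop("unlabeled cells: ",
         paste(utils::head(setdiff(cells, names(labels))), collapse = ", "))
  missing <- setdiff(genes, em_genes(expr))
  if (length(missing) > 0)
    stop("unknown genes: ", paste(missing, collapse = ", "))

  labels <- labels[cells]
  clusters <- sort(unique(labels))
  v <- expr$values[genes, , drop = FALSE]
  means <- vapply(clusters, function(cl)
    rowMeans(v[, labels == cl, drop = FALSE]), numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, clusters))
  scaled <- means
  for (i in seq_len(nrow(means))) {
    r <- means[i, ]
    scaled[i, ] <- if (mode == "zscore") {
      s <- stats::sd(r)
      if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    } else {
      rng <- range(r)
      if (diff(rng) == 0) rep(0, length(r)) else (r - rng[1]) / diff(rng)
    }
  }
  structure(scaled, mode = mode)
}

#' Five-number summary of a gene's expression per population
#'
#' min, Q1, median, Q3 and max of log2(TPM+1) per group
#' (linear-interpolation quantiles), the numbers behind per-population
#' expression boxplots.
#'
#' @param expr an [expression_matrix()] with unit `"log2"`.
#' @param groups named character vector cell -> group label, covering
#'   every cell; every group needs at least one cell.
#' @param gene a single gene symbol.
#' @return data.frame: group, n, min, q1, median, q3, max.
#' @export
population_expression_summary <- function(expr, groups, gene) {
  stopifnot(inherits(expr, "expr_matrix"), length(gene) == 1)
  if (!(gene %in% em_genes(expr))) stop("unknown gene: ", gene)
  cells <- em_cells(expr)
  if (!all(cells %in% names(groups)))
    stop("group labels missing for some cells")
  g <- groups[cells]
  vals <- expr$values[gene, ]
  res <- lapply(sort(unique(g)), function(grp) {
    x <- vals[g == grp]
    if (length(x) == 0) stop("empty group: ", grp)
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(group = grp, n = length(x), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Join embedding coordinates with a gene's expression
#'
#' The table behind gene-coloured tSNE plots: one row per cell with its
#' 2-D coordinates and the gene's log2(TPM+1) value. A pure join; no
#' recomputation.
#'
#' @param embedding data.frame from [tsne_embed()].
#' @param expr an [expression_matrix()] sharing the embedding's cells.
#' @param gene a single gene symbol (error if absent).
#' @return data.frame: cell, x, y, expression.
#' @export
embedding_gene_overlay <- function(embedding, expr, gene) {
  stopifnot(inherits(expr, "expr_matrix"), length(gene) == 1)
  if (!(gene %in% em_genes(expr))) stop("unknown gene: ", gene)
  if (!setequal(embedding$cell, em_cells(expr)))
    stop("embedding and expression matrix cover different cells")
  out <- embedding[, c("cell", "x", "y")]
  out$expression <- expr$values[gene, out$cell]
  out
}
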