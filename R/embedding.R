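#' Leading principal-component scores of cells
#'
#' PCA on the gene-centered (not unit-scaled) log2 matrix via singular
#' value decomposition. Components are ordered by decreasing explained
#' variance and their sign is fixed by making each component's
#' largest-magnitude gene loading positive, so the decomposition is
#' fully deterministic.
#'
#' @param expr an [expression_matrix()] (typically unit `"log2"`,
#'   restricted to selected genes), or a plain cells x features matrix.
#' @param n_pcs number of components (default 7).
#' @param scale. also divide each gene by its standard deviation.
#' @return cells x `n_pcs` score matrix; explained variances are in
#'   attribute `explained_variance`, gene loadings in `rotation`.
#' @export
pca_scores <- function(expr, n_pcs = 7, scale. = FALSE) {
  x <- if (inherits(expr, "expr_matrix")) t(expr$values) else as.matrix(expr)
  if (n_pcs > min(dim(x)))
    stop("n_pcs = ", n_pcs, " exceeds min(n_cells, n_genes) = ",
         min(dim(x)))
  if (nrow(x) < n_pcs + 1) stop("need at least n_pcs + 1 cells")
  x <- scale(x, center = TRUE, scale = scale.)
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs), 2, flip, "*")
  rotation <- sweep(sv$v, 2, flip, "*")
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  dimnames(rotation) <- list(colnames(x), colnames(scores))
  structure(scores,
            explained_variance = sv$d[seq_len(n_pcs)]^2 / (nrow(x) - 1),
            rotation = rotation)
}

#' 2-D tSNE embedding of PC scores
#'
#' Exact (theta = 0) t-stochastic neighbour embedding at the given
#' perplexity, randomly initialized from the seed; the same seed gives
#' bit-identical coordinates. When there are not more than
#' 3 * perplexity cells the perplexity is reduced with a warning.
#'
#' @param scores cells x components matrix (e.g. from [pca_scores()]).
#' @param perplexity effective neighbour count (default 20).
#' @param seed RNG seed.
#' @param max_iter gradient-descent iterations.
#' @return data.frame `cell`, `x`, `y`; provenance (n_pcs, perplexity,
#'   seed) in attribute `provenance`.
#' @export
tsne_embed <- function(scores, perplexity = 20, seed = 1L,
                       max_iter = 1000) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("non-finite values in input scores")
  n <- nrow(scores)
  if (n <= 3 * perplexity) {
    perplexity <- max(1, floor((n - 1) / 3))
    warning("too few cells for requested perplexity; reduced to ",
            perplexity)
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity,
                      theta = 0, pca = FALSE, max_iter = max_iter,
                      check_duplicates = FALSE, num_threads = 1)
  ids <- rownames(scores) %||% sprintf("cell_%04d", seq_len(n))
  out <- data.frame(cell = ids, x = fit$Y[, 1], y = fit$Y[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "provenance") <- list(n_pcs = ncol(scores),
                                  perplexity = perplexity, seed = seed)
  out
}

#' PCA followed by tSNE in one call
#'
#' The visualization of the reference workflow: 7 leading principal
#' components, tSNE at perplexity 20.
#'
#' @inheritParams pca_scores
#' @inheritParams tsne_embed
#' @return as [tsne_embed()].
#' @export
embed_cells <- function(expr, n_pcs = 7, perplexity = 20, seed = 1L) {
  tsne_embed(pca_scores(expr, n_pcs = n_pcs), perplexity = perplexity,
             seed = seed)
}
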