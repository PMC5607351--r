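#' Build a Jaccard-weighted k-nearest-neighbour graph of cells
#'
#' Each cell is connected to its `k` nearest neighbours (Euclidean by
#' default); distance ties are broken deterministically by lower cell
#' index, so duplicate cells are never dropped. Edge weights are the
#' Jaccard overlap of the two endpoints' neighbourhood sets, where a
#' cell's neighbourhood includes itself (so `k` mutual identical cells
#' get weight 1).
#'
#' @param x numeric matrix, cells in rows (row names = cell ids),
#'   features (selected genes or PC scores) in columns.
#' @param k number of neighbours; needs at least `k + 1` cells.
#' @param metric distance metric passed to [stats::dist()].
#' @return a `knn_graph`: list with `nodes`, `edges` (data.frame
#'   `i`, `j`, `weight`, each undirected pair stored once with `i < j`),
#'   `neighbors` (list of neighbour index vectors), `k`, `metric`.
#' @export
build_knn_graph <- function(x, k, metric = "euclidean") {
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell_%04d", seq_len(n))
  if (n < k + 1) stop("need at least k + 1 cells (k = ", k, ")")
  d <- as.matrix(stats::dist(x, method = metric))
  diag(d) <- -Inf                       # self always sorts first
  nbr <- matrix(0L, nrow = n, ncol = k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))    # ties broken by lower index
    nbr[i, ] <- ord[2:(k + 1)]
  }
  # neighbourhood indicator incl. self; Jaccard via set intersections
  s <- matrix(FALSE, n, n)
  s[cbind(rep(seq_len(n), each = k), as.vector(t(nbr)))] <- TRUE
  diag(s) <- TRUE
  inter <- tcrossprod(s * 1)
  size <- k + 1
  jac <- inter / (2 * size - inter)

  adj <- s
  diag(adj) <- FALSE
  adj <- adj | t(adj)                   # i-j linked if either lists the other
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(i = rownames(x)[idx[, 1]],
                      j = rownames(x)[idx[, 2]],
                      weight = jac[idx],
                      stringsAsFactors = FALSE)
  structure(list(nodes = rownames(x), edges = edges,
                 neighbors = lapply(seq_len(n), function(i) nbr[i, ]),
                 k = k, metric = metric),
            class = "knn_graph")
}

#' Louvain community detection on a k-NN graph
#'
#' Modularity-based Louvain communities on the Jaccard-weighted graph;
#' isolated nodes become singleton communities. Seeded: the same graph
#' and seed give identical labels.
#'
#' @param graph a [build_knn_graph()] result.
#' @param seed RNG seed.
#' @return integer community labels named by cell id.
#' @export
detect_communities <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "knn_graph"))
  if (length(graph$nodes) == 0) stop("empty graph")
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = graph$nodes)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  membership <- igraph::membership(comm)
  stats::setNames(as.integer(membership[graph$nodes]), graph$nodes)
}

#' Consensus co-clustering matrix over random subsamples
#'
#' For each of `B` rounds: draw `ceiling(fraction * n)` cells without
#' replacement, rebuild the k-NN graph on the subsample, run Louvain,
#' and record which co-sampled pairs ended up co-clustered. The
#' consensus frequency of a pair is co-clustered / co-sampled rounds
#' (0/0 defined as 0).
#'
#' @param x cells x features matrix (row names = cell ids).
#' @param B number of subsampling rounds (the reference analysis uses
#'   1,000; tests scale this down).
#' @param subsample_fraction fraction of cells per round, in (0, 1\].
#' @param k neighbours per cell; `NULL` uses `max(5, round(sqrt(m)))`
#'   where m is the subsample size.
#' @param seed master seed; one sub-seed per round is derived from it.
#' @return a `consensus_matrix`: list of integer matrices `cooccur` and
#'   `cosample`, the `frequency` matrix, and the parameters used.
#' @export
consensus_matrix <- function(x, B = 1000, subsample_fraction = 0.7,
                             k = NULL, seed = 1L) {
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell_%04d", seq_len(n))
  if (B < 1) stop("B must be >= 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]")
  m <- ceiling(subsample_fraction * n)
  k_use <- k %||% max(5, round(sqrt(m)))
  if (m < k_use + 1)
    stop("subsample of ", m, " cells is smaller than k + 1 = ", k_use + 1)

  cells <- rownames(x)
  cooccur <- matrix(0L, n, n, dimnames = list(cells, cells))
  cosample <- matrix(0L, n, n, dimnames = list(cells, cells))
  seeds <- derive_seeds(seed, 2 * B)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sort(sample.int(n, m))
    g <- build_knn_graph(x[idx, , drop = FALSE], k = k_use)
    lab <- detect_communities(g, seed = seeds[B + b])
    same <- outer(lab, lab, "==")
    cosample[idx, idx] <- cosample[idx, idx] + 1L
    cooccur[idx, idx] <- cooccur[idx, idx] + (same * 1L)
  }
  frequency <- ifelse(cosample > 0, cooccur / pmax(cosample, 1L), 0)
  structure(list(cooccur = cooccur, cosample = cosample,
                 frequency = frequency, B = B, k = k_use,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("<consensus_matrix> %d cells, B = %d, k = %d, fraction = %g\n",
              nrow(x$frequency), x$B, x$k, x$subsample_fraction))
  invisible(x)
}

#' Cut the consensus matrix into final clusters
#'
#' Average-linkage hierarchical clustering on the consensus distance
#' 1 - frequency. With `n_clusters = "auto"` the cut maximizing the mean
#' silhouette width over `k_range` is chosen (ties go to the smaller
#' number of clusters). Clusters are labelled A, B, C, ... in order of
#' first appearance along the cell ordering; per-cluster stability is
#' the mean consensus frequency over within-cluster pairs (singletons
#' score 1).
#'
#' @param cm a [consensus_matrix()].
#' @param n_clusters integer, or `"auto"` (default).
#' @param k_range candidate cluster numbers for the auto cut.
#' @return a `cluster_assignment`: list with `labels` (named character),
#'   `n_clusters`, `stability` (named numeric), `hclust` (the
#'   dendrogram), `silhouette` (mean widths per candidate, auto mode).
#' @export
cut_consensus <- function(cm, n_clusters = "auto", k_range = 2:10) {
  stopifnot(inherits(cm, "consensus_matrix"))
  freq <- cm$frequency
  n <- nrow(freq)
  off <- cm$cosample == 0 & upper.tri(cm$cosample)
  if (any(off))
    warning(sum(off), " cell pairs were never co-sampled; ",
            "their consensus frequency is taken as 0")
  d <- stats::as.dist(1 - freq)
  hc <- stats::hclust(d, method = "average")

  sil_means <- NULL
  if (identical(n_clusters, "auto")) {
    kk <- k_range[k_range >= 2 & k_range <= n - 1]
    if (length(kk) == 0) stop("no feasible cluster numbers in k_range")
    sil_means <- vapply(kk, function(k) {
      sil <- cluster::silhouette(stats::cutree(hc, k), d)
      mean(sil[, "sil_width"])
    }, numeric(1))
    names(sil_means) <- kk
    n_clusters <- kk[which.max(sil_means)]
  }
  n_clusters <- as.integer(n_clusters)
  if (n_clusters > n) stop("n_clusters exceeds the number of cells")
  raw <- if (n_clusters == 1) rep(1L, n) else stats::cutree(hc, n_clusters)

  # relabel as A, B, ... in order of first appearance for determinism
  lab_map <- stats::setNames(LETTERS[seq_len(n_clusters)], unique(raw))
  labels <- stats::setNames(unname(lab_map[as.character(raw)]),
                            rownames(freq))

  stability <- vapply(unique(labels), function(cl) {
    members <- which(labels == cl)
    if (length(members) < 2) return(1)
    f <- freq[members, members]
    mean(f[upper.tri(f)])
  }, numeric(1))

  structure(list(labels = labels, n_clusters = n_clusters,
                 stability = stability[sort(names(stability))],
                 hclust = hc, silhouette = sil_means),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells in %d clusters\n",
              length(x$labels), x$n_clusters))
  print(table(x$labels))
  invisible(x)
}

#' Full consensus-clustering pipeline on an expression matrix
#'
#' Reduces the selected-gene log2 matrix to the leading principal
#' components (coupling the clustering and embedding feature spaces),
#' runs subsampled k-NN Louvain consensus clustering, and cuts the
#' consensus matrix.
#'
#' @param expr an [expression_matrix()] with unit `"log2"`.
#' @param genes selected (highly-variable) genes; `NULL` uses all rows.
#' @param n_pcs principal components to cluster in; `NULL` clusters on
#'   the genes directly.
#' @inheritParams consensus_matrix
#' @inheritParams cut_consensus
#' @return list: `assignment` (a `cluster_assignment`), `consensus`
#'   (a `consensus_matrix`), `features` (the cells x features matrix
#'   used).
#' @export
cluster_cells <- function(expr, genes = NULL, n_pcs = 7, B = 1000,
                          subsample_fraction = 0.7, k = NULL,
                          n_clusters = "auto", seed = 1L) {
  stopifnot(inherits(expr, "expr_matrix"))
  sub <- if (is.null(genes)) expr else em_subset(expr, genes = genes)
  features <- if (is.null(n_pcs)) t(sub$values) else pca_scores(sub, n_pcs)
  cm <- consensus_matrix(features, B = B,
                         subsample_fraction = subsample_fraction,
                         k = k, seed = seed)
  assignment <- cut_consensus(cm, n_clusters = n_clusters)
  list(assignment = assignment, consensus = cm, features = features)
}
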