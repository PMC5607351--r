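# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so failures are reproducible.

# A tiny expression matrix with explicit values.
tiny_em <- function(values, unit = "tpm",
                    genes = sprintf("g%d", seq_len(nrow(values))),
                    cells = sprintf("c%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, cells)
  expression_matrix(values, unit)
}

# The separable clustering world: 5 equal planted clusters, default
# marker program (log2FC 4), SmartSeq2-like noise with dropout 0.3.
separable_spec <- function(n_cells = 250, seed = 21, ...) {
  synthetic_spec(n_cells = n_cells,
                 cluster_proportions = c(A = .2, B = .2, C = .2,
                                         D = .2, E = .2),
                 dropout_rate = 0.3, seed = seed, ...)
}

# Cluster-discriminating markers (log2FC >= 4) of a spec's program.
strong_markers <- function(spec) {
  unique(unlist(lapply(spec$marker_program,
                       function(p) names(p)[p >= 4])))
}

truth_labels <- function(ds) {
  stats::setNames(ds$truth$cells$cluster, ds$truth$cells$cell)
}

# Two well-separated Gaussian blobs in feature space (not expression).
two_blobs <- function(n_per = 50, d = 5, sep = 50, seed = 4) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * d), n_per),
             matrix(stats::rnorm(n_per * d, mean = sep), n_per))
  rownames(x) <- sprintf("cell_%03d", seq_len(2 * n_per))
  x
}
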