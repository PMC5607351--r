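#' Default marker program for the five planted clusters
#'
#' Five transcriptional programs emulating the sorted lung-mesenchyme
#' populations the pipeline is designed for: an epithelial contaminant
#' cluster (A: Epcam, Scgb1a1, Sftpc), two Lgr5-enriched alveolar
#' mesenchymal clusters (B and D, D with additional Lgr6), an alveolar
#' fibroblast cluster (C: Pdgfra, Wnt2, Fgf10, Vcam1) and an airway
#' smooth-muscle cluster (E: Lgr6, Acta2, Cspg4, Tagln, Gli1). Each
#' cluster is padded with clearly-labelled synthetic markers
#' (`mkA1` ...) so that every cluster has `n_extra + named` distinctive
#' genes, and the pan-mesenchymal genes Col1a1, Vim and Pdgfrb are
#' shared across clusters B-E.
#'
#' @param log2_fc marker effect size, log2 fold-change over baseline.
#' @param n_extra synthetic padding markers per cluster.
#' @return named list: cluster -> named numeric vector (gene -> log2FC).
#' @export
default_marker_program <- function(log2_fc = 4, n_extra = 5) {
  pad <- function(cl, n) {
    if (n == 0) return(character(0))
    sprintf("mk%s%d", cl, seq_len(n))
  }
  program <- list(
    A = c("Epcam", "Scgb1a1", "Sftpc", pad("A", n_extra)),
    B = c("Lgr5", pad("B", n_extra + 2)),
    C = c("Pdgfra", "Wnt2", "Fgf10", "Vcam1", pad("C", n_extra - 1)),
    D = c("Lgr5", pad("D", n_extra + 2)),
    E = c("Lgr6", "Acta2", "Cspg4", "Tagln", "Gli1", pad("E", n_extra - 2))
  )
  program <- lapply(program, function(g) stats::setNames(rep(log2_fc, length(g)), g))
  # clusters B/D show "considerable" (not defining) Lgr6 expression
  program$D <- c(program$D, Lgr6 = 2)
  shared <- stats::setNames(rep(2, 3), c("Col1a1", "Vim", "Pdgfrb"))
  for (cl in c("B", "C", "D", "E")) program[[cl]] <- c(program[[cl]], shared)
  program
}

#' Parameterization of the synthetic SmartSeq2-like generator
#'
#' The stated world the generator emulates: 182 sorted cells in two gates
#' (57 Lgr5+, 125 Lgr6+), five latent clusters with marker programs, a
#' negative-binomial count model (variance = mu + mu^2/theta) with
#' independent Bernoulli dropout, and log-normal per-cell library sizes.
#' Cluster proportions default to the split that apportions 182 cells as
#' 11/31/16/26/98 over clusters A-E, putting exactly 57 cells in the
#' Lgr5-gated clusters B and D.
#'
#' @param n_cells number of cells to generate.
#' @param cluster_proportions named fractions over the planted clusters,
#'   summing to 1.
#' @param marker_program named list cluster -> named numeric vector of
#'   log2 fold-changes over baseline (see [default_marker_program()]).
#' @param baseline_mean central relative mean (TPM-scale units) of
#'   non-marker genes.
#' @param baseline_log_sd natural-log standard deviation of the
#'   mean-preserving lognormal spread of per-gene baseline means
#'   (0 = perfectly flat background). Real SmartSeq2 data spans orders
#'   of magnitude in gene abundance; a flat background would also put
#'   only markers into the top mean-expression bins and defeat the
#'   binned dispersion standardization.
#' @param dispersion negative-binomial overdispersion theta (> 0);
#'   `Inf` gives Poisson counts.
#' @param dropout_rate maximum dropout probability, in \[0, 1\]: the chance
#'   that a nonzero count of a lowly-expressed gene is zeroed. The
#'   per-gene probability decays logistically with the planted log2 mean
#'   TPM around `dropout_midpoint`, emulating the expression-dependent
#'   dropout of SmartSeq2 libraries (uniform dropout on high-expression
#'   genes would inject unstructured log-scale variance larger than any
#'   realistic cluster signal).
#' @param dropout_midpoint TPM at which the dropout probability is half
#'   its maximum.
#' @param library_size_lognormal named vector `c(meanlog=, sdlog=)` of the
#'   per-cell total read count distribution.
#' @param qc_failure_plan named integer vector of engineered QC failures,
#'   names in `criterion_1` ... `criterion_6`.
#' @param n_background_genes size of the flat background gene universe.
#' @param housekeeping_panel gene symbols of the housekeeping panel; the
#'   source study does not name its panel, so this is configuration.
#' @param housekeeping_mean relative mean of housekeeping genes.
#' @param reporter_genes named vector mapping roles `tom`, `ptprc`,
#'   `pecam1` to gene symbols.
#' @param tom_mean relative mean of the R26-Tom reporter in Tom-gated
#'   (Lgr5) clusters; zero elsewhere.
#' @param lgr5_gate_clusters clusters whose cells carry the `Lgr5` sort
#'   gate label (Tom+); all other cells are labelled `Lgr6`.
#' @param seed integer RNG seed; identical spec implies bit-identical output.
#' @return a validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_cells = 182,
                           cluster_proportions = c(A = 0.060, B = 0.170,
                                                   C = 0.090, D = 0.143,
                                                   E = 0.537),
                           marker_program = default_marker_program(),
                           baseline_mean = 10,
                           baseline_log_sd = 1,
                           dispersion = 2,
                           dropout_rate = 0.3,
                           dropout_midpoint = 100,
                           library_size_lognormal = c(meanlog = log(1e5),
                                                      sdlog = 0.35),
                           qc_failure_plan = integer(0),
                           n_background_genes = 2000,
                           housekeeping_panel = c("Gapdh", "Actb", "B2m",
                                                  "Hprt", "Ppia", "Tbp",
                                                  "Ubc", "Rpl13a", "Sdha",
                                                  "Ywhaz"),
                           housekeeping_mean = 8 * baseline_mean,
                           reporter_genes = c(tom = "R26-Tom",
                                              ptprc = "Ptprc",
                                              pecam1 = "Pecam1"),
                           tom_mean = 32 * baseline_mean,
                           lgr5_gate_clusters = c("B", "D"),
                           seed = 1L) {
  spec <- list(
    n_cells = as.integer(n_cells),
    cluster_proportions = cluster_proportions,
    marker_program = marker_program,
    baseline_mean = baseline_mean,
    baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    dropout_rate = dropout_rate,
    dropout_midpoint = dropout_midpoint,
    library_size_lognormal = library_size_lognormal,
    qc_failure_plan = qc_failure_plan,
    n_background_genes = as.integer(n_background_genes),
    housekeeping_panel = housekeeping_panel,
    housekeeping_mean = housekeeping_mean,
    reporter_genes = reporter_genes,
    tom_mean = tom_mean,
    lgr5_gate_clusters = lgr5_gate_clusters,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_cells < 1) stop("n_cells must be positive")
    if (abs(sum(cluster_proportions) - 1) > 1e-9)
      stop("cluster_proportions must sum to 1")
    if (any(cluster_proportions < 0)) stop("cluster proportions must be >= 0")
    if (is.null(names(cluster_proportions)))
      stop("cluster_proportions must be named")
    if (!all(names(marker_program) %in% names(cluster_proportions)))
      stop("marker_program names unknown clusters: ",
           paste(setdiff(names(marker_program), names(cluster_proportions)),
                 collapse = ", "))
    if (baseline_mean <= 0 || housekeeping_mean < 0 || tom_mean < 0)
      stop("mean expression parameters must be non-negative")
    if (baseline_log_sd < 0) stop("baseline_log_sd must be >= 0")
    if (dispersion <= 0) stop("dispersion theta must be > 0")
    if (dropout_rate < 0 || dropout_rate > 1)
      stop("dropout_rate must lie in [0, 1]")
    if (dropout_midpoint <= 0) stop("dropout_midpoint must be positive")
    if (!all(c("meanlog", "sdlog") %in% names(library_size_lognormal)))
      stop("library_size_lognormal must have meanlog and sdlog")
    if (length(qc_failure_plan) > 0) {
      bad <- setdiff(names(qc_failure_plan), qc_criteria())
      if (length(bad) > 0)
        stop("unknown QC criteria in failure plan: ",
             paste(bad, collapse = ", "))
      if (sum(qc_failure_plan) > n_cells)
        stop("n_cells is smaller than the engineered-failure total")
    }
    if (!all(c("tom", "ptprc", "pecam1") %in% names(reporter_genes)))
      stop("reporter_genes must map tom, ptprc and pecam1")
  })
  invisible(spec)
}

# Largest-remainder apportionment of n items over fractional proportions.
apportion <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# Genes x clusters matrix of relative means implied by a spec, plus the
# full gene universe (background + markers + housekeeping + reporters).
planted_mean_matrix <- function(spec, gene_universe = NULL) {
  marker_genes <- unique(unlist(lapply(spec$marker_program, names)))
  named <- unique(c(marker_genes, spec$housekeeping_panel,
                    unname(spec$reporter_genes)))
  if (is.null(gene_universe)) {
    background <- sprintf("bg%04d", seq_len(spec$n_background_genes))
    clash <- intersect(background, named)
    if (length(clash) > 0)
      stop("marker symbols clash with reserved background names: ",
           paste(clash, collapse = ", "))
    gene_universe <- c(named, background)
  } else {
    missing <- setdiff(named, gene_universe)
    if (length(missing) > 0)
      stop("gene universe is missing required symbols: ",
           paste(missing, collapse = ", "))
  }
  clusters <- names(spec$cluster_proportions)
  # mean-preserving lognormal spread of baseline means, deterministic in
  # the spec seed and independent of the count-sampling stream
  base <- if (spec$baseline_log_sd > 0) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(derive_seeds(spec$seed, 2)[2])
    spec$baseline_mean * stats::rlnorm(length(gene_universe),
                                       meanlog = -spec$baseline_log_sd^2 / 2,
                                       sdlog = spec$baseline_log_sd)
  } else rep(spec$baseline_mean, length(gene_universe))
  m <- matrix(base, nrow = length(gene_universe),
              ncol = length(clusters),
              dimnames = list(gene_universe, clusters))
  m[spec$housekeeping_panel, ] <- spec$housekeeping_mean
  m[spec$reporter_genes[["ptprc"]], ] <- 0
  m[spec$reporter_genes[["pecam1"]], ] <- 0
  tom <- spec$reporter_genes[["tom"]]
  m[tom, ] <- 0
  m[tom, intersect(spec$lgr5_gate_clusters, clusters)] <- spec$tom_mean
  base_of <- stats::setNames(base, gene_universe)
  for (cl in names(spec$marker_program)) {
    prog <- spec$marker_program[[cl]]
    # fold change over the gene's own baseline, not the global center
    m[names(prog), cl] <- base_of[names(prog)] * 2^unname(prog)
  }
  m
}

#' Generate a synthetic SmartSeq2-like dataset with known ground truth
#'
#' Counts are drawn per gene from a negative binomial with cluster-specific
#' means (scaled to a nominal depth of 100,000), then resampled
#' multinomially to the cell's drawn library size, then thinned by
#' independent Bernoulli dropout. TPM is the count matrix rescaled so each
#' cell sums to 1e6 (all synthetic genes share unit effective length).
#' Identical spec (including seed) gives bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @param gene_universe optional explicit gene universe; must contain every
#'   marker, housekeeping and reporter symbol (configuration error
#'   otherwise). `NULL` builds the default universe of
#'   `n_background_genes` background genes plus all named genes.
#' @return list with elements `counts` and `tpm` (both [expression_matrix()]
#'   objects), and `truth`: a list with `cells` (data.frame: cell, cluster,
#'   gate), `planted_means` (gene x cluster TPM-scale means, columns sum to
#'   1e6), and `engineered_failures` (named list cell -> criteria).
#' @export
generate_dataset <- function(spec, gene_universe = NULL) {
  validate_synthetic_spec(spec)
  m_rel <- planted_mean_matrix(spec, gene_universe)
  clusters <- names(spec$cluster_proportions)
  counts_per_cluster <- apportion(spec$n_cells, spec$cluster_proportions)
  cell_cluster <- rep(clusters, counts_per_cluster)
  cell_ids <- sprintf("cell_%04d", seq_len(spec$n_cells))
  gate <- ifelse(cell_cluster %in% spec$lgr5_gate_clusters, "Lgr5", "Lgr6")

  n_genes <- nrow(m_rel)
  counts <- matrix(0, nrow = n_genes, ncol = spec$n_cells,
                   dimnames = list(rownames(m_rel), cell_ids))
  planted_tpm <- sweep(m_rel, 2, colSums(m_rel) / 1e6, "/")
  # expression-dependent dropout: logistic decay in log2 planted TPM
  drop_prob <- spec$dropout_rate /
    (1 + exp(log2(planted_tpm + 1) - log2(spec$dropout_midpoint + 1)))
  set.seed(spec$seed)
  lib_sizes <- pmax(1000, round(stats::rlnorm(
    spec$n_cells,
    meanlog = spec$library_size_lognormal[["meanlog"]],
    sdlog = spec$library_size_lognormal[["sdlog"]])))
  for (c_i in seq_len(spec$n_cells)) {
    mu_rel <- m_rel[, cell_cluster[c_i]]
    mu <- mu_rel / sum(mu_rel) * 1e5
    x <- if (is.infinite(spec$dispersion)) {
      stats::rpois(n_genes, lambda = mu)
    } else {
      stats::rnbinom(n_genes, mu = mu, size = spec$dispersion)
    }
    if (sum(x) == 0) x <- mu    # degenerate draw: fall back to the means
    y <- as.vector(stats::rmultinom(1, size = lib_sizes[c_i], prob = x))
    if (spec$dropout_rate > 0) {
      nz <- which(y > 0)
      p <- drop_prob[nz, cell_cluster[c_i]]
      dropped <- nz[stats::runif(length(nz)) < p]
      if (length(dropped) == length(nz))      # keep the cell observable
        dropped <- dropped[-which.max(y[dropped])]
      y[dropped] <- 0
    }
    counts[, c_i] <- y
  }
  counts_em <- expression_matrix(counts, "counts")
  tpm_em <- as_tpm(counts_em)

  truth <- list(
    cells = data.frame(cell = cell_ids, cluster = cell_cluster, gate = gate,
                       stringsAsFactors = FALSE),
    planted_means = planted_tpm,
    engineered_failures = stats::setNames(list(), character(0))
  )

  if (length(spec$qc_failure_plan) > 0 && sum(spec$qc_failure_plan) > 0) {
    inj <- inject_qc_failures(
      tpm_em, spec$qc_failure_plan,
      housekeeping_panel = spec$housekeeping_panel,
      reporters = spec$reporter_genes,
      gate = stats::setNames(gate, cell_ids),
      seed = spec$seed)
    tpm_em <- inj$tpm
    truth$engineered_failures <- inj$failures
  }

  list(counts = counts_em, tpm = tpm_em, truth = truth)
}

#' Generator parameterization for QC-demonstration fixtures
#'
#' The QC stage is pure threshold logic, so its fixture world suppresses
#' Bernoulli dropout (which would otherwise zero reporter genes in ~30%
#' of cells and trigger spurious reporter-criterion failures) and
#' instead lets expressed-gene counts vary through multinomial sampling
#' at a ~12,000-read library: clean cells then express ~2,470 of the
#' ~2,550-gene universe — comfortably above the 2000-gene floor, with
#' enough spread that the engineered all-gene outlier is a unique
#' maximum. The background universe is enlarged to 2,500 genes because
#' criterion 1 needs clean cells with at least 2000 expressed genes.
#'
#' @param n_cells fixture size (default 62: 56 clean cells plus one
#'   engineered failure per criterion).
#' @param qc_failure_plan engineered failures; default one per criterion.
#' @param seed RNG seed.
#' @param ... further overrides passed to [synthetic_spec()].
#' @return a [synthetic_spec()].
#' @export
qc_fixture_spec <- function(n_cells = 62,
                            qc_failure_plan = stats::setNames(rep(1L, 6),
                                                              qc_criteria()),
                            seed = 1L, ...) {
  synthetic_spec(n_cells = n_cells,
                 n_background_genes = 2500,
                 baseline_log_sd = 0,
                 dropout_rate = 0,
                 library_size_lognormal = c(meanlog = log(12000),
                                            sdlog = 0.12),
                 qc_failure_plan = qc_failure_plan,
                 seed = seed, ...)
}

#' Engineer per-criterion QC failures into a TPM matrix
#'
#' Edits selected cells so each violates exactly the targeted exclusion
#' threshold while remaining otherwise plausible; edited columns are
#' renormalized to TPM. Victim cells are drawn deterministically from
#' `seed` and never reused across criteria.
#'
#' @param tpm an [expression_matrix()] with unit `"tpm"`.
#' @param plan named integer vector, names in `criterion_1` ...
#'   `criterion_6`, values = number of cells to break per criterion.
#' @param housekeeping_panel genes used by criterion 2.
#' @param reporters named vector mapping `tom`, `ptprc`, `pecam1` to rows.
#' @param gate optional named character vector (cell -> `"Lgr5"`/`"Lgr6"`);
#'   required when planting `criterion_4` (insufficient Tom in a Tom-gated
#'   cell).
#' @param thresholds a [qc_thresholds()]; the edits are placed safely
#'   beyond these thresholds.
#' @param seed RNG seed for victim selection.
#' @return list(`tpm` = edited matrix, `failures` = named list
#'   cell -> character vector of planted criteria). An empty plan returns
#'   the input matrix unchanged.
#' @export
inject_qc_failures <- function(tpm, plan,
                               housekeeping_panel,
                               reporters = c(tom = "R26-Tom", ptprc = "Ptprc",
                                             pecam1 = "Pecam1"),
                               gate = NULL,
                               thresholds = qc_thresholds(),
                               seed = 1L) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$unit != "tpm") stop("inject_qc_failures expects a TPM matrix")
  bad <- setdiff(names(plan), qc_criteria())
  if (length(bad) > 0)
    stop("unknown QC criteria: ", paste(bad, collapse = ", "))
  plan <- plan[plan > 0]
  if (length(plan) == 0)
    return(list(tpm = tpm, failures = stats::setNames(list(), character(0))))
  if (sum(plan) > ncol(tpm$values))
    stop("fewer cells than planned failures")

  v <- tpm$values
  cells <- colnames(v)
  set.seed(seed)
  pool <- sample(cells)
  if ("criterion_4" %in% names(plan)) {
    if (is.null(gate)) stop("criterion_4 failures require sort-gate labels")
    tom_cells <- intersect(pool, names(gate)[gate == "Lgr5"])
    if (length(tom_cells) < plan[["criterion_4"]])
      stop("not enough Tom-gated cells to plant criterion_4 failures")
  }

  failures <- list()
  used <- character(0)
  take <- function(n, from = pool) {
    avail <- setdiff(from, used)
    if (length(avail) < n) stop("not enough unused cells for the plan")
    avail[seq_len(n)]
  }
  # criterion_4 victims are constrained to the Tom gate; pick them first
  order_crit <- c(intersect("criterion_4", names(plan)),
                  setdiff(names(plan), "criterion_4"))
  for (crit in order_crit) {
    n <- plan[[crit]]
    victims <- if (crit == "criterion_4") {
      take(n, intersect(pool, names(gate)[gate == "Lgr5"]))
    } else take(n)
    used <- c(used, victims)
    for (cell in victims) {
      col <- v[, cell]
      if (crit == "criterion_1") {
        keep_n <- max(1, thresholds$min_expressed_genes - 500)
        keep <- order(col, decreasing = TRUE)[seq_len(min(keep_n, length(col)))]
        col[-keep] <- 0
      } else if (crit == "criterion_2") {
        col[housekeeping_panel] <- thresholds$min_housekeeping_mean_tpm / 3
      } else if (crit == "criterion_3") {
        col[col == 0] <- 0.5
      } else if (crit == "criterion_4") {
        col[reporters[["tom"]]] <- thresholds$tom_tpm_threshold / 2
      } else if (crit == "criterion_5") {
        col[reporters[["ptprc"]]] <- 4 * thresholds$ptprc_tpm_threshold
      } else if (crit == "criterion_6") {
        col[reporters[["pecam1"]]] <- 4 * thresholds$pecam1_tpm_threshold
      }
      v[, cell] <- col / sum(col) * 1e6
      failures[[cell]] <- c(failures[[cell]], crit)
    }
  }
  list(tpm = expression_matrix(v, "tpm"), failures = failures)
}
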