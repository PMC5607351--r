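test_that("default 182-cell world reproduces the sorted-population split", {
  ds <- generate_dataset(synthetic_spec(seed = 3))
  expect_equal(dim(ds$counts), c(nrow(ds$truth$planted_means), 182))
  expect_equal(as.vector(table(ds$truth$cells$gate)), c(57, 125))
  expect_setequal(unique(ds$truth$cells$cluster), LETTERS[1:5])
  # TPM columns sum to 1e6
  expect_equal(colSums(ds$tpm$values), rep(1e6, 182),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  spec <- synthetic_spec(n_cells = 40, n_background_genes = 200, seed = 9)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$tpm$values, b$tpm$values)
  spec2 <- synthetic_spec(n_cells = 40, n_background_genes = 200, seed = 10)
  c <- generate_dataset(spec2)
  expect_false(identical(a$counts$values, c$counts$values))
})

test_that("per-cluster means converge to planted means in the noise-free limit", {
  program <- list(X = c(mX1 = 4, mX2 = 4), Y = c(mY1 = 4, mY2 = 4))
  spec <- synthetic_spec(
    n_cells = 1000,
    cluster_proportions = c(X = 0.5, Y = 0.5),
    marker_program = program,
    baseline_log_sd = 0, dispersion = Inf, dropout_rate = 0,
    library_size_lognormal = c(meanlog = log(1e5), sdlog = 0),
    n_background_genes = 300, seed = 12)
  ds <- generate_dataset(spec)
  truth <- truth_labels(ds)
  for (cl in c("X", "Y")) {
    emp <- rowMeans(ds$tpm$values[, truth == cl])
    planted <- ds$truth$planted_means[, cl]
    pos <- planted > 0
    expect_lt(max(abs(emp[pos] - planted[pos]) / planted[pos]), 0.05)
  }
})

test_that("planted clusters are separable in correlation at default noise", {
  ds <- generate_dataset(separable_spec(n_cells = 150, seed = 6))
  truth <- truth_labels(ds)
  co <- stats::cor(log2p1(ds$tpm)$values)
  same <- outer(truth[rownames(co)], truth[colnames(co)], "==")
  diag(same) <- NA
  expect_gt(mean(co[which(same)]), mean(co[which(!same)]))
})

test_that("spec validation rejects inconsistent parameterizations", {
  expect_error(synthetic_spec(cluster_proportions = c(A = 0.6, B = 0.5)),
               "sum to 1")
  expect_error(synthetic_spec(dispersion = 0), "theta")
  expect_error(synthetic_spec(dropout_rate = 1.2), "dropout_rate")
  expect_error(
    synthetic_spec(qc_failure_plan = c(criterion_7 = 1L)), "unknown QC")
  expect_error(
    synthetic_spec(n_cells = 3,
                   qc_failure_plan = stats::setNames(rep(1L, 6),
                                                     qc_criteria())),
    "smaller than the engineered-failure total")
  # explicit gene universe must contain every named gene
  spec <- synthetic_spec(n_cells = 10, n_background_genes = 50)
  expect_error(generate_dataset(spec, gene_universe = c("bg0001", "Lgr5")),
               "missing required symbols")
})

test_that("inject_qc_failures plants exactly the requested violations", {
  spec <- qc_fixture_spec(qc_failure_plan = integer(0), seed = 15)
  ds <- generate_dataset(spec)
  gate <- stats::setNames(ds$truth$cells$gate, ds$truth$cells$cell)

  # empty plan: bit-identical matrix
  same <- inject_qc_failures(ds$tpm, integer(0), spec$housekeeping_panel)
  expect_identical(same$tpm$values, ds$tpm$values)

  inj <- inject_qc_failures(
    ds$tpm, c(criterion_1 = 3L, criterion_2 = 2L),
    housekeeping_panel = spec$housekeeping_panel,
    reporters = spec$reporter_genes, gate = gate, seed = 2)
  v <- inj$tpm$values
  crit1 <- names(inj$failures)[vapply(inj$failures, function(f)
    "criterion_1" %in% f, logical(1))]
  crit2 <- names(inj$failures)[vapply(inj$failures, function(f)
    "criterion_2" %in% f, logical(1))]
  expect_length(crit1, 3)
  expect_length(crit2, 2)
  expect_true(all(colSums(v[, crit1] > 0) < 2000))
  expect_true(all(colMeans(v[spec$housekeeping_panel, crit2]) < 1.5))
  # edited columns are still TPM
  expect_equal(colSums(v), rep(1e6, ncol(v)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # untouched cells are bit-identical
  clean <- setdiff(colnames(v), names(inj$failures))
  expect_identical(v[, clean], ds$tpm$values[, clean])

  expect_error(inject_qc_failures(ds$tpm, c(criterion_9 = 1L),
                                  spec$housekeeping_panel), "unknown")
  expect_error(inject_qc_failures(ds$tpm, c(criterion_4 = 1L),
                                  spec$housekeeping_panel,
                                  reporters = spec$reporter_genes),
               "gate")
})
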