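hk <- c("hk1", "hk2")
reporters <- c(tom = "R26-Tom", ptprc = "Ptprc", pecam1 = "Pecam1")

# A hand-built TPM matrix exercising the printed boundaries.
boundary_tpm <- function() {
  n_genes <- 2100
  genes <- c(hk, unname(reporters), sprintf("g%04d", seq_len(n_genes - 5)))
  cells <- c("ok", "g1999", "allzero_like", "hk_boundary")
  v <- matrix(0, n_genes, length(cells), dimnames = list(genes, cells))
  # "ok": 2050 expressed genes, clean reporters, healthy housekeeping
  v[6:2055, "ok"] <- 10
  v[hk, "ok"] <- 100
  # exactly 1999 genes at TPM > 0
  v[6:2004, "g1999"] <- 10
  # one expressed gene only
  v["g0001", "allzero_like"] <- 5
  # housekeeping mean exactly at the 1.5 boundary: {1.0, 2.0}
  v[6:2055, "hk_boundary"] <- 10
  v["hk1", "hk_boundary"] <- 1
  v["hk2", "hk_boundary"] <- 2
  tiny_em(v, "tpm", genes = genes, cells = cells)
}

test_that("cell metrics hit the printed boundaries exactly", {
  m <- compute_cell_metrics(boundary_tpm(), hk, reporters)
  expect_equal(m$expressed_genes[m$cell == "g1999"], 1999)
  expect_equal(m$expressed_genes[m$cell == "allzero_like"], 1)
  expect_equal(m$housekeeping_mean_tpm[m$cell == "hk_boundary"], 1.5)

  r <- apply_exclusion(m, qc_thresholds())
  expect_true(r[r$cell == "g1999", "criterion_1"])      # 1999 < 2000
  expect_false(r[r$cell == "ok", "criterion_1"])
  # boundary is strict: housekeeping mean of exactly 1.5 passes
  expect_false(r[r$cell == "hk_boundary", "criterion_2"])
  # all-zero-like cell: metrics still defined
  expect_equal(m$housekeeping_mean_tpm[m$cell == "allzero_like"], 0)
})

test_that("metric preconditions are enforced", {
  em <- boundary_tpm()
  expect_error(compute_cell_metrics(em, character(0)), "empty housekeeping")
  expect_error(compute_cell_metrics(em, c("hk1", "nope")), "absent")
  expect_error(compute_cell_metrics(log2p1(em), hk), "TPM")
  # missing reporter row: metric NA, enabled criterion errors at exclusion
  m <- compute_cell_metrics(em, hk, c(tom = "R26-Tom", ptprc = "gone",
                                      pecam1 = "Pecam1"))
  expect_true(all(is.na(m$ptprc_tpm)))
  expect_error(apply_exclusion(m, qc_thresholds()), "criterion_5")
  ok <- apply_exclusion(m, qc_thresholds(enabled = c(criterion_5 = FALSE)))
  expect_false(any(ok$criterion_5))
})

test_that("outlier criterion matches a sorted-array oracle on clean cells", {
  # 200 distinct expressed-gene counts; brute-force oracle: with f = 0.01
  # the top ceiling(0.01 * 200) = 2 cells fall, 198 are retained
  set.seed(7)
  counts <- sample(3000:5000, 200)
  metrics <- data.frame(
    cell = sprintf("c%03d", 1:200),
    expressed_genes = counts,
    housekeeping_mean_tpm = 100, tom_tpm = 100,
    ptprc_tpm = 0, pecam1_tpm = 0,
    gate = "Lgr5", stringsAsFactors = FALSE)
  r <- apply_exclusion(metrics, qc_thresholds())
  sorted <- sort(counts)                       # oracle: plain sorted array
  expect_equal(attr(r, "outlier_cutoff"), sorted[198])
  expect_setequal(r$cell[r$criterion_3],
                  metrics$cell[counts > sorted[198]])
  expect_equal(sum(r$retained), 198)
  # the maximum-count cell is always among the excluded
  expect_true(r$criterion_3[which.max(counts)])
})

test_that("literal mode applies the printed directions verbatim", {
  m <- data.frame(cell = c("a", "b"), expressed_genes = c(3000, 3000),
                  housekeeping_mean_tpm = 100,
                  tom_tpm = c(40, 10), ptprc_tpm = c(0, 2),
                  pecam1_tpm = c(0, 2), gate = NA_character_,
                  stringsAsFactors = FALSE)
  r <- apply_exclusion(m, qc_thresholds(mode = "literal"))
  expect_true(r[r$cell == "a", "criterion_4"])    # Tom > 32 excluded
  expect_true(r[r$cell == "a", "criterion_5"])    # Ptprc < 1 excluded
  expect_true(r[r$cell == "a", "criterion_6"])
  expect_false(r[r$cell == "b", "criterion_5"])
  # coherent mode flips 5/6 and skips Tom without gates
  r2 <- apply_exclusion(m, qc_thresholds(mode = "coherent"))
  expect_false(any(r2$criterion_4))
  expect_true(r2[r2$cell == "b", "criterion_5"])
  expect_false(r2[r2$cell == "a", "criterion_5"])
})

test_that("engineered 62-cell fixture retains 56 with per-cell criterion tags", {
  spec <- qc_fixture_spec(seed = 11)
  ds <- generate_dataset(spec)
  gate <- stats::setNames(ds$truth$cells$gate, ds$truth$cells$cell)
  qc <- qc_filter(ds$tpm, spec$housekeeping_panel, spec$reporter_genes,
                  gate = gate)
  expect_length(qc$retained_cells, 56)
  expect_equal(dim(qc$tpm), c(nrow(ds$tpm$values), 56))
  for (cell in names(ds$truth$engineered_failures)) {
    row <- qc$report[qc$report$cell == cell, ]
    expect_false(row$retained)
    flagged <- qc_criteria()[unlist(row[, qc_criteria()])]
    expect_identical(flagged, ds$truth$engineered_failures[[cell]])
  }
})

test_that("retention equals absence of flags, and filtering is monotone and idempotent", {
  spec <- qc_fixture_spec(seed = 23)
  ds <- generate_dataset(spec)
  gate <- stats::setNames(ds$truth$cells$gate, ds$truth$cells$cell)
  metrics <- compute_cell_metrics(ds$tpm, spec$housekeeping_panel,
                                  spec$reporter_genes, gate)
  base <- apply_exclusion(metrics, qc_thresholds())
  # flag/retention consistency
  expect_equal(base$retained,
               unname(rowSums(as.matrix(base[, qc_criteria()])) == 0))
  # relaxing single thresholds never shrinks the retained set
  relaxed <- list(
    qc_thresholds(min_expressed_genes = 1000),
    qc_thresholds(min_housekeeping_mean_tpm = 0.1),
    qc_thresholds(outlier_gene_fraction = 0.002),
    qc_thresholds(tom_tpm_threshold = 1e-3),
    qc_thresholds(ptprc_tpm_threshold = 50),
    qc_thresholds(pecam1_tpm_threshold = 50))
  for (th in relaxed) {
    r <- apply_exclusion(metrics, th)
    expect_true(all(base$cell[base$retained] %in% r$cell[r$retained]))
  }
  # idempotence with the criterion-3 cutoff frozen
  kept <- metrics[base$retained, ]
  again <- apply_exclusion(kept, qc_thresholds(),
                           outlier_cutoff = attr(base, "outlier_cutoff"))
  expect_true(all(again$retained))
})

test_that("empty input warns and returns an empty report", {
  m <- compute_cell_metrics(boundary_tpm(), hk, reporters)
  expect_warning(r <- apply_exclusion(m[0, ], qc_thresholds()), "empty")
  expect_equal(nrow(r), 0)
})
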