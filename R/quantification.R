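#' qPCR fold change by the delta-delta-Ct method
#'
#' Per sample, deltaCt = Ct(target) - Ct(reference gene, e.g. Gapdh);
#' group deltaCt is the mean over replicates; fold change of a group is
#' 2^-(deltaCt_group - deltaCt_reference_group), so the reference group
#' is exactly 1 for any input. `per_replicate = TRUE` instead averages
#' per-replicate fold changes (both conventions are reported in the
#' field; the group-mean form is the standard deltaCt wording).
#'
#' @param measurements data.frame with columns `group`, `ct_target`,
#'   `ct_reference` (one row per replicate).
#' @param reference_group group whose expression is set to 1.
#' @param per_replicate use the per-replicate averaging convention.
#' @return data.frame: group, n, delta_ct (mean), fold_change, and
#'   `fold_change_sd` (SD of per-replicate fold changes around the
#'   group estimate).
#' @export
delta_ct_fold_change <- function(measurements, reference_group,
                                 per_replicate = FALSE) {
  req <- c("group", "ct_target", "ct_reference")
  missing <- setdiff(req, names(measurements))
  if (length(missing) > 0)
    stop("measurements lack columns: ", paste(missing, collapse = ", "))
  if (anyNA(measurements$ct_reference) || anyNA(measurements$ct_target))
    stop("missing Ct values")
  if (any(measurements$ct_target <= 0 | measurements$ct_reference <= 0))
    stop("Ct values must be positive")
  if (!(reference_group %in% measurements$group))
    stop("reference group '", reference_group, "' not present")

  dct <- measurements$ct_target - measurements$ct_reference
  groups <- unique(measurements$group)
  dct_mean <- vapply(groups, function(g) mean(dct[measurements$group == g]),
                     numeric(1))
  ref_dct <- dct_mean[[reference_group]]

  fc <- if (per_replicate) {
    vapply(groups, function(g)
      mean(2^-(dct[measurements$group == g] - ref_dct)), numeric(1))
  } else 2^-(dct_mean - ref_dct)
  if (!per_replicate) fc[[reference_group]] <- 1  # exact, not 2^-0 rounding

  fc_sd <- vapply(groups, function(g)
    stats::sd(2^-(dct[measurements$group == g] - ref_dct)), numeric(1))
  data.frame(group = groups,
             n = as.integer(table(measurements$group)[groups]),
             delta_ct = unname(dct_mean),
             fold_change = unname(fc),
             fold_change_sd = unname(fc_sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Colony-forming efficiency
#'
#' Colonies formed divided by cells plated, as a percentage. Vectorized
#' over wells.
#'
#' @param n_colonies colonies scored per well (>= 0).
#' @param n_plated cells plated per well (> 0).
#' @return percentage(s).
#' @export
colony_forming_efficiency <- function(n_colonies, n_plated) {
  if (any(n_plated <= 0)) stop("n_plated must be positive")
  if (any(n_colonies < 0)) stop("n_colonies must be >= 0")
  100 * n_colonies / n_plated
}

#' Mean and SD of per-well colony-forming efficiencies
#'
#' @param cfe vector of per-well CFE percentages (e.g. from
#'   [colony_forming_efficiency()]).
#' @return list with `mean` and `sd` (SD is `NA` for a single well).
#' @export
cfe_summary <- function(cfe) {
  list(mean = mean(cfe), sd = stats::sd(cfe))
}

#' Clone-size distribution
#'
#' Bins clone sizes (cells per clone) into the reporting categories
#' 1, 2, 3, 4, 5-8 and 9+ by default (configurable edges) and returns
#' the fraction of clones per bin, the mean clone size and the clone
#' count. Fractions always sum to 1; a percent column rounded to two
#' decimals is included for display.
#'
#' @param sizes positive integer clone sizes.
#' @param breaks lower bin edges (ascending, starting at 1); each bin
#'   spans up to the next edge minus one, the last is open-ended.
#' @return list: `table` (data.frame bin, n, fraction, percent),
#'   `mean_size`, `n_clones`.
#' @export
clone_size_distribution <- function(sizes, breaks = c(1, 2, 3, 4, 5, 9)) {
  if (length(sizes) == 0) stop("need at least one clone")
  if (any(sizes < 1) || any(abs(sizes - round(sizes)) > 1e-8))
    stop("clone sizes must be positive integers")
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1] != 1)
    stop("breaks must be strictly ascending and start at 1")
  upper <- c(breaks[-1] - 1, Inf)
  labels <- ifelse(is.infinite(upper), paste0(breaks, "+"),
                   ifelse(breaks == upper, as.character(breaks),
                          paste0(breaks, "-", upper)))
  bin <- findInterval(sizes, breaks)
  n <- tabulate(bin, nbins = length(breaks))
  fraction <- n / length(sizes)
  list(table = data.frame(bin = labels, n = n, fraction = fraction,
                          percent = round(100 * fraction, 2),
                          stringsAsFactors = FALSE),
       mean_size = mean(sizes),
       n_clones = length(sizes))
}
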