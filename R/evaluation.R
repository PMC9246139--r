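#' Rand index between two partitions
#'
#' Proportion of observation pairs on which the two partitions agree: a pair
#' is concordant when it is co-clustered in both or separated in both. The
#' plain (unadjusted) index of Rand (1971); for two balanced groups, random
#' assignment yields about 0.5. Invariant to relabeling of either partition
#' and symmetric in its arguments.
#'
#' @param labels_a,labels_b Equal-length cluster labels (length >= 2).
#' @return The index, in [0, 1]; 1 means identical partitions.
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 1/3
#' @export
rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions must have equal length")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 observations")
  tab <- table(labels_a, labels_b)
  total <- choose(n, 2)
  same_both <- sum(choose(tab, 2))
  same_a <- sum(choose(rowSums(tab), 2))
  same_b <- sum(choose(colSums(tab), 2))
  (total + 2 * same_both - same_a - same_b) / total
}

# population (divide-by-n) standard deviation
.sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

#' Aggregate replicate results into a scenario summary
#'
#' Tallies the distribution of the selected number of clusters (1, 2, 3, >3,
#' plus full counts 1-5), the proportion of replicates selecting the true k,
#' and the mean and population SD of the per-replicate Rand index against
#' the true labels. For one-group scenarios the Rand index against the
#' all-ones truth is reported as well: it is well-defined (driven by the
#' sizes of the spurious clusters) but should be interpreted with care.
#'
#' @param results Non-empty list of replicate records, each a list with
#'   elements `result` (a `cluster_result`) and `dataset` (a
#'   `clustsim_dataset`); all must share the same scenario and method.
#' @param n_failed Number of additional replicates that failed outright
#'   (excluded from the proportions; reported in the summary).
#' @return A one-row data frame of class `scenario_summary`.
#' @export
summarize_scenario <- function(results, n_failed = 0L) {
  if (length(results) == 0) stop("no replicate results to summarize")
  labels <- vapply(results, function(r) r$dataset$spec$label, "")
  methods <- vapply(results, function(r) r$result$method, "")
  if (length(unique(labels)) != 1 || length(unique(methods)) != 1)
    stop("all results must share the same scenario and method")
  spec <- results[[1]]$dataset$spec
  k_sel <- vapply(results, function(r) r$result$k_selected, 0L)
  rand <- vapply(results, function(r)
    rand_index(r$result$labels, r$dataset$true_labels), 0)
  n_rep <- length(results)
  prop_k <- function(cond) mean(cond)
  out <- data.frame(
    label = spec$label, method = methods[1],
    p = spec$p, n = spec$n, true_k = spec$true_k,
    d_lo = spec$d_range[1], d_hi = spec$d_range[2],
    rho_lo = spec$rho_range[1], rho_hi = spec$rho_range[2],
    n_replicates = n_rep, n_failed = as.integer(n_failed),
    k1 = sum(k_sel == 1L), k2 = sum(k_sel == 2L), k3 = sum(k_sel == 3L),
    k4 = sum(k_sel == 4L), k5 = sum(k_sel == 5L),
    prop_k1 = prop_k(k_sel == 1L), prop_k2 = prop_k(k_sel == 2L),
    prop_k3 = prop_k(k_sel == 3L), prop_k_gt3 = prop_k(k_sel > 3L),
    prop_correct = mean(k_sel == spec$true_k),
    rand_mean = mean(rand), rand_sd = .sd_pop(rand),
    stringsAsFactors = FALSE)
  class(out) <- c("scenario_summary", class(out))
  out
}

#' Write scenario summaries as CSV
#'
#' One row per scenario x method, with the scenario factors, per-k counts,
#' and Rand index mean/SD (the supplementary-table layout).
#'
#' @param summaries Data frame of stacked [summarize_scenario()] rows.
#' @param path Output file path.
#' @export
write_summary_csv <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}
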