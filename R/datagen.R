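#' Define a simulation scenario
#'
#' A scenario is one cell of the design-analysis grid: the number of
#' indicators, the sample size, the true number of latent groups, and the
#' uniform sampling ranges for the standardized mean difference (Cohen's d)
#' and the common pairwise correlation between indicators.
#'
#' @param p Number of indicators (>= 2).
#' @param n Sample size (>= 2).
#' @param true_k True number of latent groups, 1 or 2. With `true_k = 1` the
#'   effect size is fixed at 0 and `d_range` is ignored.
#' @param d_range Length-2 bounds `(a, b)` of the uniform distribution the
#'   effect size is drawn from; dimensionless standardized mean difference
#'   applied to every indicator of group 2.
#' @param rho_range Length-2 bounds `(c, d)` of the uniform distribution the
#'   common pairwise correlation is drawn from; both bounds in (-1, 1).
#' @param label Free-text scenario identifier; a default is composed from the
#'   other fields.
#'
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec(p = 6, n = 500, true_k = 2,
#'               d_range = c(0.60, 1.00), rho_range = c(0.10, 0.30))
#' @export
scenario_spec <- function(p, n, true_k, d_range = c(0, 0), rho_range,
                          label = NULL) {
  p <- as.integer(p); n <- as.integer(n); true_k <- as.integer(true_k)
  stopifnot(length(p) == 1, p >= 2,
            length(n) == 1, n >= 2,
            true_k %in% c(1L, 2L),
            length(d_range) == 2, length(rho_range) == 2)
  d_range <- as.numeric(d_range); rho_range <- as.numeric(rho_range)
  if (true_k == 1L) d_range <- c(0, 0)
  if (d_range[1] > d_range[2])
    stop("d_range must satisfy a <= b")
  if (!(rho_range[1] > -1 && rho_range[1] <= rho_range[2] && rho_range[2] < 1))
    stop("rho_range must satisfy -1 < c <= d < 1")
  if (is.null(label))
    label <- sprintf("k%d_p%d_N%d_d%.2f-%.2f_r%.2f-%.2f",
                     true_k, p, n, d_range[1], d_range[2],
                     rho_range[1], rho_range[2])
  structure(list(p = p, n = n, true_k = true_k,
                 d_range = d_range, rho_range = rho_range, label = label),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s': p = %d, N = %d, true k = %d, d ~ U(%.2f, %.2f), rho ~ U(%.2f, %.2f)\n",
    x$label, x$p, x$n, x$true_k, x$d_range[1], x$d_range[2],
    x$rho_range[1], x$rho_range[2]))
  invisible(x)
}

#' @export
as.data.frame.scenario_spec <- function(x, ...) {
  data.frame(label = x$label, p = x$p, n = x$n, true_k = x$true_k,
             d_lo = x$d_range[1], d_hi = x$d_range[2],
             rho_lo = x$rho_range[1], rho_hi = x$rho_range[2],
             stringsAsFactors = FALSE)
}

#' Draw the scenario parameters for one replicate
#'
#' Samples the realized effect size and pairwise correlation from the
#' scenario's uniform ranges, mirroring the uncertainty a researcher has in an
#' a priori design analysis. Draws use the current R random-number state.
#'
#' A drawn correlation at or below the compound-symmetry admissibility bound
#' `-1/(p - 1)` would make the correlation matrix indefinite; such draws are
#' truncated to just above the bound with a warning. This only matters for
#' p = 12 with the (-0.10, 0.10) range.
#'
#' @param spec A [scenario_spec()].
#' @return A list with `d` (0 exactly when `true_k = 1`) and `rho`.
#' @export
sample_scenario_params <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  d <- if (spec$true_k == 1L) 0 else
    stats::runif(1, spec$d_range[1], spec$d_range[2])
  rho <- stats::runif(1, spec$rho_range[1], spec$rho_range[2])
  lower <- -1 / (spec$p - 1)
  if (rho <= lower) {
    rho_trunc <- lower + 1e-6
    warning(sprintf(
      "drawn rho = %.4f is at or below the admissible bound -1/(p-1) = %.4f; truncated to %.6f",
      rho, lower, rho_trunc))
    rho <- rho_trunc
  }
  list(d = d, rho = rho)
}

#' Compound-symmetric correlation matrix
#'
#' Unit diagonal and a common correlation `rho` everywhere off the diagonal.
#' Positive definite iff `rho > -1/(p - 1)` (eigenvalues `1 + (p-1) rho` once
#' and `1 - rho` with multiplicity `p - 1`).
#'
#' @param p Dimension (>= 2).
#' @param rho Common pairwise correlation.
#' @return A `p x p` numeric matrix.
#' @examples
#' build_covariance(3, 0.5)
#' @export
build_covariance <- function(p, rho) {
  p <- as.integer(p)
  stopifnot(p >= 2, length(rho) == 1)
  lower <- -1 / (p - 1)
  if (rho <= lower)
    stop(sprintf(
      "rho = %.4f gives an indefinite compound-symmetry matrix; rho must exceed -1/(p-1) = %.4f",
      rho, lower))
  if (rho >= 1) stop("rho must be < 1")
  s <- matrix(rho, p, p)
  diag(s) <- 1
  s
}

#' Generate one synthetic cohort
#'
#' Draws `n` units from `N_p(mu_g, Sigma(rho))` where group membership is an
#' independent fair Bernoulli draw when `true_k = 2` (so the two
#' sub-populations are equally numerous only on average), `mu_1 = 0`, and
#' `mu_2 = d * 1` adds the drawn effect size to every indicator. Indicators
#' have unit variance by construction, so no standardization precedes
#' clustering.
#'
#' Reproducibility contract: the same random seed and spec yield a
#' bit-identical dataset.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `clustsim_dataset`: list with `x` (n x p
#'   matrix), `true_labels` (in {1, 2}), `d_drawn`, `rho_drawn`, `spec`.
#' @examples
#' set.seed(1)
#' dat <- generate_dataset(scenario_spec(3, 100, 2, c(1, 2), c(0.1, 0.3)))
#' table(dat$true_labels)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  par <- sample_scenario_params(spec)
  sigma <- build_covariance(spec$p, par$rho)
  labels <- if (spec$true_k == 2L)
    stats::rbinom(spec$n, 1L, 0.5) + 1L else rep(1L, spec$n)
  x <- MASS::mvrnorm(spec$n, mu = rep(0, spec$p), Sigma = sigma)
  if (any(labels == 2L))
    x[labels == 2L, ] <- x[labels == 2L, , drop = FALSE] + par$d
  colnames(x) <- paste0("v", seq_len(spec$p))
  structure(list(x = x, true_labels = labels,
                 d_drawn = par$d, rho_drawn = par$rho, spec = spec),
            class = "clustsim_dataset")
}

#' @export
print.clustsim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic cohort: N = %d, p = %d, true k = %d, d = %.3f, rho = %.3f\n",
              nrow(x$x), ncol(x$x), x$spec$true_k, x$d_drawn, x$rho_drawn))
  invisible(x)
}

#' Export a dataset as plain CSV
#'
#' Columns `v1..vp` plus `true_label`.
#'
#' @param dataset A `clustsim_dataset`.
#' @param path Output file path.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "clustsim_dataset"))
  df <- as.data.frame(dataset$x)
  df$true_label <- dataset$true_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a scenario spec as JSON
#'
#' @param spec A [scenario_spec()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  j <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}
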