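#' Convert a correlation to a standardized mean difference
#'
#' `d = 2 r / sqrt(1 - r^2)`, the standard conversion for two equal groups;
#' [d_to_r()] is its inverse, `r = d / sqrt(d^2 + 4)`.
#'
#' @param r Correlation, |r| < 1.
#' @return Cohen's d.
#' @examples
#' r_to_d(0.36)  # ~0.77
#' @export
r_to_d <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  2 * r / sqrt(1 - r^2)
}

#' @rdname r_to_d
#' @param d Standardized mean difference.
#' @export
d_to_r <- function(d) d / sqrt(d^2 + 4)

#' Power of the two-sided two-sample t-test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' `d * sqrt(n/2)` and `2n - 2` degrees of freedom (as computed by
#' [stats::power.t.test()]).
#'
#' @param d Standardized mean difference between the two groups.
#' @param n_per_group Sample size per group (>= 2).
#' @param alpha Two-sided significance level.
#' @return The power.
#' @examples
#' ttest_power(0.40, 100)  # ~0.80
#' @export
ttest_power <- function(d, n_per_group, alpha = 0.05) {
  stopifnot(n_per_group >= 2, alpha > 0, alpha < 1)
  if (d == 0) return(alpha)
  stats::power.t.test(n = n_per_group, delta = abs(d), sd = 1,
                      sig.level = alpha, type = "two.sample",
                      alternative = "two.sided")$power
}

#' Power of the two-sided test of a single correlation
#'
#' Fisher-z approximation: the test statistic `atanh(r_hat) * sqrt(n - 3)`
#' is compared with the standard normal; under the alternative it is
#' approximately normal with mean `atanh(r) * sqrt(n - 3)`.
#'
#' @param r True correlation, |r| < 1.
#' @param n Total sample size (>= 4).
#' @param alpha Two-sided significance level.
#' @return The power.
#' @examples
#' corr_power(0.20, 193)  # ~0.80
#' @export
corr_power <- function(r, n, alpha = 0.05) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, abs(r) < 1)
  if (r == 0) return(alpha)
  ncp <- atanh(r) * sqrt(n - 3)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - zc) + stats::pnorm(-ncp - zc)
}

#' Artifactual effect size of a median split
#'
#' Standardized mean difference (below-median group minus above-median
#' group, over the pooled within-group SD) obtained by splitting a single
#' continuous variable at its median — a textbook overestimation artifact,
#' since the "groups" are halves of one distribution. Closed forms:
#' `-sqrt(12)` (about -3.5) for a uniform variable and
#' `-2 sqrt(2/pi) / sqrt(1 - 2/pi)` (about -2.6) for a normal one. The
#' simulation mode splits `n_sim` draws at the sample median and confirms
#' the closed form within Monte-Carlo error.
#'
#' @param distribution `"uniform"` or `"normal"`.
#' @param method `"closed_form"` (default) or `"simulation"`.
#' @param n_sim Number of draws in simulation mode.
#' @return The signed standardized mean difference.
#' @examples
#' median_split_d("uniform")  # -3.46
#' median_split_d("normal")   # -2.65
#' @export
median_split_d <- function(distribution = c("uniform", "normal"),
                           method = c("closed_form", "simulation"),
                           n_sim = 1e6) {
  distribution <- match.arg(distribution)
  method <- match.arg(method)
  if (method == "closed_form") {
    return(switch(distribution,
      uniform = -sqrt(12),
      normal = -2 * sqrt(2 / pi) / sqrt(1 - 2 / pi)))
  }
  x <- switch(distribution,
    uniform = stats::runif(n_sim),
    normal = stats::rnorm(n_sim))
  lo <- x[x <= stats::median(x)]
  hi <- x[x > stats::median(x)]
  n1 <- length(lo); n2 <- length(hi)
  pooled_sd <- sqrt(((n1 - 1) * stats::var(lo) + (n2 - 1) * stats::var(hi)) /
                      (n1 + n2 - 2))
  (mean(lo) - mean(hi)) / pooled_sd
}
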