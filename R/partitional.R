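#' Euclidean dissimilarity matrix
#'
#' Distances are computed on the raw generated indicators, which have unit
#' variance by construction, so no rescaling is applied.
#'
#' @param x Numeric data matrix.
#' @return A `dist` object (lower triangle of the n x n Euclidean matrix).
#' @export
dissimilarity <- function(x) stats::dist(as.matrix(x))

#' Partitioning around medoids
#'
#' Classic BUILD + SWAP via [cluster::pam()]; the SWAP phase never increases
#' the total dissimilarity of units to their medoids and stops at a local
#' optimum. The trivial case `k = n` (every unit its own medoid, zero cost)
#' is handled directly.
#'
#' @param dist A `dist` object or square distance matrix.
#' @param k Number of clusters (1 <= k <= n).
#' @return List with `labels`, `medoids` (observation indices), and the
#'   total `cost` (sum of dissimilarities to assigned medoids).
#' @export
pam_cluster <- function(dist, k) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  k <- as.integer(k)
  if (k > n) stop("k cannot exceed the number of observations")
  if (k == n)
    return(list(labels = seq_len(n), medoids = seq_len(n), cost = 0))
  fit <- cluster::pam(d, k, diss = TRUE)
  dm <- as.matrix(d)
  cost <- sum(dm[cbind(seq_len(n), fit$id.med[fit$clustering])])
  list(labels = unname(fit$clustering), medoids = unname(fit$id.med),
       cost = cost)
}

#' Complete-linkage hierarchical agglomerative clustering
#'
#' @param dist A `dist` object or square distance matrix.
#' @return An `hclust` tree; merge heights are the maximum pairwise distance
#'   between the merged clusters and are non-decreasing.
#' @export
hac_complete <- function(dist) {
  stats::hclust(stats::as.dist(dist), method = "complete")
}

#' Cut a hierarchical tree into k groups
#'
#' @param tree An `hclust` object.
#' @param k Number of clusters.
#' @return Integer labels with exactly `k` distinct values.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k > n) stop("k cannot exceed the number of observations")
  unname(stats::cutree(tree, k))
}

#' Export a dendrogram as a nested merge list (JSON)
#'
#' @param tree An `hclust` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  build <- function(i) {
    if (i < 0) return(list(leaf = -i))
    list(height = tree$height[i],
         left = build(tree$merge[i, 1]),
         right = build(tree$merge[i, 2]))
  }
  j <- jsonlite::toJSON(build(nrow(tree$merge)), auto_unbox = TRUE,
                        digits = NA)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}

#' Average silhouette width of a partition
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean within-cluster
#' distance and `b` the smallest mean distance to another cluster; units in
#' singleton clusters score 0 (the standard convention). Returns the mean
#' over units, in [-1, 1].
#'
#' @param dist A `dist` object or square distance matrix.
#' @param labels Cluster labels with at least 2 distinct values.
#' @return The average silhouette width.
#' @export
avg_silhouette <- function(dist, labels) {
  d <- stats::as.dist(dist)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    stop("average silhouette needs at least 2 clusters")
  sil <- cluster::silhouette(labels, dist = d)
  mean(sil[, "sil_width"])
}

#' Duda-Hart test of one cluster versus two
#'
#' Compares the pooled within-cluster sum of squares of a 2-cluster partition,
#' `Je(2)`, with the total sum of squares about the grand mean, `Je(1)`.
#' Homogeneity (a single cluster) is rejected when `Je(2)/Je(1)` falls below
#' the normal-approximation critical value
#' `1 - 2/(pi p) - z_{1-alpha} * sqrt(2 (1 - 8/(pi^2 p)) / (N p))`,
#' with a one-sided standard-normal quantile.
#'
#' @param x Numeric data matrix.
#' @param labels2 A partition of the rows into exactly 2 non-empty groups.
#' @param alpha Significance level.
#' @return An object of class `duda_hart`: `je1`, `je2`, `ratio`,
#'   `critical_value`, `alpha`, `reject_homogeneity`.
#' @export
duda_hart <- function(x, labels2, alpha = 0.05) {
  x <- as.matrix(x)
  labels2 <- as.integer(factor(labels2))
  if (length(labels2) != nrow(x))
    stop("labels2 must have one value per row of x")
  if (length(unique(labels2)) != 2)
    stop("labels2 must define exactly 2 non-empty groups")
  n <- nrow(x); p <- ncol(x)
  within_ss <- function(m) sum(sweep(m, 2, colMeans(m))^2)
  je1 <- within_ss(x)
  je2 <- sum(vapply(split(seq_len(n), labels2),
                    function(i) within_ss(x[i, , drop = FALSE]), 0))
  ratio <- je2 / je1
  crit <- 1 - 2 / (pi * p) -
    stats::qnorm(1 - alpha) * sqrt(2 * (1 - 8 / (pi^2 * p)) / (n * p))
  structure(list(je1 = je1, je2 = je2, ratio = ratio,
                 critical_value = crit, alpha = alpha,
                 reject_homogeneity = ratio < crit),
            class = "duda_hart")
}

#' @export
print.duda_hart <- function(x, ...) {
  cat(sprintf(
    "Duda-Hart test: Je(2)/Je(1) = %.4f vs critical %.4f (alpha = %.2f) -> %s homogeneity\n",
    x$ratio, x$critical_value, x$alpha,
    if (x$reject_homogeneity) "reject" else "retain"))
  invisible(x)
}

#' Partitional clustering with silhouette selection and the Duda-Hart gate
#'
#' The average silhouette is undefined at k = 1, so the one-cluster
#' possibility is tested first with the Duda-Hart test applied to the
#' method's own 2-cluster partition. If homogeneity is not rejected the
#' result is k = 1; otherwise k is the argmax of the average silhouette
#' width over `k_range`, with ties broken toward smaller k.
#'
#' @param x Numeric data matrix.
#' @param method `"pam"` or `"hac"` (complete linkage).
#' @param k_range Candidate numbers of clusters (default 2:5).
#' @param alpha Level of the Duda-Hart test.
#' @return A `cluster_result` with the silhouette table in
#'   `criterion_by_k` and the Duda-Hart record in `duda_hart`.
#' @export
select_k_partitional <- function(x, method = c("pam", "hac"), k_range = 2:5,
                                 alpha = 0.05) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= max(k_range)) stop("need more observations than max(k_range)")
  d <- dissimilarity(x)
  tree <- if (method == "hac") hac_complete(d) else NULL
  labels_at <- function(k) {
    if (method == "hac") cut_tree(tree, k) else pam_cluster(d, k)$labels
  }
  lab2 <- labels_at(2)
  dh <- duda_hart(x, lab2, alpha = alpha)
  if (!dh$reject_homogeneity) {
    tab <- data.frame(k = 1L, avg_silhouette = NA_real_)
    return(new_cluster_result(method = method, k_selected = 1L,
                              labels = rep(1L, n), criterion_by_k = tab,
                              duda_hart = dh))
  }
  labs <- lapply(k_range, function(k) if (k == 2) lab2 else labels_at(k))
  sil <- vapply(labs, function(l) avg_silhouette(d, l), 0)
  tab <- data.frame(k = as.integer(k_range), avg_silhouette = sil)
  best <- which.max(sil)  # first maximum: ties go to smaller k
  new_cluster_result(method = method, k_selected = k_range[best],
                     labels = as.integer(factor(labs[[best]])),
                     criterion_by_k = tab, duda_hart = dh)
}
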