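#' Construct a clustering result
#'
#' Common container returned by the three selection procedures: the chosen
#' number of clusters, the hard assignment, and the per-candidate criterion
#' table (BIC per (g, family) for the mixture method; average silhouette per
#' k for the partitional methods, together with the Duda-Hart record).
#'
#' @param method One of `"mgc"`, `"pam"`, `"hac"`.
#' @param k_selected Chosen number of clusters.
#' @param labels Integer hard assignment, one value per observation.
#' @param criterion_by_k Data frame of criterion values per candidate.
#' @param duda_hart Optional `duda_hart` test record (partitional methods).
#' @param fit Optional winning `mixture_fit` (mixture method).
#' @return An object of class `cluster_result`.
#' @export
new_cluster_result <- function(method, k_selected, labels, criterion_by_k,
                               duda_hart = NULL, fit = NULL) {
  method <- match.arg(method, c("mgc", "pam", "hac"))
  k_selected <- as.integer(k_selected)
  labels <- as.integer(labels)
  stopifnot(k_selected >= 1, length(unique(labels)) == k_selected)
  structure(list(method = method, k_selected = k_selected, labels = labels,
                 criterion_by_k = criterion_by_k, duda_hart = duda_hart,
                 fit = fit),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Clustering result (%s): k = %d selected over %d observations\n",
              x$method, x$k_selected, length(x$labels)))
  if (!is.null(x$duda_hart))
    cat(sprintf("  Duda-Hart: ratio = %.4f, critical = %.4f, %s homogeneity\n",
                x$duda_hart$ratio, x$duda_hart$critical_value,
                if (x$duda_hart$reject_homogeneity) "rejects" else "retains"))
  invisible(x)
}

#' Serialize a clustering result as JSON
#'
#' @param result A `cluster_result`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
result_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  obj <- list(method = result$method, k_selected = result$k_selected,
              labels = result$labels,
              criterion_by_k = result$criterion_by_k)
  if (!is.null(result$duda_hart))
    obj$duda_hart <- unclass(result$duda_hart)
  j <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}
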