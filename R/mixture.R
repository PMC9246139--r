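#' Covariance parameterizations for the Gaussian mixture
#'
#' The six families span spherical / diagonal / full covariance crossed with
#' equal / varying across components, in increasing flexibility order:
#' EII (spherical, shared), VII (spherical, per-component), EEI (diagonal,
#' shared), VVI (diagonal, per-component), EEE (full, shared), VVV (full,
#' per-component). Enumeration order doubles as the tie-break order in model
#' selection (simpler first).
#'
#' @return Character vector of family identifiers.
#' @export
mgc_models <- function() c("EII", "VII", "EEI", "VVI", "EEE", "VVV")

#' Free-parameter count of a constrained Gaussian mixture
#'
#' `(g - 1)` mixing proportions plus `g * p` means plus the family's
#' covariance parameters: 1 (EII), g (VII), p (EEI), g*p (VVI),
#' p(p+1)/2 (EEE), g*p(p+1)/2 (VVV).
#'
#' @param model Covariance family, one of [mgc_models()].
#' @param g Number of components (>= 1).
#' @param p Dimension (>= 1).
#' @return Integer parameter count, as used in the BIC penalty.
#' @examples
#' n_free_params("EII", g = 2, p = 3)  # 8
#' @export
n_free_params <- function(model, g, p) {
  stopifnot(g >= 1, p >= 1)
  cov_np <- switch(model,
    EII = 1,
    VII = g,
    EEI = p,
    VVI = g * p,
    EEE = p * (p + 1) / 2,
    VVV = g * p * (p + 1) / 2,
    stop("unknown covariance family: ", model))
  as.integer((g - 1) + g * p + cov_np)
}

#' Bayesian Information Criterion, mixture-modelling convention
#'
#' `2 * loglik - m * log(n)`; larger is better and model selection maximizes
#' it (equivalent to minimizing the textbook `-2 loglik + m log n`).
#'
#' @param loglik Maximized log-likelihood.
#' @param m Free-parameter count.
#' @param n Sample size.
#' @return The criterion value.
#' @export
bic_score <- function(loglik, m, n) {
  stopifnot(n >= 1)
  2 * loglik - m * log(n)
}

# Log densities of all components: n x g matrix. covs is a list of g
# p x p matrices (shared families repeat the same matrix).
.component_logdens <- function(x, means, covs) {
  n <- nrow(x); p <- ncol(x); g <- nrow(means)
  out <- matrix(NA_real_, n, g)
  for (k in seq_len(g)) {
    ch <- tryCatch(chol(covs[[k]]), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    xc <- sweep(x, 2, means[k, ])
    q <- rowSums((xc %*% backsolve(ch, diag(p)))^2)
    out[, k] <- -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
  }
  out
}

# M step under the family constraint. Returns weights/means/covs plus a
# `floored` flag when the regularization floor on eigenvalues (or variances)
# was hit, and `failed` when a component emptied out.
.mstep_mgc <- function(x, z, model, floor_eps = 1e-6) {
  n <- nrow(x); p <- ncol(x); g <- ncol(z)
  nk <- colSums(z)
  if (any(nk < 1e-8)) return(list(failed = TRUE))
  w <- nk / n
  means <- crossprod(z, x) / nk
  scatter <- vector("list", g)
  for (k in seq_len(g)) {
    xc <- sweep(x, 2, means[k, ])
    sk <- crossprod(xc * z[, k], xc)
    scatter[[k]] <- (sk + t(sk)) / 2
  }
  floored <- FALSE
  floor_diag <- function(v) {
    if (any(v < floor_eps)) floored <<- TRUE
    pmax(v, floor_eps)
  }
  floor_full <- function(s) {
    e <- eigen(s, symmetric = TRUE)
    if (any(e$values < floor_eps)) {
      floored <<- TRUE
      s <- e$vectors %*% (pmax(e$values, floor_eps) * t(e$vectors))
      s <- (s + t(s)) / 2
    }
    s
  }
  covs <- switch(model,
    EII = {
      s2 <- floor_diag(sum(vapply(scatter, function(s) sum(diag(s)), 0)) / (n * p))
      rep(list(diag(s2, p)), g)
    },
    VII = lapply(seq_len(g), function(k)
      diag(floor_diag(sum(diag(scatter[[k]])) / (nk[k] * p)), p)),
    EEI = {
      v <- floor_diag(Reduce(`+`, lapply(scatter, diag)) / n)
      rep(list(diag(v, p)), g)
    },
    VVI = lapply(seq_len(g), function(k)
      diag(floor_diag(diag(scatter[[k]]) / nk[k]), p)),
    EEE = {
      s <- floor_full(Reduce(`+`, scatter) / n)
      rep(list(s), g)
    },
    VVV = lapply(seq_len(g), function(k) floor_full(scatter[[k]] / nk[k])),
    stop("unknown covariance family: ", model))
  list(failed = FALSE, floored = floored, weights = w, means = means,
       covs = covs)
}

# E step: responsibilities and observed-data log-likelihood via log-sum-exp.
.estep_mgc <- function(x, params) {
  ld <- .component_logdens(x, params$means, params$covs)
  if (is.null(ld)) return(NULL)
  lw <- sweep(ld, 2, log(params$weights), `+`)
  mx <- apply(lw, 1, max)
  lse <- mx + log(rowSums(exp(lw - mx)))
  list(z = exp(lw - lse), loglik = sum(lse))
}

#' Fit a constrained Gaussian mixture by EM
#'
#' Alternates responsibilities (E step) and family-constrained covariance
#' updates (M step) from a hard initial partition until the relative
#' log-likelihood change falls below `tol` or `max_iter` is reached. The
#' log-likelihood is non-decreasing across iterations (EM ascent). Component
#' covariances are floored at `1e-6` on eigenvalues; a fit that hits the
#' floor is flagged `degenerate` and excluded from model selection, and a fit
#' whose components empty out is flagged `failed` rather than raising.
#'
#' @param x Numeric data matrix (n x p).
#' @param g Number of components.
#' @param model Covariance family, one of [mgc_models()].
#' @param init Hard initial partition (length-n integer vector with `g`
#'   non-empty groups); ignored for `g = 1`, which is the closed-form single
#'   Gaussian. Defaults to the complete-linkage hierarchical cut at `g`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `mixture_fit` with weights, means, covariance
#'   list, `loglik`, free-parameter count `m`, `bic`, `responsibilities`,
#'   `loglik_trace`, and flags `converged` / `degenerate` / `failed`.
#' @export
em_fit <- function(x, g, model = "VVV", init = NULL, tol = 1e-5,
                   max_iter = 500) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  g <- as.integer(g)
  model <- match.arg(model, mgc_models())
  if (n <= g) stop("need more observations than components")
  if (g == 1L) {
    z <- matrix(1, n, 1)
  } else {
    if (is.null(init))
      init <- stats::cutree(stats::hclust(stats::dist(x), "complete"), g)
    init <- as.integer(factor(init))
    if (length(init) != n || length(unique(init)) != g)
      stop("init must be a hard partition of the rows into g non-empty groups")
    z <- matrix(0, n, g)
    z[cbind(seq_len(n), init)] <- 1
  }
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE; degenerate <- FALSE; failed <- FALSE
  params <- NULL; resp <- z; ll <- NA_real_
  for (iter in seq_len(max_iter)) {
    ms <- .mstep_mgc(x, z, model)
    if (ms$failed) { failed <- TRUE; break }
    es <- .estep_mgc(x, ms)
    if (is.null(es) || !is.finite(es$loglik)) { failed <- TRUE; break }
    params <- ms
    resp <- es$z
    ll <- es$loglik
    trace <- c(trace, ll)
    if (ms$floored) { degenerate <- TRUE; break }
    if (g == 1L) { converged <- TRUE; break }
    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) < tol * (abs(prev_ll) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
  }
  if (failed || is.null(params)) {
    return(structure(list(g = g, model = model, failed = TRUE,
                          converged = FALSE, degenerate = degenerate,
                          loglik = NA_real_, m = n_free_params(model, g, p),
                          bic = NA_real_, loglik_trace = trace),
                     class = "mixture_fit"))
  }
  m <- n_free_params(model, g, p)
  structure(list(g = g, model = model,
                 weights = as.numeric(params$weights),
                 means = params$means, covariances = params$covs,
                 loglik = ll, m = m, bic = bic_score(ll, m, n),
                 converged = converged, degenerate = degenerate,
                 failed = FALSE, responsibilities = resp,
                 loglik_trace = trace),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: g = %d, model = %s, loglik = %.3f, BIC = %.3f%s\n",
              x$g, x$model, x$loglik, x$bic,
              if (isTRUE(x$failed)) " [failed]"
              else if (isTRUE(x$degenerate)) " [degenerate]"
              else if (!isTRUE(x$converged)) " [not converged]" else ""))
  invisible(x)
}

# Deterministic farthest-point seeds + Lloyd iterations; used as the second
# EM initialization besides the hierarchical cut.
.kmeans_init <- function(x, g) {
  n <- nrow(x)
  ctr <- colMeans(x)
  idx <- which.max(rowSums(sweep(x, 2, ctr)^2))
  mind <- rowSums(sweep(x, 2, x[idx, ])^2)
  while (length(idx) < g) {
    nxt <- which.max(mind)
    idx <- c(idx, nxt)
    mind <- pmin(mind, rowSums(sweep(x, 2, x[nxt, ])^2))
  }
  km <- suppressWarnings(
    stats::kmeans(x, centers = x[idx, , drop = FALSE], iter.max = 50))
  km$cluster
}

#' Gaussian mixture clustering with BIC selection of the number of clusters
#'
#' Fits every combination of component count `g = 1..g_max` and covariance
#' family, each from two deterministic initializations (the complete-linkage
#' hierarchical cut at `g`, and a farthest-point k-means partition), keeping
#' the better log-likelihood, and returns the combination with maximal BIC
#' among converged, non-degenerate fits. Ties in BIC break toward smaller `g`
#' and then toward the simpler family. Hard labels are the
#' maximum-responsibility assignment.
#'
#' @param x Numeric data matrix (n x p).
#' @param g_max Largest number of components tried (default 5).
#' @param models Covariance families to sweep (default all six).
#' @param tol,max_iter Passed to [em_fit()].
#' @return A `cluster_result` with method `"mgc"`, the selected `k`, hard
#'   labels, the per-(g, model) BIC table (`criterion_by_k`), and the winning
#'   `mixture_fit` as `$fit`.
#' @export
select_mgc <- function(x, g_max = 5, models = mgc_models(), tol = 1e-5,
                       max_iter = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= g_max) stop("need more observations than g_max")
  tree <- stats::hclust(stats::dist(x), "complete")
  fits <- list()
  tab <- list()
  for (g in seq_len(g_max)) {
    inits <- list(NULL)
    if (g > 1) {
      inits <- list(stats::cutree(tree, g))
      km <- tryCatch(.kmeans_init(x, g), error = function(e) NULL)
      if (!is.null(km) && length(unique(km)) == g)
        inits <- c(inits, list(km))
    }
    for (model in models) {
      best <- NULL
      for (init in inits) {
        f <- em_fit(x, g, model, init = init, tol = tol, max_iter = max_iter)
        if (!f$failed && (is.null(best) || isTRUE(f$loglik > best$loglik)))
          best <- f
      }
      if (is.null(best))
        best <- structure(list(g = g, model = model, failed = TRUE,
                               converged = FALSE, degenerate = FALSE,
                               loglik = NA_real_, bic = NA_real_),
                          class = "mixture_fit")
      key <- paste0(model, ":", g)
      fits[[key]] <- best
      tab[[key]] <- data.frame(
        g = g, model = model, loglik = best$loglik,
        m = n_free_params(model, g, ncol(x)), bic = best$bic,
        converged = isTRUE(best$converged),
        degenerate = isTRUE(best$degenerate),
        failed = isTRUE(best$failed), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  eligible <- tab$converged & !tab$degenerate & !tab$failed
  if (!any(eligible)) stop("all mixture fits failed or were degenerate")
  cand <- tab[eligible, ]
  # rows are already in (g ascending, simpler family first) order, and
  # which.max returns the first maximum, so ties break as documented
  pick <- cand[which.max(cand$bic), ]
  best <- fits[[paste0(pick$model, ":", pick$g)]]
  labels <- if (best$g == 1L) rep(1L, n) else max.col(best$responsibilities)
  labels <- as.integer(factor(labels, levels = unique(labels)))
  new_cluster_result(method = "mgc", k_selected = best$g, labels = labels,
                     criterion_by_k = tab, fit = best)
}
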