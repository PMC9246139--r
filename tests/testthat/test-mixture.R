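test_that("free-parameter counts match a direct count of constrained parameters", {
  expect_identical(n_free_params("EII", 2, 3), 8L)   # 1 + 6 + 1
  expect_identical(n_free_params("VVV", 1, 2), 5L)   # 0 + 2 + 3
  expect_identical(n_free_params("EII", 1, 3), 4L)   # 0 + 3 + 1
  expect_error(n_free_params("XYZ", 2, 3), "unknown")

  # cross-check every family against mclust's independent count
  skip_if_not_installed("mclust")
  for (model in mgc_models())
    for (g in 1:5)
      for (p in c(2, 3, 6, 12))
        expect_identical(n_free_params(model, g, p),
                         as.integer(mclust::nMclustParams(model, d = p, G = g)),
                         info = paste(model, g, p))
})

test_that("BIC follows the 2*loglik - m*log(n) convention", {
  expect_equal(bic_score(-100, 5, 100), -200 - 5 * log(100))
  expect_equal(bic_score(-100, 5, 100), -223.0259, tolerance = 1e-6)
  expect_equal(bic_score(-50, 0, 10), -100)
  # equal log-likelihoods: the smaller parameter count wins
  expect_gt(bic_score(-100, 3, 50), bic_score(-100, 8, 50))
})

test_that("single-component full-covariance fit equals the closed-form Gaussian", {
  set.seed(21)
  x <- matrix(rnorm(80 * 3), 80, 3)
  fit <- em_fit(x, 1, "VVV")
  expect_true(fit$converged)
  expect_equal(unname(fit$means[1, ]), unname(colMeans(x)))
  expect_equal(fit$covariances[[1]], crossprod(sweep(x, 2, colMeans(x))) / 80,
               ignore_attr = TRUE)
  ll <- single_gaussian_loglik(x)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(fit$bic, 2 * ll - n_free_params("VVV", 1, 3) * log(80),
               tolerance = 1e-6)

  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  mfit <- mclust::Mclust(x, G = 1, modelNames = "VVV", verbose = FALSE)
  expect_equal(fit$loglik, mfit$loglik, tolerance = 1e-6)
  expect_equal(fit$bic, as.numeric(mfit$bic), tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone non-decreasing for every family", {
  set.seed(22)
  blobs <- make_two_blobs(n_per = 40, p = 3, sep = 3, sd = 1)
  for (model in mgc_models()) {
    fit <- em_fit(blobs$x, 2, model)
    expect_false(fit$failed)
    tr <- fit$loglik_trace
    expect_gte(min(diff(tr)), -1e-8 * max(1, abs(tr[1])))
  }
})

test_that("EM recovers well-separated tight blobs", {
  set.seed(23)
  blobs <- make_two_blobs(n_per = 30, p = 3, sep = 8, sd = 0.5)
  fit <- em_fit(blobs$x, 2, "EII")
  hard <- max.col(fit$responsibilities)
  expect_equal(rand_index(hard, blobs$labels), 1)
  expect_gt(min(apply(fit$responsibilities, 1, max)), 0.999)
  # component means near the blob centers (either order)
  centers <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(centers[1, ] - 0)), 0.3)
  expect_lt(max(abs(centers[2, ] - 8)), 0.3)
})

test_that("BIC selection finds the separated two-group structure", {
  set.seed(24)
  blobs <- make_two_blobs(n_per = 50, p = 3, sep = 5, sd = 1)
  res <- select_mgc(blobs$x)
  expect_s3_class(res, "cluster_result")
  expect_identical(res$k_selected, 2L)
  expect_equal(rand_index(res$labels, blobs$labels), 1)
  expect_identical(nrow(res$criterion_by_k), 30L)  # 5 g x 6 families

  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  mfit <- mclust::Mclust(blobs$x, G = 1:5, modelNames = mgc_models(),
                         verbose = FALSE)
  expect_identical(res$k_selected, as.integer(mfit$G))
})

test_that("single homogeneous spherical cloud selects one component", {
  set.seed(25)
  x <- matrix(rnorm(300 * 3), 300, 3)
  res <- select_mgc(x)
  expect_identical(res$k_selected, 1L)
})

test_that("permuting the rows permutes the labels identically", {
  set.seed(26)
  blobs <- make_two_blobs(n_per = 25, p = 3, sep = 5, sd = 1)
  res <- select_mgc(blobs$x)
  perm <- sample(nrow(blobs$x))
  res_p <- select_mgc(blobs$x[perm, ])
  expect_identical(res_p$k_selected, res$k_selected)
  expect_equal(rand_index(res_p$labels, res$labels[perm]), 1)
})

test_that("degenerate and failed fits are flagged and excluded from selection", {
  # two exactly coincident points per would-be component force a floored fit
  x <- rbind(matrix(0, 4, 2), matrix(5, 4, 2)) + 1e-9
  fit <- em_fit(x, 2, "VVV", init = rep(1:2, each = 4))
  expect_true(fit$degenerate || fit$failed)

  set.seed(27)
  xx <- matrix(rnorm(40 * 2), 40, 2)
  res <- select_mgc(xx)
  tab <- res$criterion_by_k
  expect_false(any(tab$degenerate[match(paste0(res$fit$model, res$fit$g),
                                        paste0(tab$model, tab$g))]))
})
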