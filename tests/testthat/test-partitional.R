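test_that("PAM matches exhaustive k-medoid search on small fixtures", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  d <- dissimilarity(x)
  res <- pam_cluster(d, 2)
  expect_setequal(res$medoids, c(2, 5))              # points 1 and 11
  expect_identical(res$labels[1:3], rep(res$labels[1], 3))
  expect_identical(res$labels[4:6], rep(res$labels[4], 3))
  oracle <- pam_exhaustive(d, 2)
  expect_equal(res$cost, oracle$cost)

  # 2-D two-block fixture: BUILD + SWAP attains the global optimum at all k
  x2 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
              c(10, 10), c(11, 10), c(10, 11), c(11, 11))
  d2 <- dissimilarity(x2)
  for (k in 2:4)
    expect_equal(pam_cluster(d2, k)$cost, pam_exhaustive(d2, k)$cost,
                 info = paste("k", k))

  # on arbitrary configurations the SWAP local optimum can exceed, but
  # never beat, the exhaustive optimum
  set.seed(31)
  for (i in 1:5) {
    xx <- matrix(rnorm(8 * 2), 8, 2)
    dd <- dissimilarity(xx)
    for (k in 2:3)
      expect_gte(pam_cluster(dd, k)$cost,
                 pam_exhaustive(dd, k)$cost - 1e-12)
  }
})

test_that("PAM handles the trivial and error cases", {
  x <- matrix(rnorm(6), ncol = 1)
  d <- dissimilarity(x)
  res <- pam_cluster(d, 6)
  expect_identical(res$labels, 1:6)
  expect_identical(res$cost, 0)
  expect_error(pam_cluster(d, 7), "exceed")
})

test_that("PAM is equivariant under row permutation", {
  set.seed(32)
  x <- matrix(rnorm(20 * 2), 20, 2)
  perm <- sample(20)
  a <- pam_cluster(dissimilarity(x), 3)
  b <- pam_cluster(dissimilarity(x[perm, ]), 3)
  expect_equal(rand_index(b$labels, a$labels[perm]), 1)
})

test_that("complete-linkage tree matches the hand trace on {0, 1, 10, 11}", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  tree <- hac_complete(dissimilarity(x))
  expect_equal(sort(tree$height), c(1, 1, 11))
  labs <- cut_tree(tree, 2)
  expect_identical(labs[1], labs[2])
  expect_identical(labs[3], labs[4])
  expect_false(labs[1] == labs[3])
  expect_true(all(cut_tree(tree, 1) == 1L))
  expect_error(cut_tree(tree, 5), "exceed")
  # merge heights are non-decreasing
  expect_true(!is.unsorted(tree$height))
})

test_that("complete-linkage heights dominate single-linkage heights", {
  set.seed(33)
  x <- matrix(rnorm(30 * 2), 30, 2)
  d <- dissimilarity(x)
  hc <- hac_complete(d)
  hs <- stats::hclust(d, "single")
  expect_true(all(sort(hc$height) >= sort(hs$height) - 1e-12))
})

test_that("average silhouette matches the hand computation and its bounds", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  d <- dissimilarity(x)
  # hand enumeration: a = 1 for every unit; outer units (0, 11) have
  # b = mean(10, 11) = 10.5, inner units (1, 10) have b = mean(9, 10) = 9.5
  hand <- (2 * (9.5 / 10.5) + 2 * (8.5 / 9.5)) / 4
  expect_equal(avg_silhouette(d, c(1, 1, 2, 2)), hand, tolerance = 1e-12)
  expect_equal(avg_silhouette(d, c(1, 1, 2, 2)), 0.8997, tolerance = 1e-4)
  expect_error(avg_silhouette(d, rep(1, 4)), "at least 2")

  # near-coincident points per cluster, clusters far apart: average near 1
  xx <- matrix(c(0, 1e-6, 100, 100 + 1e-6), ncol = 1)
  expect_gt(avg_silhouette(dissimilarity(xx), c(1, 1, 2, 2)), 0.999)

  # random labels on exchangeable data: near 0, and always within [-1, 1]
  set.seed(34)
  sils <- replicate(50, {
    z <- matrix(rnorm(40 * 2), 40, 2)
    avg_silhouette(dissimilarity(z), sample(1:2, 40, replace = TRUE))
  })
  expect_true(all(sils >= -1 & sils <= 1))
  expect_lt(abs(mean(sils)), 0.05)
})

test_that("Duda-Hart statistic and critical value match the published form", {
  # zero within-cluster scatter: ratio 0, homogeneity rejected
  x <- rbind(matrix(0, 5, 2), matrix(3, 5, 2))
  dh <- duda_hart(x, rep(1:2, each = 5))
  expect_equal(dh$je2, 0)
  expect_equal(dh$ratio, 0)
  expect_true(dh$reject_homogeneity)

  # critical value, N = 100, p = 3, alpha = .05 (verified independently)
  set.seed(35)
  x2 <- matrix(rnorm(300), 100, 3)
  dh2 <- duda_hart(x2, rep(1:2, each = 50))
  expect_equal(dh2$critical_value, 0.6731, tolerance = 1e-4)
  expect_equal(dh2$critical_value,
               1 - 2 / (3 * pi) - qnorm(0.95) * sqrt(2 * (1 - 8 / (pi^2 * 3)) / 300),
               tolerance = 1e-12)

  # je2 <= je1 for any 2-partition; ratio in [0, 1]
  set.seed(36)
  for (i in 1:20) {
    xx <- matrix(rnorm(30 * 3), 30, 3)
    lab <- sample(1:2, 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    dh3 <- duda_hart(xx, lab)
    expect_lte(dh3$je2, dh3$je1)
    expect_gte(dh3$ratio, 0)
  }
  expect_error(duda_hart(x2, rep(1, 100)), "exactly 2")
})

test_that("the Duda-Hart test is conservative on homogeneous Gaussian data", {
  # the published normal-approximation critical value over-penalizes, so the
  # rejection rate sits at or below the nominal level; this is what drives
  # the near-perfect one-cluster detection of PAM/HAC with orthogonal
  # indicators
  set.seed(37)
  rej <- replicate(300, {
    x <- matrix(rnorm(100 * 3), 100, 3)
    lab <- cut_tree(hac_complete(dissimilarity(x)), 2)
    duda_hart(x, lab)$reject_homogeneity
  })
  expect_lte(mean(rej), 0.05 + 0.02)
})

test_that("silhouette selection with the Duda-Hart gate picks sensible k", {
  # homogeneous blob: k = 1 in the large majority of replicates
  set.seed(38)
  k1 <- replicate(20, {
    x <- matrix(rnorm(120 * 3), 120, 3)
    select_k_partitional(x, "hac")$k_selected
  })
  expect_gte(mean(k1 == 1L), 0.8)

  # two far blobs: k = 2 with perfect recovery for both methods
  set.seed(39)
  blobs <- make_two_blobs(n_per = 40, p = 3, sep = 6, sd = 1)
  for (m in c("pam", "hac")) {
    res <- select_k_partitional(blobs$x, m)
    expect_identical(res$k_selected, 2L)
    expect_equal(rand_index(res$labels, blobs$labels), 1)
    expect_true(res$duda_hart$reject_homogeneity)
  }

  # exact symmetric 3-blob structure: silhouette is maximized at k = 3
  set.seed(40)
  x3 <- rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
              matrix(rnorm(60, 10, 0.5), ncol = 2),
              cbind(rnorm(30, 5, 0.5), rnorm(30, 12, 0.5)))
  res3 <- select_k_partitional(x3, "pam")
  expect_identical(res3$k_selected, 3L)
  tab <- res3$criterion_by_k
  expect_identical(tab$k[which.max(tab$avg_silhouette)], 3L)
  expect_equal(rand_index(res3$labels, rep(1:3, each = 30)), 1)
})
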