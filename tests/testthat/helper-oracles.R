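# Independent brute-force oracles used across the suite.

# Rand index by explicit enumeration of all unit pairs.
rand_bruteforce <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1L
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1L
  }
  agree / total
}

# Exhaustive k-medoid search: best total dissimilarity over all medoid sets.
pam_exhaustive <- function(d, k) {
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  best <- NULL
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(dm[, med, drop = FALSE], 1, min))
    if (is.null(best) || cost < best$cost) best <- list(medoids = med, cost = cost)
  }
  best
}

# Log-likelihood of a single multivariate Gaussian at its ML estimates,
# computed from the explicit density formula.
single_gaussian_loglik <- function(x) {
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  s <- crossprod(sweep(x, 2, mu)) / n
  xc <- sweep(x, 2, mu)
  quad <- rowSums((xc %*% solve(s)) * xc)
  sum(-0.5 * (p * log(2 * pi) + determinant(s)$modulus[1] + quad))
}

# Small well-separated two-blob fixture.
make_two_blobs <- function(n_per = 30, p = 3, sep = 8, sd = 0.5) {
  x <- rbind(matrix(rnorm(n_per * p, 0, sd), ncol = p),
             matrix(rnorm(n_per * p, sep, sd), ncol = p))
  list(x = x, labels = rep(1:2, each = n_per))
}
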