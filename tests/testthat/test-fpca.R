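test_that("a rank-1 matrix concentrates all variance in one component", {
  u <- withr::with_seed(1, rnorm(15)); v <- withr::with_seed(2, rnorm(40))
  f <- fpca_region(outer(u, v), n_components = 3)
  expect_gt(f$var_explained[1], 1 - 1e-10)
  expect_true(all(f$eigenvalues[-1] < 1e-10))
})

test_that("scores are centred, orthogonal and deterministic in sign", {
  X <- withr::with_seed(3, matrix(rnorm(30 * 50), 30))
  f <- fpca_region(X, n_components = 4)
  expect_true(all(abs(colMeans(f$scores)) < 1e-8))
  G <- crossprod(f$scores)
  expect_true(all(abs(G[upper.tri(G)]) < 1e-8 * sqrt(diag(G)[1] * diag(G)[2])))
  expect_true(all(diff(f$eigenvalues) <= 1e-10))
  expect_lte(sum(f$var_explained), 1 + 1e-12)
  expect_identical(f$scores, fpca_region(X, n_components = 4)$scores)
  ## the dominant loading of each component is positive by convention
  for (j in seq_len(ncol(f$loadings)))
    expect_gt(f$loadings[which.max(abs(f$loadings[, j])), j], 0)
})

test_that("a planted two-component spectrum with ratio 4:1 is recovered", {
  stats <- sapply(1:20, function(r) withr::with_seed(400 + r, {
    p <- 100; n <- 200
    phi <- qr.Q(qr(matrix(rnorm(p * 2), p)))
    X <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 1)) %*% t(phi) +
      matrix(rnorm(n * p, 0, 0.03), n)
    f <- fpca_region(X, n_components = 2)
    c(ratio = f$eigenvalues[1] / f$eigenvalues[2],
      var2 = sum(f$var_explained[1:2]))
  }))
  expect_gte(median(stats["ratio", ]), 3)
  expect_lte(median(stats["ratio", ]), 5.3)
  expect_true(all(stats["var2", ] >= 0.95))
})

test_that("loadings agree with a dense eigendecomposition, with and without duplicates", {
  X <- withr::with_seed(5, matrix(rnorm(12 * 9), 12))
  for (M in list(X, rbind(X, X[3, ]))) {
    f <- fpca_region(M, n_components = 3)
    ev <- eigen(stats::cov(M), symmetric = TRUE)
    expect_equal(f$eigenvalues[1:3], ev$values[1:3], tolerance = 1e-8)
    for (j in 1:3) {
      a <- f$loadings[, j]; b <- ev$vectors[, j]
      expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)  # same direction
    }
  }
})

test_that("reconstruction error is non-increasing in the component count", {
  X <- withr::with_seed(6, matrix(rnorm(20 * 30), 20))
  Xc <- scale(X, scale = FALSE)
  errs <- sapply(1:5, function(k) {
    f <- fpca_region(X, n_components = k)
    sum((Xc - f$scores %*% t(f$loadings))^2)
  })
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("automatic component count honours the variance target and cap", {
  X <- withr::with_seed(7, matrix(rnorm(40 * 60), 40))
  f <- fpca_region(X, variance_target = 0.2)
  cum <- cumsum(f$var_explained)
  expect_gte(cum[f$n_components], 0.2)
  expect_lte(f$n_components, 5)
  expect_error(fpca_region(X, n_components = 45), "n_components")
  expect_error(fpca_region(X[1, , drop = FALSE]), "2 subjects")
})

test_that("gene FPCA: rank-1 genes, equivariance, single-SNP bypass, monomorphic error", {
  g <- withr::with_seed(8, rbinom(30, 2, 0.3))
  G <- cbind(g, g)                    # two perfectly correlated SNPs
  f <- fpca_gene(G, c(100, 500), n_components = 2)
  expect_gt(f$var_explained[1], 1 - 1e-10)

  G2 <- withr::with_seed(9, matrix(rbinom(25 * 6, 2, 0.4), 25))
  pos <- c(10, 40, 90, 160, 400, 900)
  f2 <- fpca_gene(G2, pos, n_components = 3)
  perm <- withr::with_seed(10, sample(25))
  f3 <- fpca_gene(G2[perm, ], pos, n_components = 3)
  expect_equal(f3$scores, f2$scores[perm, ], ignore_attr = TRUE)

  solo <- fpca_gene(matrix(g, ncol = 1), 42)
  expect_equal(as.numeric(solo$scores), g - mean(g))

  expect_error(fpca_gene(matrix(1, 10, 3), c(1, 2, 3)), "monomorphic")
  expect_error(fpca_gene(G2, pos[c(1, 1, 2, 3, 4, 5)]), "increasing")
})

test_that("a three-component latent genotype structure is recovered", {
  ok <- sapply(1:20, function(r) withr::with_seed(500 + r, {
    n <- 2000; p <- 20
    pos <- sort(sample(1e6, p))
    B <- splines::bs((pos - pos[1]) / (pos[p] - pos[1]), df = 5,
                     intercept = TRUE)
    L <- B[, c(1, 3, 5)]
    G <- cbind(rnorm(n, 0, 1.5), rnorm(n, 0, 1), rnorm(n, 0, 0.7)) %*% t(L) +
      matrix(rnorm(n * p, 0, 0.08), n)
    f <- fpca_gene(G, pos, n_components = 5)
    sum(f$var_explained[1:3]) >= 0.9
  }))
  expect_gte(sum(ok), 18)
})
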