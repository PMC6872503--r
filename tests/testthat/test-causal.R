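test_that("KNN two-sample accuracy matches a brute-force oracle on small instances", {
  for (r in 1:6) {
    d <- if (r %% 2) 1L else 2L
    real <- withr::with_seed(r, matrix(rnorm(10 * d), ncol = d))
    synth <- withr::with_seed(100 + r, matrix(rnorm(10 * d, 0.5), ncol = d))
    split <- 1:5
    for (K in c(1L, 3L)) {
      res <- knn_c2st(real, synth, K = K, split_train = split)
      train <- rbind(real[split, , drop = FALSE], synth[split, , drop = FALSE])
      lab <- c(rep("0", 5), rep("1", 5))
      test <- rbind(real[-split, , drop = FALSE], synth[-split, , drop = FALSE])
      truth <- c(rep("0", 5), rep("1", 5))
      expect_identical(res$t, mean(bf_knn(train, lab, test, K) == truth))
    }
  }
})

test_that("the C2ST separates disjoint samples and validates its inputs", {
  zeros <- matrix(0, 20, 2); hundreds <- matrix(100, 20, 2)
  expect_identical(knn_c2st(zeros, hundreds, K = 3)$t, 1)
  expect_error(knn_c2st(zeros, matrix(1, 20, 3)), "dimensionality")
  expect_error(knn_c2st(numeric(0), 1:5), "non-empty")
  expect_error(knn_c2st(rnorm(10), rnorm(10), K = 10), "training size")
})

test_that("under equal distributions the C2ST accuracy is centred at one half", {
  ts <- sapply(1:50, function(i) {
    uv <- withr::with_seed(3000 + i, list(u = rnorm(400), v = rnorm(400)))
    knn_c2st(uv$u, uv$v, seed = i)$t
  })
  expect_lt(abs(mean(ts) - 0.5), 0.03)
})

test_that("the CGAN fit honours its contracts", {
  pair <- generate_causal_pair(causal_pair_spec(200, "linear", "x_to_y",
                                                noise_sd = 0.5, seed = 1))
  cfg <- test_cgan(epochs = 30L)
  fit <- fit_cgan(pair$x, pair$y, cfg, seed = 2)
  expect_s3_class(fit, "direction_fit")
  expect_identical(fit$direction, "x_to_y")
  expect_identical(nrow(fit$generated), 200L)
  rev <- fit_cgan(pair$y, pair$x, cfg, direction = "y_to_x", seed = 2)
  expect_identical(rev$direction, "y_to_x")
  ## reproducible under a fixed seed
  expect_identical(fit$generated,
                   fit_cgan(pair$x, pair$y, cfg, seed = 2)$generated)
  expect_error(fit_cgan(rep(1, 50), rep(2, 50), cfg), "degenerate")
  expect_error(fit_cgan(rnorm(10), rnorm(10), cfg), "n >= 20")
  expect_error(fit_cgan(rnorm(30), rnorm(29), cfg), "equal length")
})

test_that("a converged generator matches the first moment of the effect", {
  devs <- sapply(1:5, function(i) {
    pair <- generate_causal_pair(causal_pair_spec(500, "linear", "x_to_y",
                                                  noise_sd = 0.5, seed = 600 + i))
    f <- fit_cgan(pair$x, pair$y, test_cgan(epochs = 300L), seed = i)
    abs(mean(f$generated$effect_hat) - mean(pair$y)) / sd(pair$y)
  })
  expect_lte(mean(devs), 0.1)
})

test_that("the causal test is exactly antisymmetric in its arguments", {
  pair <- generate_causal_pair(causal_pair_spec(120, "quadratic", "x_to_y",
                                                noise_sd = 0.4, seed = 5))
  cfg <- test_cgan(epochs = 40L)
  a <- causal_test(pair$x, pair$y, cfg, n_covariance_splits = 5, seed = 9)
  b <- causal_test(pair$y, pair$x, cfg, n_covariance_splits = 5, seed = 9)
  expect_identical(a$T, -b$T)
  expect_identical(a$t_xy, b$t_yx)
  expect_identical(a$sigma2, b$sigma2)
  expect_identical(a$p_value, b$p_value)
  swap <- c(x_to_y = "y_to_x", y_to_x = "x_to_y", inconclusive = "inconclusive")
  expect_identical(unname(swap[a$call]), b$call)
})

test_that("the null variance respects the published formula and its floor", {
  pair <- generate_causal_pair(causal_pair_spec(100, "linear", "none",
                                                seed = 6))
  ct <- causal_test(pair$x, pair$y, test_cgan(epochs = 40L),
                    n_covariance_splits = 5, seed = 2)
  expect_identical(ct$sigma2,
                   max(0.5 / ct$n_test - 2 * ct$cov_hat, 0.1 / ct$n_test))
  expect_gte(ct$sigma2, 0.1 / ct$n_test)
  expect_identical(ct$T, ct$t_xy - ct$t_yx)
  expect_gte(ct$p_value, 0); expect_lte(ct$p_value, 1)
})

test_that("Bonferroni thresholds reproduce the published values", {
  expect_equal(round(bonferroni_threshold(0.05, 23), 4), 0.0022)
  expect_equal(round(bonferroni_threshold(0.05, 61), 5), 0.00082)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("screening filters p-values, counts by timepoint and parses interval tokens", {
  tab <- roi_ad_screen_table()
  scr <- screen_results(tab, 0.0022)
  expect_identical(unname(scr$counts[c("baseline", "m06", "m12", "m24")]),
                   c(1L, 1L, 2L, 4L))
  ## the sub-resolution entries count as significant at 0.0022 ...
  expect_true(18 %in% scr$significant$roi_index[scr$significant$timepoint == "m12"])
  ## ... but not below their stated bound
  scr2 <- screen_results(tab, 1e-5)
  expect_identical(sum(scr2$counts), 0L)

  empty <- screen_results(tab[0, ], 0.05)
  expect_identical(nrow(empty$significant), 0L)
  expect_identical(sum(empty$counts), 0L)

  bad <- data.frame(timepoint = "baseline", p_value = "oops")
  expect_error(screen_results(bad, 0.05), "row 1")
  expect_error(screen_results(data.frame(timepoint = 1, p_value = 1.7), 0.05),
               "outside")
})

test_that("association test: minimal p for exact dependence, calibrated null, equivariance", {
  X <- withr::with_seed(7, matrix(rnorm(40 * 2), 40))
  Y <- X %*% matrix(c(1, 0.5, -0.3, 2), 2)     # exact linear transform
  res <- association_test(X, Y, n_permutations = 999, seed = 1)
  expect_identical(res$p_value, 1 / 1000)

  ps <- sapply(1:100, function(i) {
    XY <- withr::with_seed(5000 + i, list(a = matrix(rnorm(30 * 2), 30),
                                          b = matrix(rnorm(30 * 2), 30)))
    association_test(XY$a, XY$b, n_permutations = 99, seed = i)$p_value
  })
  expect_lte(mean(ps < 0.05), 0.10)

  perm <- withr::with_seed(8, sample(40))
  res2 <- association_test(X[perm, ], Y[perm, ], n_permutations = 199, seed = 3)
  res3 <- association_test(X, Y, n_permutations = 199, seed = 3)
  expect_identical(res2$p_value, res3$p_value)
  expect_error(association_test(X[1:2, ], Y[1:2, ]), "3 subjects")
  expect_error(association_test(X, Y[1:10, ]), "match")
})
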