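test_that("generators are pure functions of spec and seed", {
  spec <- image_cohort_spec(c(10, 10, 10), 3, 4,
                            signal_regions = list(rbind(c(2, 2, 2), c(6, 6, 6))),
                            effect_size = 2, smoothness_sigma = 1, seed = 42)
  expect_identical(generate_image_cohort(spec), generate_image_cohort(spec))

  gspec <- genotype_spec(20, list(g1 = c(100, 250, 900), g2 = c(5, 60)),
                         seed = 9)
  expect_identical(generate_genotypes(gspec), generate_genotypes(gspec))

  pspec <- causal_pair_spec(50, "sigmoid", "x_to_y", 0.4, seed = 3)
  expect_identical(generate_causal_pair(pspec), generate_causal_pair(pspec))
})

test_that("cohort has requested counts and planted mean shift", {
  boxes <- list(rbind(c(1, 1, 1), c(5, 5, 5)), rbind(c(8, 2, 2), c(12, 6, 6)))
  spec <- image_cohort_spec(c(14, 10, 10), 12, 10, signal_regions = boxes,
                            effect_size = 5, noise_sd = 1, seed = 11)
  co <- generate_image_cohort(spec)
  expect_length(co$volumes, 22)
  expect_equal(sum(co$labels == 1), 12)
  expect_equal(sum(co$labels == 0), 10)
  mask <- co$truth$signal_mask
  v_count <- sum(mask)
  case_mean <- mean(sapply(co$volumes[co$labels == 1], function(v) mean(v[mask])))
  ctrl_mean <- mean(sapply(co$volumes[co$labels == 0], function(v) mean(v[mask])))
  se <- sqrt(1 / (12 * v_count) + 1 / (10 * v_count))
  expect_lt(abs((case_mean - ctrl_mean) - 5), 3 * se)
})

test_that("zero effect size leaves no class difference across replicates", {
  diffs <- sapply(1:20, function(r) {
    spec <- image_cohort_spec(c(8, 8, 8), 5, 5,
                              signal_regions = list(rbind(c(2, 2, 2), c(6, 6, 6))),
                              effect_size = 0, noise_sd = 1, seed = 1000 + r)
    co <- generate_image_cohort(spec)
    mask <- co$truth$signal_mask
    mean(sapply(co$volumes[co$labels == 1], function(v) mean(v[mask]))) -
      mean(sapply(co$volumes[co$labels == 0], function(v) mean(v[mask])))
  })
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("cohort spec validation names the offending field", {
  expect_error(image_cohort_spec(c(8, 8), 1, 1), "grid_shape")
  expect_error(image_cohort_spec(c(8, 8, 8), 0, 1), "n_cases")
  expect_error(image_cohort_spec(c(8, 8, 8), 1, 1, noise_sd = 0), "noise_sd")
  expect_error(image_cohort_spec(c(8, 8, 8), 1, 1,
                                 signal_regions = list(rbind(c(2, 2, 2), c(9, 6, 6)))),
               "signal_regions")
})

test_that("genotypes follow the requested allele frequencies and shapes", {
  gs <- genotype_spec(10000, list(g = c(1, 2, 3)), maf_range = c(0.5, 0.5),
                      seed = 5)
  g <- generate_genotypes(gs)
  se3 <- 3 * sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(colMeans(g$genotypes) - 1) < se3))
  expect_true(all(g$genotypes %in% 0:2))

  tiny <- generate_genotypes(genotype_spec(5, list(solo = 77), seed = 1))
  expect_identical(dim(tiny$genotypes), c(5L, 1L))

  expect_error(genotype_spec(5, list()), "genes")
  expect_error(genotype_spec(5, list(g = c(5, 5))), "increasing")
  expect_error(genotype_spec(5, list(g = 1), maf_range = c(0, 0.6)), "maf_range")
})

test_that("independent pairs are uncorrelated and the noiseless limit is exact", {
  cors <- sapply(1:100, function(r) {
    p <- generate_causal_pair(causal_pair_spec(10000, "linear", "none",
                                               seed = 2000 + r))
    abs(cor(p$x, p$y))
  })
  expect_gte(mean(cors < 0.05), 0.95)

  p <- generate_causal_pair(causal_pair_spec(500, "quadratic", "x_to_y",
                                             noise_sd = 1e-8, seed = 4))
  expect_lt(var(p$y - p$x^2), 1e-12)

  expect_error(causal_pair_spec(500, "cubic"), "mechanism")
  expect_error(causal_pair_spec(5, "linear"), "n")
})

test_that("additive noise is independent of the cause (distance correlation)", {
  mech <- list(linear = function(u) u, quadratic = function(u) u^2,
               sigmoid = function(u) tanh(2 * u))
  hits <- sapply(1:10, function(r) {
    m <- names(mech)[(r %% 3) + 1]
    p <- generate_causal_pair(causal_pair_spec(200, m, "x_to_y", 0.5,
                                               seed = 3000 + r))
    resid <- p$y - mech[[m]](p$x)
    obs <- dcor_stat(p$x, resid)
    null <- withr::with_seed(r, sapply(1:100, function(i)
      dcor_stat(p$x, sample(resid))))
    obs < quantile(null, 0.95)
  })
  expect_gte(sum(hits), 9)
})

test_that("cohorts round-trip through NIfTI and TSV", {
  dir <- withr::local_tempdir()
  co <- strong_cohort(grid = 8L, n_cases = 2L, n_controls = 2L, seed = 3L)
  write_image_cohort(co, dir)
  back <- read_image_cohort(dir)
  expect_equal(back$labels, co$labels)
  expect_equal(back$volumes[[1]], unclass(co$volumes[[1]]), tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "truth_regions.tsv")))
})
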