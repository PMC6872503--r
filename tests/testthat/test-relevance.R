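test_that("log-odds relevance score has its closed-form values and symmetry", {
  expect_identical(relevance_score(0.5, 0.5), 0)
  expect_equal(relevance_score(0.9, 0.5), log(9), tolerance = 1e-12)
  for (r in 1:20) {
    pq <- withr::with_seed(r, runif(2, 0.01, 0.99))
    expect_equal(relevance_score(pq[1], pq[2]),
                 -relevance_score(pq[2], pq[1]), tolerance = 1e-12)
  }
  expect_true(is.finite(relevance_score(1, 0)))   # clipped, not infinite
  expect_error(relevance_score(1.2, 0.5), "p0")
  expect_error(relevance_score(0.5, -0.1), "p1")
})

test_that("occlusion replaces only the patch, exactly", {
  v <- withr::with_seed(1, array(rnorm(8^3), c(8, 8, 8)))
  train <- withr::with_seed(2, lapply(1:4, function(i)
    array(rnorm(8^3), c(8, 8, 8))))
  sampler <- patch_sampler(train, n_draws = 3)
  occ <- occlude_patch(v, c(2, 3, 4), sampler, seed = 5)
  expect_length(occ, 3)
  for (o in occ) {
    changed <- o != v
    expect_true(all(which(changed, arr.ind = TRUE)[, 1] %in% 3:5))
    outside <- o; outside[3:5, 4:6, 5:7] <- v[3:5, 4:6, 5:7]
    expect_identical(outside, v)          # bit-identical outside the patch
  }
  expect_error(occlude_patch(v, c(6, 6, 6), sampler), "location")
})

test_that("degenerate replacement with the original patch is a no-op", {
  v <- withr::with_seed(3, array(rnorm(6^3), c(6, 6, 6)))
  patch <- as.numeric(v[2:4, 2:4, 2:4])
  sampler <- patch_sampler(mean = patch, cov = matrix(0, 27, 27), n_draws = 2)
  occ <- occlude_patch(v, c(1, 1, 1), sampler, seed = 1)
  expect_equal(occ[[1]], v)
})

test_that("replacement draws match the sampler mean at Monte-Carlo precision", {
  train <- withr::with_seed(4, lapply(1:6, function(i)
    array(rnorm(6^3), c(6, 6, 6))))
  sampler <- patch_sampler(train, n_draws = 10000)
  loc <- c(1, 2, 1)
  draws <- neurocausal:::draw_replacements(sampler, loc, 10000, seed = 8)
  mo <- neurocausal:::sampler_moments(sampler, loc)
  se <- sqrt(diag(tcrossprod(mo$factor)) / 10000)
  expect_true(all(abs(colMeans(draws) - mo$mean) < 3 * pmax(se, 1e-12)))
})

test_that("a constant classifier yields an identically zero map", {
  model <- build_classifier(test_arch(), c(8, 8, 8), init = "zero")
  vols <- withr::with_seed(5, lapply(1:2, function(i)
    array(rnorm(8^3), c(8, 8, 8))))
  sampler <- patch_sampler(vols, n_draws = 2)
  map <- compute_relevance_map(model, vols, sampler, stride = 3, seed = 1)
  expect_true(all(map$W == 0))
})

test_that("the relevance map equals a per-window brute-force loop", {
  model <- build_classifier(test_arch(), c(8, 8, 8), seed = 21)
  vols <- withr::with_seed(6, lapply(1:2, function(i)
    array(rnorm(8^3), c(8, 8, 8))))
  train <- withr::with_seed(7, lapply(1:5, function(i)
    array(rnorm(8^3), c(8, 8, 8))))
  sampler <- patch_sampler(train, n_draws = 2)
  map <- compute_relevance_map(model, vols, sampler, stride = 3, seed = 9)

  ## independent per-window loop over non-overlapping patches
  W <- array(0, c(8, 8, 8))
  l0 <- decision_logit(model, vols)
  for (x0 in c(0, 3)) for (y0 in c(0, 3)) for (z0 in c(0, 3)) {
    dbar <- 0
    for (s in 1:2) {
      occ <- occlude_patch(vols[[s]], c(x0, y0, z0), sampler,
                           seed = derive_seed(9, paste0("loc", x0, "_", y0, "_", z0)))
      dbar <- dbar + (l0[s] - mean(sapply(occ, function(o)
        decision_logit(model, o))))
    }
    W[x0 + 1:3, y0 + 1:3, z0 + 1:3] <- dbar / 2
  }
  expect_equal(map$W, W, tolerance = 1e-12)
  ## away from saturation the logit difference is the probability log-odds
  p <- predict_proba(model, vols[[1]])[, "case"]
  expect_equal(decision_logit(model, vols[[1]]), unname(qlogis(p)),
               tolerance = 1e-8)
})

test_that("the map is invariant to subject ordering", {
  model <- build_classifier(test_arch(), c(8, 8, 8), seed = 22)
  vols <- withr::with_seed(8, lapply(1:3, function(i)
    array(rnorm(8^3), c(8, 8, 8))))
  sampler <- patch_sampler(vols, n_draws = 2)
  m1 <- compute_relevance_map(model, vols, sampler, stride = 3, seed = 2)
  m2 <- compute_relevance_map(model, rev(vols), sampler, stride = 3, seed = 2)
  expect_equal(m1$W, m2$W)
})

test_that("doubling the draw count does not add noise beyond seed-level noise", {
  model <- build_classifier(test_arch(), c(8, 8, 8), seed = 23)
  vols <- withr::with_seed(9, lapply(1:2, function(i)
    array(rnorm(8^3), c(8, 8, 8))))
  train <- withr::with_seed(10, lapply(1:5, function(i)
    array(rnorm(8^3), c(8, 8, 8))))
  s10 <- patch_sampler(train, n_draws = 10)
  s20 <- patch_sampler(train, n_draws = 20)
  a <- compute_relevance_map(model, vols, s10, stride = 2, seed = 1)$W
  b <- compute_relevance_map(model, vols, s10, stride = 2, seed = 99)$W
  c20 <- compute_relevance_map(model, vols, s20, stride = 2, seed = 1)$W
  ## doubling draws halves the Monte-Carlo variance, so the c20-vs-a gap
  ## should on average be sqrt(3)/2 of the equal-draw seed-to-seed gap;
  ## allow slack for the finite number of windows
  expect_lte(mean(abs(c20 - a)), 1.15 * mean(abs(b - a)))
})

test_that("top-decile thresholding and connectivity behave as specified", {
  ## one supra-threshold 4^3 cube occupying exactly the top decile
  W <- array(0, c(8, 8, 10))          # 640 voxels, 64 = 10%
  W[3:6, 3:6, 3:6] <- 1
  rs <- select_top_regions(W, percentile = 90)
  expect_equal(nrow(rs$rois), 1)
  expect_equal(rs$rois$size, 64)

  ## two cubes separated by one sub-threshold voxel along an axis
  W2 <- array(0, c(11, 5, 5))
  W2[2:4, 2:4, 2:4] <- 1
  W2[6:8, 2:4, 2:4] <- 1    # gap plane at x index 5
  for (conn in c(6L, 26L)) {
    rs2 <- select_top_regions(W2, percentile = 85, connectivity = conn)
    expect_equal(nrow(rs2$rois), 2)
    expect_equal(sum(rs2$rois$size), 54)
  }

  ## exact percentile count with no ties
  W3 <- array(withr::with_seed(11, sample(seq_len(1000))), c(10, 10, 10))
  rs3 <- select_top_regions(W3, percentile = 90)
  expect_equal(sum(rs3$rois$size), 100)

  ## constant map: warning and empty set
  expect_warning(rs4 <- select_top_regions(array(1, c(4, 4, 4))), "constant")
  expect_equal(nrow(rs4$rois), 0)
})

test_that("connected components agree with a brute-force oracle", {
  for (r in 1:5) {
    mask <- withr::with_seed(r, array(runif(8^3) < 0.35, c(8, 8, 8)))
    for (conn in c(6L, 26L)) {
      ours <- neurocausal:::.label_components(mask, dim(mask), conn)
      ref <- bf_components(mask, conn)
      expect_identical(component_signature(ours), component_signature(ref))
    }
  }
})

test_that("ROIs are disjoint, ordered by size, and matrix extraction is lexicographic", {
  W <- withr::with_seed(12, array(rnorm(12^3), c(12, 12, 12)))
  rs <- select_top_regions(W, percentile = 85)
  expect_true(all(diff(rs$rois$size) <= 0))
  all_vox <- do.call(rbind, rs$voxels)
  expect_equal(nrow(all_vox), nrow(unique(all_vox)))     # pairwise disjoint
  expect_true(all(W[all_vox + 1L] >= rs$threshold))
  vols <- withr::with_seed(13, lapply(1:3, function(i)
    array(rnorm(12^3), c(12, 12, 12))))
  m <- region_signal_matrix(vols, rs, 1)
  vx <- attr(m, "voxels")
  expect_identical(vx, vx[order(vx[, 1], vx[, 2], vx[, 3]), , drop = FALSE])
  expect_equal(m[2, 1], vols[[2]][vx[1, 1] + 1, vx[1, 2] + 1, vx[1, 3] + 1])
})

test_that("a trained classifier's relevance concentrates in the planted box", {
  co <- strong_cohort(grid = 16L, n_cases = 8L, n_controls = 8L, seed = 30L)
  model <- build_classifier(test_arch(), c(16, 16, 16), seed = 31)
  model <- train_classifier(model, co$volumes, co$labels,
                            list(lr = 3e-3, epochs = 10L, batch_size = 8L),
                            seed = 32)
  sampler <- patch_sampler(co$volumes, n_draws = 3)
  map <- compute_relevance_map(model, co$volumes[c(1, 2, 9, 10)], sampler,
                               stride = 3, seed = 33)
  mask <- co$truth$signal_mask
  expect_gt(mean(map$W[mask]), mean(map$W[!mask]))
})
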