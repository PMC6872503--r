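## Shared fixtures and independent oracles for the suite. Everything is
## generated in code; no stored binary data.

## Small two-layer architecture used for desk-scale training tests.
test_arch <- function() {
  architecture_config(conv_specs = list(c(5, 2, 2, 8), c(3, 1, 1, 16)),
                      n_maxpool = 2L)
}

## Strong planted-signal cohort at a given grid size.
strong_cohort <- function(grid = 32L, n_cases = 15L, n_controls = 15L,
                          seed = 7L, effect_size = 5) {
  lo <- as.integer(grid / 4); hi <- as.integer(grid / 2)
  generate_image_cohort(image_cohort_spec(
    rep(grid, 3), n_cases, n_controls,
    signal_regions = list(rbind(rep(lo, 3), rep(hi, 3))),
    effect_size = effect_size, noise_sd = 1, smoothness_sigma = 1,
    seed = seed))
}

train_hp <- function() list(lr = 3e-3, epochs = 15L, batch_size = 8L)

## Reduced CGAN settings used throughout the causal tests (small widths and
## a linear noise path keep a single fit in the low seconds).
test_cgan <- function(epochs = 300L) {
  cgan_config(epochs = epochs, batch_size = 100L, lr = 1e-3, noise_dim = 2L,
              gen_hidden = c(16, 16), disc_hidden = c(16, 16))
}

## Brute-force K-nearest-neighbour classifier (majority vote over exact
## distances). Independent of class::knn; assumes no distance or vote ties.
bf_knn <- function(train, labels, test, K) {
  apply(test, 1, function(pt) {
    d <- sqrt(colSums((t(train) - pt)^2))
    nb <- labels[order(d)[seq_len(K)]]
    names(which.max(table(nb)))
  })
}

## Brute-force connected components: iterative label propagation over an
## explicit neighbour list until a fixed point.
bf_components <- function(mask, connectivity) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(array(0L, d))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- seq_len(n)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  pos <- setNames(seq_len(n), key(idx))
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (o in seq_len(nrow(offs))) {
        nb <- idx[i, ] + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        j <- pos[paste(nb[1], nb[2], nb[3])]
        if (!is.na(j) && lab[j] < lab[i]) { lab[i] <- lab[j]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  out <- array(0L, d)
  out[mask] <- match(lab, sort(unique(lab)))
  out
}

## Partition of voxels into components, as a canonical set-of-sets signature
## (independent of label numbering).
component_signature <- function(lab) {
  lev <- setdiff(sort(unique(as.integer(lab))), 0L)
  sig <- lapply(lev, function(l) sort(which(lab == l)))
  sig[order(vapply(sig, `[`, integer(1), 1))]
}

## Distance correlation plus its permutation null (used for the
## additive-noise independence property).
dcor_stat <- function(x, y) {
  n <- length(x)
  A <- as.matrix(dist(x)); B <- as.matrix(dist(y))
  Ac <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
  Bc <- B - rowMeans(B)[row(B)] - colMeans(B)[col(B)] + mean(B)
  dcov2 <- mean(Ac * Bc)
  dvar <- sqrt(mean(Ac * Ac) * mean(Bc * Bc))
  if (dvar <= 0) return(0)
  sqrt(max(dcov2, 0) / dvar)
}

## Independent parameter-count oracle: layer-by-layer arithmetic over the
## architecture schedule (never consults the built model).
oracle_param_count <- function(cfg, hidden_fc = integer(0)) {
  cin <- 1L; total <- 0L
  for (cs in cfg$conv_specs) {
    k <- cs[1]; cout <- cs[4]
    total <- total + k^3 * cin * cout + cout
    cin <- cout
  }
  widths <- c(cin, hidden_fc, cfg$n_output)
  for (j in seq_len(length(widths) - 1L))
    total <- total + widths[j] * widths[j + 1L] + widths[j + 1L]
  as.integer(total)
}
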