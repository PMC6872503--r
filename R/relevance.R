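## Prediction-difference relevance analysis: slide a small patch across the
## volume, replace its contents with multivariate-normal draws estimated from
## training images, and score each window by the log-odds drop in the
## classifier's case probability. Voxel coordinates are 0-based and boxes
## half-open throughout.

#' Log-odds relevance score
#'
#' `d = log[(p0/(1-p0)) / (p1/(1-p1))]`, where `p0` is the case probability
#' on the intact image and `p1` with the window's information removed.
#' Positive scores mean the window carried evidence for the case class.
#' Probabilities are clipped to `[1e-6, 1 - 1e-6]` before the log-odds to
#' avoid infinities under softmax saturation.
#'
#' @param p0,p1 Probabilities in `[0, 1]` (vectorised).
#' @return Numeric score(s); 0 iff `p0 == p1` after clipping.
#' @export
relevance_score <- function(p0, p1) {
  if (any(!is.finite(p0)) || any(p0 < 0) || any(p0 > 1))
    stop_field("p0", "probabilities must lie in [0, 1]")
  if (any(!is.finite(p1)) || any(p1 < 0) || any(p1 > 1))
    stop_field("p1", "probabilities must lie in [0, 1]")
  clip <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  qlogis(clip(p0)) - qlogis(clip(p1))
}

#' Case-vs-control decision logit of a classifier
#'
#' The log-odds of the predicted case probability, computed directly as the
#' difference of the two output logits. Identical to
#' `qlogis(predict_proba(...)[, "case"])` in exact arithmetic, but immune to
#' softmax saturation — confident models routinely push probabilities within
#' double-precision distance of 0 or 1, where probability-space log-odds
#' degenerate. The relevance map is built on this quantity.
#'
#' @param model A `cnn_classifier` with two output classes.
#' @param volumes List of 3D arrays (or a single array).
#' @return Numeric vector of log-odds (positive favours the case class).
#' @export
decision_logit <- function(model, volumes) {
  stopifnot(model$cfg$n_output == 2L)
  if (is.array(volumes) && length(dim(volumes)) == 3) volumes <- list(volumes)
  vapply(volumes, function(v) {
    z <- forward_cnn(model, v)$logits
    z[2] - z[1]
  }, numeric(1))
}

#' Multivariate-normal patch replacement sampler
#'
#' Replacement values for an occluded patch are drawn from a multivariate
#' normal whose mean and covariance are estimated, per patch location, from
#' the marginal distribution of that patch across training volumes. A fixed
#' `mean`/`cov` pair can be supplied instead (mainly for degenerate tests).
#'
#' @param train_volumes List of 3D arrays used to estimate the per-location
#'   moments (ignored when `mean` is supplied).
#' @param patch_shape Integer vector of 3 patch dimensions (default 3x3x3).
#' @param n_draws Number of replacement samples averaged per location.
#' @param mean,cov Optional fixed mean vector / covariance matrix (covariance
#'   must be symmetric positive semi-definite).
#' @return An object of class `patch_sampler`.
#' @export
patch_sampler <- function(train_volumes = NULL, patch_shape = c(3L, 3L, 3L),
                          n_draws = 10L, mean = NULL, cov = NULL) {
  patch_shape <- as.integer(patch_shape)
  if (length(patch_shape) != 3 || any(patch_shape < 1))
    stop_field("patch_shape", "must be 3 positive integers")
  n_draws <- check_count(n_draws, "n_draws")
  p <- prod(patch_shape)
  if (!is.null(mean)) {
    if (length(mean) != p) stop_field("mean", "length must equal prod(patch_shape)")
    if (is.null(cov)) cov <- matrix(0, p, p)
    if (!isTRUE(all.equal(cov, t(cov))))
      stop_field("cov", "covariance must be symmetric")
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop_field("cov", "covariance must be positive semi-definite")
  } else if (is.null(train_volumes) || length(train_volumes) < 2) {
    stop_field("train_volumes",
               "need >= 2 training volumes (or a fixed mean/cov)")
  }
  structure(list(train_volumes = train_volumes, patch_shape = patch_shape,
                 n_draws = n_draws, mean = mean, cov = cov),
            class = "patch_sampler")
}

## Patch values of one volume at a 0-based location, as a vector in R's
## column-major order.
extract_patch <- function(vol, location, patch_shape) {
  i <- location + 1L
  as.numeric(vol[i[1]:(i[1] + patch_shape[1] - 1L),
                 i[2]:(i[2] + patch_shape[2] - 1L),
                 i[3]:(i[3] + patch_shape[3] - 1L)])
}

## Mean and eigen-factorised covariance of the sampler at one location.
sampler_moments <- function(sampler, location) {
  if (!is.null(sampler$mean)) {
    mu <- sampler$mean; cv <- sampler$cov
  } else {
    pm <- t(vapply(sampler$train_volumes, extract_patch,
                   numeric(prod(sampler$patch_shape)),
                   location = location, patch_shape = sampler$patch_shape))
    mu <- colMeans(pm)
    cv <- cov(pm)
  }
  ed <- eigen(cv, symmetric = TRUE)
  list(mean = mu, factor = ed$vectors %*% diag(sqrt(pmax(ed$values, 0)),
                                               nrow = length(mu)))
}

## n draws from the sampler at one location (rows = draws).
draw_replacements <- function(sampler, location, n, seed) {
  mo <- sampler_moments(sampler, location)
  p <- length(mo$mean)
  z <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  sweep(z %*% t(mo$factor), 2, mo$mean, `+`)
}

#' Occlude one patch of a volume
#'
#' Returns `n_draws` copies of the volume with the patch at `location`
#' replaced by independent multivariate-normal draws; every voxel outside the
#' patch is bit-identical to the input.
#'
#' @param volume 3D array.
#' @param location 0-based voxel coordinates of the patch corner.
#' @param sampler A [patch_sampler()].
#' @param seed Integer seed for the draws.
#' @return List of `n_draws` occluded volumes.
#' @export
occlude_patch <- function(volume, location, sampler, seed = 1L) {
  stopifnot(inherits(sampler, "patch_sampler"))
  location <- as.integer(location)
  if (length(location) != 3 || any(location < 0) ||
      any(location + sampler$patch_shape > dim(volume)))
    stop_field("location", "patch must fit inside the volume (0-based corner)")
  reps <- draw_replacements(sampler, location, sampler$n_draws, seed)
  i <- location + 1L
  xs <- i[1]:(i[1] + sampler$patch_shape[1] - 1L)
  ys <- i[2]:(i[2] + sampler$patch_shape[2] - 1L)
  zs <- i[3]:(i[3] + sampler$patch_shape[3] - 1L)
  lapply(seq_len(sampler$n_draws), function(d) {
    v <- volume
    v[xs, ys, zs] <- array(reps[d, ], sampler$patch_shape)
    v
  })
}

#' Compute an occlusion relevance map
#'
#' Slides the sampler's patch across the grid with the given stride. At each
#' window the score is the drop in the classifier's case log-odds when the
#' window's information is removed: the intact volume's [decision_logit()]
#' minus the mean logit over the occluded copies (averaging on the log-odds
#' scale keeps the score meaningful where the softmax saturates; away from
#' saturation it agrees with [relevance_score()] applied to the intact and
#' mean occluded probabilities). Scores are accumulated into every voxel of
#' the window, overlapping windows are averaged by coverage count, and
#' per-subject maps are averaged over the subject set. Replacement draws are shared across subjects and seeded per
#' window location (the window with 0-based corner `(x, y, z)` draws with
#' `derive_seed(seed, paste0("loc", x, "_", y, "_", z))`), so the map depends
#' neither on subject order nor on window traversal order, and a per-window
#' loop using [occlude_patch()] with those seeds reproduces it exactly.
#'
#' @param model A trained `cnn_classifier`.
#' @param volumes List of 3D arrays (the evaluation subjects).
#' @param sampler A [patch_sampler()].
#' @param stride Window stride in voxels (1 = dense).
#' @param seed Integer seed.
#' @return Object of class `relevance_map`: `W` (array on the image grid),
#'   plus metadata (`n_subjects`, `stride`, `patch_shape`, `n_draws`).
#' @export
compute_relevance_map <- function(model, volumes, sampler, stride = 1L,
                                  seed = 1L) {
  stopifnot(inherits(sampler, "patch_sampler"))
  if (is.array(volumes) && length(dim(volumes)) == 3) volumes <- list(volumes)
  d <- dim(volumes[[1]])
  stride <- check_count(stride, "stride")
  k <- sampler$patch_shape
  starts <- lapply(1:3, function(a) seq(0L, d[a] - k[a], by = stride))
  l0 <- decision_logit(model, volumes)
  W <- array(0, d); count <- array(0L, d)
  for (z0 in starts[[3]]) for (y0 in starts[[2]]) for (x0 in starts[[1]]) {
    loc <- c(x0, y0, z0)
    reps <- draw_replacements(sampler, loc, sampler$n_draws,
                              derive_seed(seed, paste0("loc", x0, "_", y0, "_", z0)))
    xs <- (x0 + 1L):(x0 + k[1]); ys <- (y0 + 1L):(y0 + k[2]); zs <- (z0 + 1L):(z0 + k[3])
    dbar <- 0
    for (s in seq_along(volumes)) {
      v <- volumes[[s]]
      l1s <- numeric(sampler$n_draws)
      for (r in seq_len(sampler$n_draws)) {
        v[xs, ys, zs] <- array(reps[r, ], k)
        l1s[r] <- decision_logit(model, v)
      }
      dbar <- dbar + (l0[s] - mean(l1s))
    }
    W[xs, ys, zs] <- W[xs, ys, zs] + dbar / length(volumes)
    count[xs, ys, zs] <- count[xs, ys, zs] + 1L
  }
  covered <- count > 0
  W[covered] <- W[covered] / count[covered]
  structure(list(W = W, n_subjects = length(volumes), stride = stride,
                 patch_shape = k, n_draws = sampler$n_draws, seed = seed),
            class = "relevance_map")
}

#' Select top-percentile relevance regions
#'
#' Retains voxels whose relevance reaches the stated percentile of all
#' values (ties at the boundary are kept), labels connected components under
#' the chosen connectivity, and indexes the resulting regions of interest in
#' decreasing size order.
#'
#' @param map A `relevance_map` (or bare numeric 3D array).
#' @param percentile Percentile threshold (default 90 = top decile).
#' @param connectivity 6 or 26 (default) neighbour connectivity.
#' @return Object of class `roi_set`: `rois` (data.frame with roi_index,
#'   size, centroid and 0-based half-open bounding box), `labels` (integer
#'   array, 0 = background), `voxels` (list of 0-based coordinate matrices),
#'   `threshold`, `percentile`, `connectivity`. A constant map yields an
#'   empty set with a warning.
#' @export
select_top_regions <- function(map, percentile = 90, connectivity = 26L) {
  W <- if (inherits(map, "relevance_map")) map$W else map
  stopifnot(is.array(W), length(dim(W)) == 3)
  if (any(!is.finite(W))) stop_field("map", "relevance values must be finite")
  if (!connectivity %in% c(6L, 26L))
    stop_field("connectivity", "must be 6 or 26")
  empty <- structure(list(rois = data.frame(roi_index = integer(),
                                            size = integer(),
                                            centroid_x = numeric(),
                                            centroid_y = numeric(),
                                            centroid_z = numeric()),
                          labels = array(0L, dim(W)), voxels = list(),
                          threshold = NA_real_, percentile = percentile,
                          connectivity = connectivity),
                     class = "roi_set")
  if (diff(range(W)) == 0) {
    warning("constant relevance map: all voxels tie; returning an empty ROI set")
    return(empty)
  }
  thr <- quantile(W, percentile / 100, names = FALSE)
  mask <- W >= thr
  lab <- .label_components(mask, dim(W), as.integer(connectivity))
  nlab <- max(lab)
  if (nlab == 0) { empty$threshold <- thr; return(empty) }
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  ord <- order(sizes, decreasing = TRUE)
  voxels <- vector("list", nlab)
  rois <- do.call(rbind, lapply(seq_len(nlab), function(r) {
    vx <- which(lab == ord[r], arr.ind = TRUE) - 1L
    vx <- vx[order(vx[, 1], vx[, 2], vx[, 3]), , drop = FALSE]
    voxels[[r]] <<- unname(vx)
    data.frame(roi_index = r, size = nrow(vx),
               centroid_x = mean(vx[, 1]), centroid_y = mean(vx[, 2]),
               centroid_z = mean(vx[, 3]),
               x0 = min(vx[, 1]), y0 = min(vx[, 2]), z0 = min(vx[, 3]),
               x1 = max(vx[, 1]) + 1L, y1 = max(vx[, 2]) + 1L,
               z1 = max(vx[, 3]) + 1L)
  }))
  relab <- array(0L, dim(W))
  for (r in seq_len(nlab)) relab[lab == ord[r]] <- r
  structure(list(rois = rois, labels = relab, voxels = voxels,
                 threshold = thr, percentile = percentile,
                 connectivity = connectivity),
            class = "roi_set")
}

#' Extract a subjects-by-voxels matrix for one ROI
#'
#' Rows are subjects, columns the ROI's voxels in lexicographic
#' (x, y, z) coordinate order — the input expected by [fpca_region()].
#'
#' @param volumes List of 3D arrays.
#' @param roi_set An `roi_set`.
#' @param roi_index Which ROI (1 = largest).
#' @return Numeric matrix with the ROI's 0-based voxel coordinates attached
#'   as attribute `"voxels"`.
#' @export
region_signal_matrix <- function(volumes, roi_set, roi_index = 1L) {
  stopifnot(inherits(roi_set, "roi_set"))
  vx <- roi_set$voxels[[roi_index]]
  idx <- vx + 1L
  m <- t(vapply(volumes, function(v) v[idx], numeric(nrow(vx))))
  attr(m, "voxels") <- vx
  m
}

#' Write a relevance map as NIfTI-1
#' @param map A `relevance_map`.
#' @param path Output file path (`.nii`).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @return Invisibly, the path.
#' @export
write_relevance_map <- function(map, path, voxel_size = 2) {
  img <- RNifti::asNifti(map$W, pixdim = rep(voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
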