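## Augmentation and class balancing for small labelled 3D cohorts.
## Composition rule: per original volume emit the original, one blurred copy
## per blur setting, one translated copy per signed one-voxel axis shift,
## then a horizontal flip of every image so far; balancing afterwards
## duplicates randomly chosen minority-class images until classes are equal.

#' Augmentation configuration
#'
#' Defaults follow a blur/translate/flip scheme for registered brain volumes:
#' Gaussian blurs with kernels 3, 5, 7 and spreads 0.7, 0.7, 0.6; one-voxel
#' shifts along each axis in both directions (mimicking registration jitter);
#' and a left-right flip of every image (exploiting approximate anatomical
#' symmetry). With the defaults each original yields
#' 2 x (1 + 3 blurs + 6 shifts) = 20 images before balancing.
#'
#' @param blur_settings List of `c(kernel_size, spread)` pairs; kernel sizes
#'   must be odd.
#' @param translation_voxels Magnitude of the axis shifts (0 disables).
#' @param flip_axis Axis index (1-3) treated as left-right, or `NA` to
#'   disable flipping.
#' @param balance If `TRUE`, duplicate random minority-class images (with
#'   replacement) until class counts are equal.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(blur_settings = list(c(3, 0.7), c(5, 0.7), c(7, 0.6)),
                                translation_voxels = 1L,
                                flip_axis = 1L,
                                balance = TRUE) {
  for (b in blur_settings) {
    if (length(b) != 2 || b[1] %% 2 != 1 || b[2] <= 0)
      stop_field("blur_settings", "each entry must be c(odd kernel size, spread > 0)")
  }
  if (translation_voxels < 0 || translation_voxels != as.integer(translation_voxels))
    stop_field("translation_voxels", "must be a non-negative integer")
  if (!is.na(flip_axis) && !flip_axis %in% 1:3)
    stop_field("flip_axis", "flip axis must be in [1, 3] (or NA to disable)")
  structure(list(blur_settings = blur_settings,
                 translation_voxels = as.integer(translation_voxels),
                 flip_axis = if (is.na(flip_axis)) NA_integer_ else as.integer(flip_axis),
                 balance = isTRUE(balance)),
            class = "augmentation_config")
}

## All augmented variants of one volume (original first, flips appended last).
augment_one <- function(vol, cfg) {
  out <- list(vol)
  for (b in cfg$blur_settings)
    out[[length(out) + 1L]] <- gaussian_blur3d(vol, b[1], b[2])
  if (cfg$translation_voxels > 0) {
    t <- cfg$translation_voxels
    for (axis in 1:3) for (s in c(-t, t)) {
      shift <- integer(3); shift[axis] <- s
      out[[length(out) + 1L]] <- translate3d(vol, shift)
    }
  }
  if (!is.na(cfg$flip_axis))
    out <- c(out, lapply(out, flip3d, axis = cfg$flip_axis))
  out
}

#' Augment a labelled volume dataset
#'
#' Applies the pinned blur/translate/flip composition to every volume, then
#' (optionally) balances classes by random duplication of minority-class
#' images. Augmented copies keep their source `subject_id`, so downstream
#' cross-validation can keep every derived image of a held-out subject out of
#' training.
#'
#' @param cohort An `image_cohort`, or any list with `volumes`, `labels`,
#'   `subject_ids`.
#' @param cfg An [augmentation_config()].
#' @param seed Integer seed (used only for balancing duplication).
#' @return An `image_cohort` with augmented `volumes`, `labels`,
#'   `subject_ids` (source ids) and an `origin` vector describing each
#'   image's provenance.
#' @export
augment_dataset <- function(cohort, cfg = augmentation_config(), seed = 1L) {
  stopifnot(!is.null(cohort$volumes), !is.null(cohort$labels))
  labels <- as.integer(cohort$labels)
  if (isTRUE(cfg$balance) && length(unique(labels)) < 2)
    stop("balance = TRUE requires at least one volume per class", call. = FALSE)
  ids <- if (!is.null(cohort$subject_ids)) cohort$subject_ids
         else sprintf("S%03d", seq_along(labels))
  volumes <- list(); out_labels <- integer(); out_ids <- character()
  origin <- character()
  for (i in seq_along(cohort$volumes)) {
    aug <- augment_one(cohort$volumes[[i]], cfg)
    volumes <- c(volumes, aug)
    out_labels <- c(out_labels, rep(labels[i], length(aug)))
    out_ids <- c(out_ids, rep(ids[i], length(aug)))
    origin <- c(origin, paste0(ids[i], "/aug", seq_along(aug)))
  }
  if (isTRUE(cfg$balance)) {
    tab <- table(out_labels)
    minority <- as.integer(names(tab)[which.min(tab)])
    deficit <- max(tab) - min(tab)
    if (deficit > 0) {
      pool <- which(out_labels == minority)
      dup <- withr::with_seed(seed, sample(pool, deficit, replace = TRUE))
      volumes <- c(volumes, volumes[dup])
      out_labels <- c(out_labels, out_labels[dup])
      out_ids <- c(out_ids, out_ids[dup])
      origin <- c(origin, paste0(origin[dup], "/dup"))
    }
  }
  structure(list(volumes = volumes, labels = out_labels, subject_ids = out_ids,
                 origin = origin, grid_shape = dim(cohort$volumes[[1]]),
                 truth = cohort$truth),
            class = "image_cohort")
}
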