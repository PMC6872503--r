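## Synthetic-data module: labelled 3D volumes with planted signal regions,
## Hardy-Weinberg genotype matrices, and bivariate additive-noise cause-effect
## pairs. Every generator is a pure function of (spec, seed).

#' Specification of a synthetic labelled image cohort
#'
#' Describes a case/control cohort of registered 3D volumes in which the
#' class signal is concentrated in planted axis-aligned boxes: case volumes
#' have their mean intensity inside each box elevated by `effect_size`.
#' The background is Gaussian noise, optionally smoothed to mimic the spatial
#' correlation of registered diffusion images.
#'
#' @param grid_shape Integer vector of 3 positive voxel counts.
#' @param n_cases,n_controls Subject counts (>= 1 each).
#' @param signal_regions List of boxes, each a 2x3 matrix `rbind(start, end)`
#'   of 0-based half-open voxel coordinates (`start` inclusive, `end`
#'   exclusive).
#' @param effect_size Mean intensity shift added inside each box for cases.
#' @param noise_sd Standard deviation of the background noise (> 0).
#' @param smoothness_sigma Gaussian smoothing of the noise field, in voxels
#'   (0 = white noise). Smoothed fields are rescaled back to `noise_sd`.
#' @param seed Integer seed; the cohort is a pure function of spec + seed.
#' @return An object of class `image_cohort_spec`.
#' @export
image_cohort_spec <- function(grid_shape, n_cases, n_controls,
                              signal_regions = list(),
                              effect_size = 1, noise_sd = 1,
                              smoothness_sigma = 0, seed = 1L) {
  if (length(grid_shape) != 3 || any(grid_shape < 1) ||
      any(grid_shape != as.integer(grid_shape)))
    stop_field("grid_shape", "must be 3 positive integers")
  grid_shape <- as.integer(grid_shape)
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  effect_size <- check_number(effect_size, "effect_size")
  smoothness_sigma <- check_number(smoothness_sigma, "smoothness_sigma", lower = 0)
  if (!is.list(signal_regions)) stop_field("signal_regions", "must be a list of boxes")
  signal_regions <- lapply(signal_regions, function(b) {
    b <- matrix(as.integer(b), nrow = 2)
    if (ncol(b) != 3) stop_field("signal_regions", "each box must be a 2x3 matrix")
    if (any(b[1, ] < 0) || any(b[2, ] > grid_shape) || any(b[2, ] <= b[1, ]))
      stop_field("signal_regions",
                 "box must be non-empty and lie inside grid_shape (0-based, half-open)")
    b
  })
  structure(list(grid_shape = grid_shape, n_cases = n_cases,
                 n_controls = n_controls, signal_regions = signal_regions,
                 effect_size = effect_size, noise_sd = noise_sd,
                 smoothness_sigma = smoothness_sigma,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "image_cohort_spec")
}

## Logical mask of all planted boxes on the spec's grid.
region_mask <- function(grid_shape, signal_regions) {
  m <- array(FALSE, grid_shape)
  for (b in signal_regions)
    m[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2], (b[1, 3] + 1):b[2, 3]] <- TRUE
  m
}

#' Generate a labelled synthetic image cohort
#'
#' Case volumes (label 1) carry the planted mean shift inside every signal
#' region; control volumes (label 0) are pure background. Identical specs and
#' seeds reproduce bit-identical cohorts.
#'
#' @param spec An [image_cohort_spec()].
#' @return A list of class `image_cohort` with `volumes` (list of 3D arrays),
#'   `labels` (integer 0/1, 1 = case), `subject_ids`, and `truth`
#'   (a `synthetic_truth` echoing the planted regions and parameters).
#' @export
generate_image_cohort <- function(spec) {
  stopifnot(inherits(spec, "image_cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  labels <- c(rep(1L, spec$n_cases), rep(0L, spec$n_controls))
  mask <- region_mask(spec$grid_shape, spec$signal_regions)
  smooth_size <- if (spec$smoothness_sigma > 0)
    2L * as.integer(ceiling(2 * spec$smoothness_sigma)) + 1L else 0L
  volumes <- withr::with_seed(spec$seed, lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(spec$grid_shape)), spec$grid_shape)
    if (smooth_size > 0) {
      v <- gaussian_blur3d(v, smooth_size, spec$smoothness_sigma)
      v <- v / sd(v)          # restore unit scale lost to smoothing
    }
    v <- v * spec$noise_sd
    if (labels[i] == 1L && any(mask)) v[mask] <- v[mask] + spec$effect_size
    v
  }))
  ids <- sprintf("S%03d", seq_len(n))
  truth <- structure(list(signal_regions = spec$signal_regions,
                          signal_mask = mask, spec = spec),
                     class = "synthetic_truth")
  structure(list(volumes = volumes, labels = labels, subject_ids = ids,
                 grid_shape = spec$grid_shape, truth = truth),
            class = "image_cohort")
}

#' Specification of a synthetic genotype cohort
#'
#' @param n_subjects Subject count.
#' @param genes Named list mapping gene ids to strictly increasing SNP
#'   base-pair positions.
#' @param maf_range Length-2 interval inside (0, 0.5] from which each SNP's
#'   minor-allele frequency is drawn uniformly.
#' @param seed Integer seed.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(n_subjects, genes, maf_range = c(0.05, 0.5), seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (!is.list(genes) || length(genes) == 0 || is.null(names(genes)) ||
      any(!nzchar(names(genes))))
    stop_field("genes", "must be a non-empty named list of SNP position vectors")
  for (g in names(genes)) {
    pos <- genes[[g]]
    if (length(pos) < 1 || any(diff(pos) <= 0))
      stop_field("genes", sprintf("positions in gene '%s' must be strictly increasing", g))
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_field("maf_range", "must be an interval inside (0, 0.5]")
  structure(list(n_subjects = n_subjects, genes = genes,
                 maf_range = as.numeric(maf_range),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "genotype_spec")
}

#' Generate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Each SNP draws a minor-allele frequency uniformly from `maf_range` and
#' genotypes as Binomial(2, maf) counts of the minor allele; SNPs are
#' independent (no linkage disequilibrium).
#'
#' @param spec A [genotype_spec()].
#' @return List with `genotypes` (subjects x SNPs integer matrix, values
#'   0/1/2), and `map` (data.frame: snp_id, gene_id, position, maf).
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "genotype_spec"))
  map <- do.call(rbind, lapply(names(spec$genes), function(g) {
    data.frame(gene_id = g, position = spec$genes[[g]],
               stringsAsFactors = FALSE)
  }))
  map$snp_id <- sprintf("%s_snp%03d", map$gene_id,
                        unlist(lapply(spec$genes, seq_along), use.names = FALSE))
  withr::with_seed(spec$seed, {
    map$maf <- runif(nrow(map), spec$maf_range[1], spec$maf_range[2])
    geno <- vapply(map$maf,
                   function(p) rbinom(spec$n_subjects, 2L, p),
                   integer(spec$n_subjects))
  })
  geno <- matrix(as.integer(geno), nrow = spec$n_subjects,
                 dimnames = list(sprintf("S%03d", seq_len(spec$n_subjects)),
                                 map$snp_id))
  list(genotypes = geno, map = map[, c("snp_id", "gene_id", "position", "maf")])
}

anm_mechanisms <- list(
  linear    = function(u) u,
  quadratic = function(u) u^2,
  sigmoid   = function(u) tanh(2 * u)
)

#' Specification of a bivariate additive-noise cause-effect pair
#'
#' Under `direction = "x_to_y"` the pair follows the additive-noise model
#' `y = f(x) + e` with `e` independent of `x`; `"y_to_x"` swaps the roles;
#' `"none"` makes the variables independent.
#'
#' @param n Sample count (>= 10).
#' @param mechanism One of `"linear"`, `"quadratic"`, `"sigmoid"`.
#' @param direction One of `"x_to_y"`, `"y_to_x"`, `"none"`.
#' @param noise_sd Additive-noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return An object of class `causal_pair_spec`.
#' @export
causal_pair_spec <- function(n, mechanism = "quadratic",
                             direction = "x_to_y", noise_sd = 1, seed = 1L) {
  n <- check_count(n, "n", min = 10L)
  if (!is.character(mechanism) || length(mechanism) != 1 ||
      !mechanism %in% names(anm_mechanisms))
    stop_field("mechanism", sprintf("must be one of %s",
                                    paste(names(anm_mechanisms), collapse = ", ")))
  if (!direction %in% c("x_to_y", "y_to_x", "none"))
    stop_field("direction", "must be one of x_to_y, y_to_x, none")
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  structure(list(n = n, mechanism = mechanism, direction = direction,
                 noise_sd = noise_sd, seed = check_count(seed, "seed", min = 0L)),
            class = "causal_pair_spec")
}

#' Generate a bivariate cause-effect pair
#'
#' @param spec A [causal_pair_spec()].
#' @return List of class `causal_pair` with `x`, `y`, and `truth`
#'   (class `synthetic_truth`, holding `true_direction` and the spec).
#' @export
generate_causal_pair <- function(spec) {
  stopifnot(inherits(spec, "causal_pair_spec"))
  f <- anm_mechanisms[[spec$mechanism]]
  withr::with_seed(spec$seed, {
    cause <- rnorm(spec$n)
    noise <- rnorm(spec$n, 0, spec$noise_sd)
  })
  if (spec$direction == "x_to_y") { x <- cause; y <- f(cause) + noise }
  else if (spec$direction == "y_to_x") { y <- cause; x <- f(cause) + noise }
  else { x <- cause; y <- noise }
  truth <- structure(list(true_direction = spec$direction, spec = spec),
                     class = "synthetic_truth")
  structure(list(x = x, y = y, truth = truth), class = "causal_pair")
}

#' Write a synthetic image cohort to disk
#'
#' Volumes are written as NIfTI-1 files with an identity affine scaled by the
#' voxel size; labels and planted-region truth go to TSV sidecars.
#'
#' @param cohort An `image_cohort`.
#' @param dir Output directory (created if needed).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @return Invisibly, the manifest data.frame (subject_id, path, label).
#' @export
write_image_cohort <- function(cohort, dir, voxel_size = 2) {
  stopifnot(inherits(cohort, "image_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$subject_ids, ".nii"))
  for (i in seq_along(cohort$volumes)) {
    img <- RNifti::asNifti(cohort$volumes[[i]],
                           pixdim = rep(voxel_size, 3))
    RNifti::writeNifti(img, paths[i])
  }
  manifest <- data.frame(subject_id = cohort$subject_ids, path = paths,
                         label = cohort$labels, stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  boxes <- do.call(rbind, lapply(seq_along(cohort$truth$signal_regions), function(i) {
    b <- cohort$truth$signal_regions[[i]]
    data.frame(region = i, x0 = b[1, 1], y0 = b[1, 2], z0 = b[1, 3],
               x1 = b[2, 1], y1 = b[2, 2], z1 = b[2, 3])
  }))
  if (!is.null(boxes))
    write.table(boxes, file.path(dir, "truth_regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_image_cohort()]
#'
#' @param dir Directory holding `labels.tsv` and the NIfTI volumes.
#' @return An `image_cohort` (without truth if no sidecar is present).
#' @export
read_image_cohort <- function(dir) {
  manifest <- read.delim(file.path(dir, "labels.tsv"), stringsAsFactors = FALSE)
  volumes <- lapply(manifest$path, function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim(v))
  })
  structure(list(volumes = volumes, labels = as.integer(manifest$label),
                 subject_ids = manifest$subject_id,
                 grid_shape = dim(volumes[[1]]), truth = NULL),
            class = "image_cohort")
}
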