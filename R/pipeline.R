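## End-to-end orchestration: synthesize (or ingest) a cohort, train the CNN,
## compute the occlusion relevance map, extract ROIs, summarise them by FPC
## scores, run the CGAN/C2ST causal tests against disease status, and screen
## with Bonferroni correction. Every stage draws its seed deterministically
## from one global seed and is recorded in a hash manifest.

#' Pipeline run configuration
#'
#' Stage settings are stored as plain argument lists (so a configuration
#' round-trips bit-exactly through YAML); the corresponding objects are built
#' when the pipeline runs. Stages form a fixed dependency chain
#' synth -> train -> relevance -> fpca -> causal -> screen; enabling a stage
#' whose upstream is disabled is a configuration error.
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed; per-stage seeds are derived from it.
#' @param stages Character vector of enabled stages.
#' @param synth Arguments for [image_cohort_spec()] (boxes may be given as
#'   flat `c(x0, y0, z0, x1, y1, z1)` vectors).
#' @param input_dir Directory of an existing cohort (alternative to synth).
#' @param arch Arguments for [architecture_config()].
#' @param augment Arguments for [augmentation_config()], or `NULL` to train
#'   without augmentation.
#' @param train List: `hyperparams` (see [train_classifier()]) and
#'   `holdout_fraction` (stratified held-out share used for evaluation and
#'   relevance; default 0.25).
#' @param relevance List: `patch_shape`, `n_draws`, `stride`, `percentile`,
#'   `connectivity`, `n_eval_subjects`.
#' @param fpca List: `max_rois`, plus arguments of [fpca_region()].
#' @param causal List: `cgan` ([cgan_config()] arguments),
#'   `n_covariance_splits`, `alpha`.
#' @param write_volumes Also write the synthetic volumes as NIfTI.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("synth", "train", "relevance", "fpca",
                                  "causal", "screen"),
                       synth = list(), input_dir = NULL,
                       arch = list(), augment = list(),
                       train = list(), relevance = list(), fpca = list(),
                       causal = list(), write_volumes = FALSE) {
  all_stages <- c("synth", "train", "relevance", "fpca", "causal", "screen")
  if (!all(stages %in% all_stages))
    stop_field("stages", paste("must be among", paste(all_stages, collapse = ", ")))
  deps <- c(train = if (is.null(input_dir)) "synth" else NA,
            relevance = "train", fpca = "relevance", causal = "fpca",
            screen = "causal")
  for (st in stages) {
    d <- deps[st]
    if (!is.na(d) && !is.null(d) && !(d %in% stages) && st %in% names(deps))
      stop(sprintf("stage '%s' requires stage '%s' to be enabled", st, d),
           call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = check_count(seed, "seed", min = 0L),
                 stages = stages, synth = synth, input_dir = input_dir,
                 arch = arch, augment = augment, train = train,
                 relevance = relevance, fpca = fpca, causal = causal,
                 write_volumes = isTRUE(write_volumes)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

build_cohort_spec <- function(args, seed) {
  if (!is.null(args$signal_regions))
    args$signal_regions <- lapply(args$signal_regions, function(b) {
      if (is.matrix(b)) b else rbind(unlist(b)[1:3], unlist(b)[4:6])
    })
  if (is.null(args$seed)) args$seed <- seed
  do.call(image_cohort_spec, args)
}

stage_record <- function(manifest, name, seed, inputs, outputs, t0, settings = NULL) {
  manifest[[name]] <- list(seed = seed,
                           inputs = lapply(inputs, rlang::hash),
                           outputs = lapply(outputs, rlang::hash),
                           elapsed_sec = round(as.numeric(Sys.time()) - t0, 3),
                           settings = settings)
  manifest
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order and writes per-stage
#' outputs (TSV/NIfTI) under `config$out_dir`, plus `manifest.json` with the
#' seed and input/output hashes of every stage. Deterministic stages
#' reproduce identical hashes when re-run with the same config and seed.
#'
#' @param config A [run_config()].
#' @return List of class `run_manifest`: per-stage hash records plus
#'   `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = as.character(utils::packageVersion("neurocausal")),
                   seed = config$seed)
  res <- list()
  on <- function(st) st %in% config$stages

  if (on("synth")) {
    t0 <- as.numeric(Sys.time())
    sseed <- derive_seed(config$seed, "synth")
    spec <- build_cohort_spec(config$synth, sseed)
    cohort <- generate_image_cohort(spec)
    if (config$write_volumes)
      write_image_cohort(cohort, file.path(config$out_dir, "volumes"))
    else
      write.table(data.frame(subject_id = cohort$subject_ids,
                             label = cohort$labels),
                  file.path(config$out_dir, "labels.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    res$cohort <- cohort
    manifest <- stage_record(manifest, "synth", spec$seed,
                             list(spec = unclass(spec)),
                             list(volumes = cohort$volumes,
                                  labels = cohort$labels), t0)
  } else if (!is.null(config$input_dir)) {
    res$cohort <- read_image_cohort(config$input_dir)
  }

  if (on("train")) {
    if (is.null(res$cohort))
      stop("stage 'train': missing upstream cohort (enable synth or set input_dir)",
         call. = FALSE)
    t0 <- as.numeric(Sys.time())
    tseed <- derive_seed(config$seed, "train")
    topt <- modifyList(list(hyperparams = list(), holdout_fraction = 0.25),
                       config$train)
    arch <- do.call(architecture_config, config$arch)
    labels <- res$cohort$labels
    holdout <- stratified_folds(labels, max(2L, round(1 / topt$holdout_fraction)),
                                derive_seed(tseed, "holdout")) == 1L
    train_set <- list(volumes = res$cohort$volumes[!holdout],
                      labels = labels[!holdout],
                      subject_ids = res$cohort$subject_ids[!holdout])
    if (!is.null(config$augment))
      train_set <- augment_dataset(train_set,
                                   do.call(augmentation_config, config$augment),
                                   seed = derive_seed(tseed, "augment"))
    model <- build_classifier(arch, res$cohort$grid_shape,
                              seed = derive_seed(tseed, "init"))
    model <- train_classifier(model, train_set$volumes, train_set$labels,
                              topt$hyperparams, seed = derive_seed(tseed, "sgd"))
    metrics <- evaluate(model, res$cohort$volumes[holdout], labels[holdout])
    mdf <- data.frame(accuracy = metrics$accuracy,
                      sensitivity = metrics$sensitivity,
                      specificity = metrics$specificity, auc = metrics$auc)
    write.table(mdf, file.path(config$out_dir, "holdout_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$model <- model; res$holdout <- which(holdout)
    res$train_subjects <- unique(train_set$subject_ids)
    res$metrics <- metrics
    manifest <- stage_record(manifest, "train", tseed,
                             list(labels = labels),
                             list(weights = lapply(model$layers, `[`, c("w", "b")),
                                  metrics = mdf), t0,
                             settings = model$log$hyperparams)
  }

  if (on("relevance")) {
    if (is.null(res$model))
      stop("stage 'relevance': missing upstream trained model", call. = FALSE)
    t0 <- as.numeric(Sys.time())
    rseed <- derive_seed(config$seed, "relevance")
    ropt <- modifyList(list(patch_shape = c(3L, 3L, 3L), n_draws = 5L,
                            stride = 3L, percentile = 90,
                            connectivity = 26L, n_eval_subjects = 6L),
                       config$relevance)
    eval_idx <- head(res$holdout, ropt$n_eval_subjects)
    if (length(eval_idx) == 0) eval_idx <- seq_along(res$cohort$volumes)
    train_idx <- setdiff(seq_along(res$cohort$volumes), res$holdout)
    sampler <- patch_sampler(res$cohort$volumes[train_idx],
                             ropt$patch_shape, ropt$n_draws)
    map <- compute_relevance_map(res$model, res$cohort$volumes[eval_idx],
                                 sampler, stride = ropt$stride, seed = rseed)
    rois <- select_top_regions(map, ropt$percentile, ropt$connectivity)
    write_relevance_map(map, file.path(config$out_dir, "relevance.nii"))
    write.table(rois$rois, file.path(config$out_dir, "rois.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$map <- map; res$rois <- rois
    manifest <- stage_record(manifest, "relevance", rseed,
                             list(eval_idx = eval_idx),
                             list(W = map$W, rois = rois$rois), t0,
                             settings = ropt[c("patch_shape", "n_draws",
                                               "stride", "percentile")])
  }

  if (on("fpca")) {
    if (is.null(res$rois))
      stop("stage 'fpca': missing upstream ROI set (enable relevance)",
           call. = FALSE)
    t0 <- as.numeric(Sys.time())
    fopt <- modifyList(list(max_rois = 10L, n_components = NULL,
                            variance_target = 0.8, max_components = 5L),
                       config$fpca)
    n_rois <- min(nrow(res$rois$rois), fopt$max_rois)
    if (n_rois == 0)
      stop("stage 'fpca': relevance produced no ROIs", call. = FALSE)
    scores <- lapply(seq_len(n_rois), function(r) {
      m <- region_signal_matrix(res$cohort$volumes, res$rois, r)
      fpca_region(m, n_components = fopt$n_components,
                  variance_target = fopt$variance_target,
                  max_components = fopt$max_components)
    })
    for (r in seq_len(n_rois))
      write_fpc_scores(scores[[r]],
                       file.path(config$out_dir, sprintf("fpc_roi%02d.tsv", r)),
                       res$cohort$subject_ids)
    res$fpc <- scores
    manifest <- stage_record(manifest, "fpca", derive_seed(config$seed, "fpca"),
                             list(rois = res$rois$rois),
                             list(scores = lapply(scores, `[[`, "scores")), t0)
  }

  if (on("causal")) {
    if (is.null(res$fpc))
      stop("stage 'causal': missing upstream FPC scores (enable fpca)",
           call. = FALSE)
    t0 <- as.numeric(Sys.time())
    cseed <- derive_seed(config$seed, "causal")
    copt <- modifyList(list(cgan = list(epochs = 120L), n_covariance_splits = 10L,
                            alpha = 0.05, timepoint = "baseline"),
                       config$causal)
    cgan <- do.call(cgan_config, copt$cgan)
    rows <- lapply(seq_along(res$fpc), function(r) {
      ct <- causal_test(res$fpc[[r]]$scores[, 1],
                        as.numeric(res$cohort$labels), cfg = cgan,
                        n_covariance_splits = copt$n_covariance_splits,
                        seed = derive_seed(cseed, paste0("roi", r)),
                        alpha = copt$alpha)
      data.frame(timepoint = copt$timepoint, roi_index = r,
                 p_value = ct$p_value, t_xy = ct$t_xy, t_yx = ct$t_yx,
                 T = ct$T, sigma2 = ct$sigma2, call = ct$call)
    })
    causal_tab <- do.call(rbind, rows)
    write.table(causal_tab, file.path(config$out_dir, "causal_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$causal <- causal_tab
    manifest <- stage_record(manifest, "causal", cseed,
                             list(scores = lapply(res$fpc, `[[`, "scores")),
                             list(table = causal_tab), t0,
                             settings = copt)
  }

  if (on("screen")) {
    if (is.null(res$causal))
      stop("stage 'screen': missing upstream causal results", call. = FALSE)
    t0 <- as.numeric(Sys.time())
    alpha <- if (!is.null(config$causal$alpha)) config$causal$alpha else 0.05
    thr <- bonferroni_threshold(alpha, nrow(res$causal))
    scr <- screen_results(res$causal, thr)
    write.table(scr$significant,
                file.path(config$out_dir, "screen_significant.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$screen <- scr
    manifest <- stage_record(manifest, "screen",
                             derive_seed(config$seed, "screen"),
                             list(table = res$causal),
                             list(significant = scr$significant,
                                  counts = scr$counts), t0,
                             settings = list(threshold = thr))
  }

  manifest$results <- res
  jsonlite::write_json(manifest[setdiff(names(manifest), "results")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(manifest, class = "run_manifest")
}
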