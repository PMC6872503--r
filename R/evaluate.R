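## Evaluation metrics (accuracy, sensitivity, specificity, AUC with the case
## class as positive) and stratified, leak-free k-fold cross-validation.

#' Metrics from predicted case probabilities
#'
#' Core metric computation shared by [evaluate()] and the cross-validation
#' driver. Sensitivity and specificity treat the case class (label 1, AD in
#' the disease application) as positive; predicted class is the argmax
#' (probability >= 0.5). AUC is the Mann-Whitney rank statistic on the
#' predicted case probability, with ties counted half.
#'
#' @param case_prob Numeric vector of predicted case probabilities.
#' @param labels Integer 0/1 truth.
#' @return Object of class `eval_metrics`: accuracy, sensitivity,
#'   specificity, auc (each `NA` when undefined), and the confusion counts.
#' @export
evaluate_predictions <- function(case_prob, labels) {
  labels <- as.integer(labels)
  stopifnot(length(case_prob) == length(labels), all(labels %in% 0:1))
  pred <- as.integer(case_prob >= 0.5)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(case_prob)                      # midranks handle ties
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(accuracy = (tp + tn) / length(labels),
                 sensitivity = if (n1 == 0) NA_real_ else tp / (tp + fn),
                 specificity = if (n0 == 0) NA_real_ else tn / (tn + fp),
                 auc = auc,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "eval_metrics")
}

#' Evaluate a trained classifier on labelled volumes
#'
#' @param model A `cnn_classifier`.
#' @param volumes List of 3D arrays.
#' @param labels Integer 0/1 labels (1 = case).
#' @return An `eval_metrics` object.
#' @export
evaluate <- function(model, volumes, labels) {
  p <- predict_proba(model, volumes)
  evaluate_predictions(p[, "case"], labels)
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | sensitivity %s | specificity %s | AUC %s\n",
              x$accuracy,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.4f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.4f", x$specificity)),
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

## Stratified fold assignment: within each class, subjects are shuffled and
## dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  })
  fold
}

#' Stratified k-fold cross-validation of the 3D CNN
#'
#' Subjects are assigned to stratified folds; augmentation (when configured)
#' is applied inside each training fold only, so no augmented copy of a
#' held-out subject ever enters training. Metrics are computed on the intact
#' held-out volumes.
#'
#' @param volumes List of 3D arrays.
#' @param labels Integer 0/1 labels.
#' @param k Number of folds (every class must have >= k members).
#' @param seed Integer seed driving fold assignment, augmentation and
#'   training.
#' @param arch An [architecture_config()].
#' @param augment An [augmentation_config()] or `NULL` to train on the raw
#'   fold.
#' @param hyperparams Passed to [train_classifier()].
#' @param subject_ids Optional subject identifiers (defaults to S001...).
#' @return List of class `cv_result`: `folds` (assignment vector), `metrics`
#'   (per-fold `eval_metrics`), `mean` (averaged metrics), `case_prob`
#'   (out-of-fold predicted probabilities), and `train_subjects` (per fold,
#'   the subject ids present in its training data, augmented copies
#'   included).
#' @export
crossvalidate <- function(volumes, labels, k = 5L, seed = 1L,
                          arch = architecture_config(),
                          augment = NULL, hyperparams = list(),
                          subject_ids = NULL) {
  labels <- as.integer(labels)
  k <- check_count(k, "k", min = 2L)
  if (min(table(labels)) < k)
    stop_field("k", "each class must have at least k members")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_along(labels))
  ## Canonical subject order makes folds, training batches and hence all
  ## metrics invariant to the order volumes are supplied in.
  ord <- order(subject_ids)
  volumes <- volumes[ord]; labels <- labels[ord]; subject_ids <- subject_ids[ord]
  fold <- stratified_folds(labels, k, derive_seed(seed, "folds"))
  case_prob <- numeric(length(labels))
  metrics <- vector("list", k)
  train_subjects <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    train_set <- list(volumes = volumes[tr], labels = labels[tr],
                      subject_ids = subject_ids[tr])
    if (!is.null(augment))
      train_set <- augment_dataset(train_set, augment,
                                   seed = derive_seed(seed, paste0("augment", f)))
    train_subjects[[f]] <- unique(train_set$subject_ids)
    model <- build_classifier(arch, dim(volumes[[1]]),
                              seed = derive_seed(seed, paste0("init", f)))
    model <- train_classifier(model, train_set$volumes, train_set$labels,
                              hyperparams,
                              seed = derive_seed(seed, paste0("train", f)))
    p <- predict_proba(model, volumes[te])
    case_prob[te] <- p[, "case"]
    metrics[[f]] <- evaluate_predictions(p[, "case"], labels[te])
  }
  nums <- c("accuracy", "sensitivity", "specificity", "auc")
  mean_metrics <- sapply(nums, function(m)
    mean(vapply(metrics, `[[`, numeric(1), m), na.rm = TRUE))
  ## Report per-subject quantities in the caller's original order.
  unord <- order(ord)
  structure(list(folds = fold[unord], metrics = metrics, mean = mean_metrics,
                 case_prob = case_prob[unord],
                 train_subjects = train_subjects,
                 subject_ids = subject_ids[unord], k = k, seed = seed),
            class = "cv_result")
}
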