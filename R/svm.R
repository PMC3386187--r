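# Tumor-stage classification from low-frequency subband texture principal
# components with a cross-validated radial-basis SVM.

#' SVM configuration
#'
#' Radial-basis kernel with a small regularization/width grid on
#' standardized features; "maximum classification accuracy" implies a
#' parameter search, so the grid maximum is reported. One-vs-one
#' multiclass decomposition (the e1071/libsvm default).
#'
#' @param cost regularization grid.
#' @param gamma kernel-width grid.
#' @param folds stratified CV folds (default 5).
#' @param seed integer seed for fold assignment and the permutation
#'   baseline.
#' @return an `svm_config` list.
#' @export
svm_config <- function(cost = c(0.1, 1, 10, 100), gamma = c(0.01, 0.1, 1),
                       folds = 5L, seed = 0L) {
  if (!length(cost) || !length(gamma)) stop_config("parameter grids are empty")
  if (!is_count(folds) || folds < 2L) stop_config("`folds` must be >= 2")
  structure(list(cost = cost, gamma = gamma, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' Build the stage-classification dataset from LF1 subband texture
#'
#' Pools the tumor-ROI texture vectors of the level-1 low-frequency
#' subband across all stages, standardizes them, fits the correlation PCA
#' and retains the leading components by the cumulative contribution-rate
#' rule. Rows carry their stage labels.
#'
#' @param dt_features data.frame from [subband_texture_features()].
#' @param subband subband used as the classification basis (default
#'   `"LF1"`).
#' @param cr_threshold contribution-rate threshold (default 0.80).
#' @return a `stage_dataset`: data.frame of PC-score features plus a
#'   `stage` column, with the fitted `pca_model` and selected components
#'   as attributes.
#' @export
build_stage_features <- function(dt_features, subband = "LF1",
                                 cr_threshold = 0.80) {
  sub <- dt_features[dt_features$subband == subband &
                       dt_features$region_label == "tumor", , drop = FALSE]
  stages <- unique(sub$stage)
  if (length(stages) < 2L)
    stop_config("need >= 2 stages for classification, got %d",
                length(stages))
  cnt <- table(sub$stage)
  if (any(cnt < 5L))
    stop_config("need >= 5 ROIs per stage (min observed: %d)", min(cnt))
  std <- standardize_features(sub[, glcm_feature_names(), drop = FALSE])
  model <- pca_fit(std)
  model <- orient_signs(model, std, labels = NULL) # unsupervised orientation
  keep <- select_components(model, cr_threshold)
  sc <- pca_scores(model, std)[, keep, drop = FALSE]
  ds <- data.frame(sc, stage = factor(sub$stage, levels = tumor_stages()[
    tumor_stages() %in% stages]))
  attr(ds, "pca_model") <- model
  attr(ds, "components") <- keep
  class(ds) <- c("stage_dataset", class(ds))
  ds
}

# deterministic stratified fold assignment: depends only on (labels, folds,
# seed)
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < folds)
        stop_config(
          "class '%s' has %d rows, fewer than %d folds; use fewer folds",
          cl, length(idx), folds)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

cv_accuracy <- function(x, y, fold, folds, cost, gamma) {
  acc <- numeric(folds)
  conf <- table(factor(levels(y), levels = levels(y)),
                factor(levels(y), levels = levels(y))) * 0L
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, x[te, , drop = FALSE])
    acc[f] <- mean(pred == y[te])
    conf <- conf + table(factor(y[te], levels = levels(y)),
                         factor(pred, levels = levels(y)))
  }
  list(mean = mean(acc), per_fold = acc, confusion = conf)
}

#' Cross-validated SVM staging with a permutation baseline
#'
#' Stratified k-fold cross-validation over the parameter grid; reports the
#' maximum mean CV accuracy, its grid point, per-fold accuracies and the
#' pooled confusion matrix at the best grid point, plus a label-permutation
#' baseline computed with the same folds and grid after shuffling the
#' labels with the run seed.
#'
#' @param dataset a [build_stage_features()] dataset (or any data.frame
#'   with feature columns and a `stage` factor).
#' @param config an [svm_config()].
#' @return a `classification_report` list.
#' @export
crossval_svm <- function(dataset, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  y <- droplevels(factor(dataset$stage))
  x <- as.matrix(dataset[, setdiff(names(dataset), "stage"), drop = FALSE])
  fold <- stratified_folds(y, config$folds, config$seed)
  grid <- expand.grid(cost = config$cost, gamma = config$gamma)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    res <- cv_accuracy(x, y, fold, config$folds, grid$cost[g], grid$gamma[g])
    if (is.null(best) || res$mean > best$mean) {
      best <- res
      best$cost <- grid$cost[g]; best$gamma <- grid$gamma[g]
    }
  }
  # permutation baseline: same folds and procedure on shuffled labels
  yp <- with_seed(config$seed + 1L, sample(y))
  pbest <- 0
  for (g in seq_len(nrow(grid))) {
    res <- cv_accuracy(x, yp, fold, config$folds, grid$cost[g], grid$gamma[g])
    pbest <- max(pbest, res$mean)
  }
  structure(list(accuracy = best$mean, per_fold = best$per_fold,
                 confusion = best$confusion,
                 best_cost = best$cost, best_gamma = best$gamma,
                 permutation_baseline = pbest,
                 folds = config$folds, seed = config$seed,
                 multiclass = "one-vs-one"),
            class = "classification_report")
}
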