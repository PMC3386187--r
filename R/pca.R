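# Correlation-matrix PCA of texture feature matrices, contribution-rate
# component selection, sign-oriented first-component discrimination, and
# the stage-monotonicity statistic.

#' Standardize a texture feature matrix
#'
#' Centers and scales every column to mean 0 and sample (n-1) sd 1.
#' Constant columns cannot be standardized; they are dropped with a
#' warning naming the feature and recorded in the result.
#'
#' @param features numeric matrix or data.frame of feature columns.
#' @return list with `x` (standardized matrix), `center`, `scale`,
#'   `dropped` (names of constant columns).
#' @export
standardize_features <- function(features) {
  x <- as.matrix(features)
  if (!is.numeric(x) || nrow(x) < 2L)
    stop_config("`features` must be a numeric matrix with >= 2 rows")
  if (anyNA(x) || any(!is.finite(x)))
    stop_config("`features` contains missing or non-finite values")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  const <- scl == 0
  if (all(const))
    stop_config("all feature columns are constant; nothing to standardize")
  if (any(const)) {
    warning(sprintf("dropping constant feature column(s): %s",
                    paste(colnames(x)[const], collapse = ", ")),
            call. = FALSE)
  }
  x <- x[, !const, drop = FALSE]
  ctr <- ctr[!const]; scl <- scl[!const]
  list(x = sweep(sweep(x, 2L, ctr), 2L, scl, `/`),
       center = ctr, scale = scl,
       dropped = colnames(features)[const] %||% character(0))
}

#' Fit a correlation-matrix PCA
#'
#' Eigendecomposition of the sample correlation matrix of the standardized
#' features. Eigenvalues are returned in descending order (tiny negative
#' values from rounding are clipped at zero) together with the
#' contribution rates `CR_i = lambda_i / sum(lambda)`.
#'
#' @param std a [standardize_features()] result (or a standardized matrix).
#' @return a `pca_model` with `eigenvalues`, `vectors` (columns, unit
#'   norm), `cr`, `flips` (sign-orientation record, initially all `1`),
#'   and the standardization parameters.
#' @export
pca_fit <- function(std) {
  if (is.matrix(std)) std <- list(x = std, center = NULL, scale = NULL,
                                  dropped = character(0))
  x <- std$x
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_config("need >= 2 rows and >= 2 surviving columns for PCA")
  if (any(!is.finite(x))) stop_config("non-finite values in input")
  R <- stats::cor(x)
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  structure(list(eigenvalues = ev,
                 vectors = eg$vectors,
                 cr = ev / sum(ev),
                 flips = rep(1, length(ev)),
                 feature_names = colnames(x),
                 center = std$center, scale = std$scale,
                 dropped = std$dropped),
            class = "pca_model")
}

#' Component scores of standardized rows
#'
#' `F_i = x . e_i` per row, using the model's (possibly sign-oriented)
#' eigenvectors; the sample variance of `F_i` equals `lambda_i`.
#'
#' @param model a [pca_fit()] model.
#' @param std standardized matrix or [standardize_features()] result.
#' @return numeric matrix of scores (columns `F1`, `F2`, ...).
#' @export
pca_scores <- function(model, std) {
  stopifnot(inherits(model, "pca_model"))
  x <- if (is.list(std)) std$x else std
  if (ncol(x) != nrow(model$vectors))
    stop_config("score input has %d columns but the model was fitted on %d",
                ncol(x), nrow(model$vectors))
  s <- x %*% sweep(model$vectors, 2L, model$flips, `*`)
  colnames(s) <- paste0("F", seq_len(ncol(s)))
  s
}

#' Orient eigenvector signs against a reference group
#'
#' Eigenvector signs are mathematically arbitrary; the sign rule of the
#' first-component discriminant ("positive means normal") is only
#' well-defined after orientation. Each component is flipped, if needed, so
#' that the mean score of the reference group is non-negative. Without
#' labels the fallback orients each component so its largest-magnitude
#' loading is positive.
#'
#' @param model a [pca_fit()] model.
#' @param std standardized matrix the model was fitted on.
#' @param labels character vector of per-row region labels (or `NULL` for
#'   the unsupervised fallback).
#' @param reference_label the reference group (default `"normal"`).
#' @return the model with updated `flips`.
#' @export
orient_signs <- function(model, std, labels = NULL,
                         reference_label = "normal") {
  stopifnot(inherits(model, "pca_model"))
  x <- if (is.list(std)) std$x else std
  flips <- rep(1, ncol(model$vectors))
  if (is.null(labels)) {
    for (i in seq_len(ncol(model$vectors))) {
      v <- model$vectors[, i]
      if (v[which.max(abs(v))] < 0) flips[i] <- -1
    }
  } else {
    if (!reference_label %in% labels)
      stop_config("reference group '%s' is absent from `labels`",
                  reference_label)
    raw <- x %*% model$vectors
    ref <- labels == reference_label
    for (i in seq_len(ncol(raw))) {
      if (mean(raw[ref, i]) < 0) flips[i] <- -1
    }
  }
  model$flips <- flips
  model
}

#' Select principal components by cumulative contribution rate
#'
#' The smallest leading set of components whose cumulative contribution
#' rate reaches the threshold ("components with the CR up to 80%"); when
#' `CR_1` already exceeds the threshold this is just the first component.
#'
#' @param model a [pca_fit()] model.
#' @param threshold cumulative contribution-rate threshold (default 0.80).
#' @return integer vector of selected component indices `1..k`.
#' @export
select_components <- function(model, threshold = 0.80) {
  stopifnot(inherits(model, "pca_model"))
  k <- which(cumsum(model$cr) >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(model$cr)
  seq_len(k)
}

#' First-component sign discrimination of normal vs tumor ROIs
#'
#' Predicts `normal` where the oriented first-component score `F1 > 0`
#' and `tumor` where `F1 < 0`; the tie `F1 = 0` is assigned to `normal`
#' (documented convention). Reports per-group mean and sd of `F1`, the
#' contribution rate of `F1`, per-ROI predictions, and agreement with the
#' true labels.
#'
#' @param scores score matrix from [pca_scores()] (oriented).
#' @param labels true region labels per row.
#' @param cr1 contribution rate of the first component (for the report).
#' @return a `discriminant_report` list.
#' @export
sign_discriminate <- function(scores, labels, cr1 = NA_real_) {
  f1 <- scores[, 1]
  predicted <- ifelse(f1 >= 0, "normal", "tumor")
  groups <- sort(unique(labels))
  gs <- lapply(groups, function(g) {
    v <- f1[labels == g]
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  names(gs) <- groups
  structure(list(group_stats = gs, cr1 = cr1,
                 predicted = predicted,
                 agreement = mean(predicted == labels)),
            class = "discriminant_report")
}

#' Per-stage GLCM texture discriminant
#'
#' Runs, for every stage present: standardization of that stage's 9-feature
#' ROI matrix, correlation PCA, sign orientation against the normal group,
#' the contribution-rate rule, and the F1 sign discriminant.
#'
#' @param features data.frame from [texture_features()] with `stage` and
#'   `region_label` columns.
#' @param threshold contribution-rate threshold (default 0.80).
#' @return named list (per stage) of `discriminant_report`s, each with the
#'   selected components attached.
#' @export
glcm_discriminant <- function(features, threshold = 0.80) {
  stopifnot(all(c("stage", "region_label") %in% names(features)))
  stages <- unique(features$stage)
  out <- lapply(stages, function(sg) {
    sub <- features[features$stage == sg, , drop = FALSE]
    std <- standardize_features(sub[, glcm_feature_names(), drop = FALSE])
    model <- pca_fit(std)
    model <- orient_signs(model, std, labels = sub$region_label)
    sc <- pca_scores(model, std)
    rep <- sign_discriminate(sc, sub$region_label, cr1 = model$cr[1])
    rep$selected_components <- select_components(model, threshold)
    rep
  })
  names(out) <- stages
  out
}

#' Spearman stage-monotonicity of per-stage means
#'
#' Rank correlation between the stage index and the per-stage means; the
#' statistic is 1 exactly when the means increase strictly with stage.
#' Ties among means are handled by midranks and flagged.
#'
#' @param stage_means numeric vector of per-stage means, ordered by stage
#'   (at least 3 stages).
#' @return list with `rho` and `ties` (logical).
#' @export
stage_monotonicity <- function(stage_means) {
  if (length(stage_means) < 3L)
    stop_config("need >= 3 stages, got %d", length(stage_means))
  ties <- anyDuplicated(stage_means) > 0
  rho <- stats::cor(seq_along(stage_means), stage_means, method = "spearman")
  list(rho = rho, ties = ties)
}

#' Stage trend of low-frequency subband texture
#'
#' Pools the tumor-ROI texture vectors of one subband across stages,
#' standardizes, fits the correlation PCA, orients the first component as a
#' coarsening axis (loading on the inverse difference moment non-negative:
#' local homogeneity grows as necrosis coarsens the low-frequency texture),
#' and returns the per-stage mean scores and their stage monotonicity.
#'
#' @param dt_features data.frame from [subband_texture_features()].
#' @param subband which subband to analyze (default `"LF1"`).
#' @param stages stage ordering (default the four tumor stages).
#' @return list with `stage_means`, `rho`, `ties`, `cr1`, `model`.
#' @export
lf_stage_trend <- function(dt_features, subband = "LF1",
                           stages = tumor_stages()) {
  sub <- dt_features[dt_features$subband == subband &
                       dt_features$region_label == "tumor", , drop = FALSE]
  if (!nrow(sub)) stop_config("no tumor rows for subband '%s'", subband)
  std <- standardize_features(sub[, glcm_feature_names(), drop = FALSE])
  model <- pca_fit(std)
  # orient F1 so the idm loading is non-negative (coarsening axis)
  ei <- match("idm", model$feature_names)
  if (!is.na(ei) && model$vectors[ei, 1] < 0) model$flips[1] <- -1
  sc <- pca_scores(model, std)
  stages <- stages[stages %in% sub$stage]
  means <- vapply(stages, function(sg) mean(sc[sub$stage == sg, 1]),
                  numeric(1))
  mono <- stage_monotonicity(means)
  list(stage_means = means, rho = mono$rho, ties = mono$ties,
       cr1 = model$cr[1], model = model)
}
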