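# Classification methods: nearest centroid (authored here), kNN (class::knn)
# and linear SVM (e1071::svm), with SNR-magnitude feature ranking and
# cross-validated selection of the feature-set size by mean CV MCC.

#' Classifier configuration
#'
#' @param method One of `"ncentroid"`, `"knn"`, `"svm"`.
#' @param feature_grid Candidate feature-set sizes for cross-validated
#'   selection; entries are capped at the number of genes at fit time.
#' @param folds Cross-validation folds (default 5, stratified by class; folds
#'   shrink to the minority-class count with a warning when it is smaller).
#' @param k_neighbors Neighbours for kNN (default 3).
#' @param cost Soft-margin cost for the linear SVM (default 1).
#' @param sd_floor Passed to the SNR ranking.
#' @param seed Seed controlling fold assignment.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(method = c("ncentroid", "knn", "svm"),
                              feature_grid = c(5, 10, 25, 50, 100),
                              folds = 5,
                              k_neighbors = 3,
                              cost = 1,
                              sd_floor = 1e-8,
                              seed = 1) {
  method <- match.arg(method)
  folds <- check_count(folds, "folds", min = 2L)
  k_neighbors <- check_count(k_neighbors, "k_neighbors", min = 1L)
  feature_grid <- sort(unique(as.integer(feature_grid)))
  if (length(feature_grid) < 1L || any(feature_grid < 1L)) {
    stop_ssnr("feature_grid entries must be integers >= 1",
              class = "ssnr_validation_error")
  }
  structure(list(method = method, feature_grid = feature_grid, folds = folds,
                 k_neighbors = k_neighbors, cost = cost, sd_floor = sd_floor,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Rank genes by SNR magnitude
#'
#' Genes sorted by decreasing absolute SNR; ties broken by gene id
#' (lexicographic) for determinism.
#'
#' @param train A [labeled_dataset()].
#' @param sd_floor Passed to [snr_vector()].
#' @return Character vector of gene ids, strongest first.
#' @export
rank_genes_by_snr <- function(train, sd_floor = 1e-8) {
  a <- snr_vector(class_summaries(train), sd_floor = sd_floor)
  ids <- names(a)
  ids[order(-abs(a), ids, method = "radix")]
}

#' Train a classifier on selected features
#'
#' Fits one of the three supported methods on the given gene panel.
#' Nearest centroid stores the per-class mean vectors; kNN stores the
#' training subset (Euclidean distance, majority vote); the SVM fits a
#' soft-margin linear separator.
#'
#' @param train A [labeled_dataset()] with both classes present.
#' @param features Non-empty character vector of gene ids to use, in rank
#'   order.
#' @param config A [classifier_config()] (or a method name, with defaults).
#' @return An object of class `ssnr_model` with elements `method`,
#'   `features`, `levels` (class labels, class 1 first) and the fitted state.
#' @export
train_classifier <- function(train, features, config = classifier_config()) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (is.character(config)) config <- classifier_config(method = config)
  if (length(features) < 1L) {
    stop_ssnr("'features' must name at least one gene",
              class = "ssnr_validation_error")
  }
  missing <- setdiff(features, gene_ids(train))
  if (length(missing)) {
    stop_ssnr("feature(s) absent from training data: %s",
              paste(missing, collapse = ", "), class = "ssnr_validation_error")
  }
  y <- droplevels(train$labels)
  if (nlevels(y) < 2L) {
    stop_ssnr("training data contains a single class",
              class = "ssnr_single_class_error")
  }
  m <- expr_matrix(train)[features, , drop = FALSE]
  lv <- levels(train$labels)
  fit <- switch(config$method,
    ncentroid = {
      i1 <- train$labels == lv[1L]
      list(centroid1 = rowMeans(m[, i1, drop = FALSE]),
           centroid2 = rowMeans(m[, !i1, drop = FALSE]))
    },
    knn = list(x = t(m), y = train$labels, k = config$k_neighbors),
    svm = e1071::svm(x = t(m), y = train$labels, kernel = "linear",
                     cost = config$cost, scale = FALSE)
  )
  structure(list(method = config$method, features = features,
                 levels = lv, fit = fit, config = config),
            class = "ssnr_model")
}

#' @export
print.ssnr_model <- function(x, ...) {
  cat(sprintf("%s classifier on %d feature(s); classes %s (positive) vs %s\n",
              x$method, length(x$features), x$levels[1L], x$levels[2L]))
  if (!is.null(x$cv_score)) {
    cat(sprintf("  cross-validated MCC = %.4f (selected %d features from grid %s)\n",
                x$cv_score, length(x$features),
                paste(x$config$feature_grid, collapse = "/")))
  }
  invisible(x)
}

#' Predict class labels
#'
#' Nearest centroid assigns the class of the nearer centroid (Euclidean
#' distance; ties go to class 1 for determinism).  kNN takes the majority
#' vote of the `k` nearest training samples.  The SVM applies its linear
#' decision rule.
#'
#' @param object An `ssnr_model`.
#' @param newdata An [expression_dataset()], [labeled_dataset()] or a
#'   genes x samples matrix containing all of the model's features.
#' @param ... Unused.
#' @return Factor of predicted labels (levels as in training, class 1 first).
#' @export
predict.ssnr_model <- function(object, newdata, ...) {
  m <- expr_matrix(newdata)
  missing <- setdiff(object$features, rownames(m))
  if (length(missing)) {
    stop_ssnr("feature(s) absent from new data: %s",
              paste(missing, collapse = ", "), class = "ssnr_validation_error")
  }
  m <- m[object$features, , drop = FALSE]
  out <- switch(object$method,
    ncentroid = {
      d1 <- colSums((m - object$fit$centroid1)^2)
      d2 <- colSums((m - object$fit$centroid2)^2)
      ifelse(d1 <= d2, object$levels[1L], object$levels[2L])
    },
    knn = as.character(class::knn(train = object$fit$x, test = t(m),
                                  cl = object$fit$y, k = object$fit$k)),
    svm = as.character(stats::predict(object$fit, newdata = t(m)))
  )
  factor(out, levels = object$levels)
}

# Stratified fold assignment: within each class, shuffle and deal round-robin.
# Returns an integer fold id per sample.
make_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated feature-count selection
#'
#' For each candidate feature count: stratified k-fold cross-validation in
#' which the SNR ranking is recomputed on the fold-training portion only (no
#' selection leak), the fold model predicts its held-out portion, and the
#' fold MCCs are averaged.  The count with the highest mean CV MCC wins (ties
#' go to the smaller count); the final model is refit on all training samples
#' with the winning count.
#'
#' @param train A [labeled_dataset()].
#' @param config A [classifier_config()].
#' @return An `ssnr_model` with additional elements `cv_score` (winning mean
#'   CV MCC), `cv_table` (mean CV MCC per candidate count) — the "best
#'   classifier" for this training set.
#' @export
cross_validate_select <- function(train, config = classifier_config()) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(config, "classifier_config"))
  cc <- class_counts(train)
  if (min(cc) < 2L) {
    stop_ssnr("cannot cross-validate: minority class has %d sample(s)", min(cc),
              class = "ssnr_class_size_error")
  }
  folds <- config$folds
  if (min(cc) < folds) {
    folds <- min(cc)
    warning(sprintf("reducing folds from %d to %d (minority class size)",
                    config$folds, folds), call. = FALSE)
  }
  grid <- unique(pmin(config$feature_grid, nrow(expr_matrix(train))))
  fold_id <- make_folds(train$labels, folds, config$seed)

  fold_mcc <- matrix(NA_real_, nrow = folds, ncol = length(grid))
  for (f in seq_len(folds)) {
    tr <- subset_samples(train, which(fold_id != f))
    held <- which(fold_id == f)
    ranked <- rank_genes_by_snr(tr, sd_floor = config$sd_floor)
    truth <- train$labels[held]
    hm <- expr_matrix(train)[, held, drop = FALSE]
    for (j in seq_along(grid)) {
      model <- train_classifier(tr, ranked[seq_len(grid[j])], config)
      pred <- predict(model, hm)
      fold_mcc[f, j] <- mcc(confusion_counts(truth, pred))
    }
  }
  mean_cv <- colMeans(fold_mcc)
  best <- grid[which.max(mean_cv)]  # which.max takes the first (smallest) tie

  ranked_full <- rank_genes_by_snr(train, sd_floor = config$sd_floor)
  model <- train_classifier(train, ranked_full[seq_len(best)], config)
  model$cv_score <- max(mean_cv)
  model$cv_table <- data.frame(n_features = grid, mean_cv_mcc = mean_cv)
  model$folds_used <- folds
  model
}
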