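#' Expression dataset container
#'
#' Holds a real-valued log-scale expression matrix oriented genes x samples.
#' Row names are gene identifiers, column names sample identifiers; both must
#' be unique.  The `log_scale` flag records whether values are on a log scale,
#' which downstream SNR computations require.
#'
#' @param x Numeric matrix, genes in rows and samples in columns, with unique
#'   row and column names.
#' @param log_scale Logical; are the values on a log (e.g. log2) scale?
#' @return An object of class `expr_dataset`: a list with elements `x`
#'   (the matrix) and `log_scale`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' expression_dataset(m, log_scale = TRUE)
#' @export
expression_dataset <- function(x, log_scale = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_ssnr("expression data must be a numeric matrix",
              class = "ssnr_validation_error")
  }
  if (nrow(x) < 1L || ncol(x) < 2L) {
    stop_ssnr("expression matrix needs >= 1 gene and >= 2 samples (got %d x %d)",
              nrow(x), ncol(x), class = "ssnr_validation_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_ssnr("expression matrix must carry gene (row) and sample (column) names",
              class = "ssnr_validation_error")
  }
  if (anyDuplicated(rownames(x))) {
    stop_ssnr("duplicate gene ids: %s",
              paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
              class = "ssnr_validation_error")
  }
  if (anyDuplicated(colnames(x))) {
    stop_ssnr("duplicate sample ids: %s",
              paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
              class = "ssnr_validation_error")
  }
  if (anyNA(x)) {
    stop_ssnr("expression matrix contains missing values; impute or drop first",
              class = "ssnr_validation_error")
  }
  structure(list(x = x, log_scale = isTRUE(log_scale)), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d samples (%s scale)\n",
              nrow(x$x), ncol(x$x), if (x$log_scale) "log" else "linear"))
  invisible(x)
}

#' @rdname expression_dataset
#' @param object An `expr_dataset` or `labeled_dataset`.
#' @export
gene_ids <- function(object) UseMethod("gene_ids")
#' @export
gene_ids.expr_dataset <- function(object) rownames(object$x)
#' @export
gene_ids.labeled_dataset <- function(object) rownames(object$dataset$x)

#' @rdname expression_dataset
#' @export
sample_ids <- function(object) UseMethod("sample_ids")
#' @export
sample_ids.expr_dataset <- function(object) colnames(object$x)
#' @export
sample_ids.labeled_dataset <- function(object) colnames(object$dataset$x)

#' @rdname expression_dataset
#' @export
expr_matrix <- function(object) UseMethod("expr_matrix")
#' @export
expr_matrix.expr_dataset <- function(object) object$x
#' @export
expr_matrix.labeled_dataset <- function(object) object$dataset$x
#' @export
expr_matrix.matrix <- function(object) object

#' Labelled two-class expression dataset
#'
#' Couples an [expression_dataset()] with a per-sample binary endpoint.
#' Class 1 is the positive class (first factor level); both classes must be
#' present.  Optional per-sample categorical covariates (e.g. gender) support
#' positive-control construction.
#'
#' @param dataset An `expr_dataset`.
#' @param labels Factor (or vector coercible to factor) of length `n` with
#'   exactly two levels; the first level is treated as class 1 (positive).
#' @param covariates Optional data.frame of per-sample categorical covariates,
#'   rows aligned with the dataset's samples.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(dataset, labels, covariates = NULL) {
  if (!inherits(dataset, "expr_dataset")) {
    stop_ssnr("'dataset' must be an expr_dataset", class = "ssnr_validation_error")
  }
  n <- ncol(dataset$x)
  if (length(labels) != n) {
    stop_ssnr("labels length (%d) does not match sample count (%d)",
              length(labels), n, class = "ssnr_validation_error")
  }
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(labels) != 2L) {
    stop_ssnr("labels must contain exactly two classes (got %d: %s)",
              nlevels(labels), paste(levels(labels), collapse = ", "),
              class = "ssnr_single_class_error")
  }
  if (anyNA(labels)) {
    stop_ssnr("labels contain missing values", class = "ssnr_validation_error")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop_ssnr("covariates have %d rows but dataset has %d samples",
                nrow(covariates), n, class = "ssnr_validation_error")
    }
    rownames(covariates) <- colnames(dataset$x)
  }
  structure(list(dataset = dataset, labels = labels, covariates = covariates),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("Labelled expression dataset: %d genes x %d samples\n",
              nrow(x$dataset$x), ncol(x$dataset$x)))
  cat(sprintf("  classes: %s = %d (class 1), %s = %d (class 2); prevalence %.3f\n",
              names(cc)[1], cc[1], names(cc)[2], cc[2], cc[1] / sum(cc)))
  if (!is.null(x$covariates)) {
    cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  }
  invisible(x)
}

#' Per-class sample counts
#'
#' @param data A `labeled_dataset`.
#' @return Named integer vector (class 1 first).
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  tab <- table(data$labels)
  structure(as.integer(tab), names = names(tab))
}

#' Subset a labelled dataset by sample
#'
#' @param data A `labeled_dataset`.
#' @param samples Sample ids or indices to keep.
#' @return A `labeled_dataset` restricted to those samples (labels and
#'   covariates subset in step; factor levels preserved).
#' @export
subset_samples <- function(data, samples) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.character(samples)) {
    idx <- match(samples, sample_ids(data))
    if (anyNA(idx)) {
      stop_ssnr("unknown sample ids: %s",
                paste(samples[is.na(idx)], collapse = ", "),
                class = "ssnr_validation_error")
    }
  } else {
    idx <- samples
  }
  ds <- expression_dataset(data$dataset$x[, idx, drop = FALSE],
                           log_scale = data$dataset$log_scale)
  cov <- if (is.null(data$covariates)) NULL else data$covariates[idx, , drop = FALSE]
  labs <- data$labels[idx]
  if (nlevels(droplevels(labs)) < 2L) {
    stop_ssnr("subset would leave a single class", class = "ssnr_single_class_error")
  }
  structure(list(dataset = ds, labels = labs, covariates = cov),
            class = "labeled_dataset")
}

#' Training/validation split pair
#'
#' Bundles two labelled datasets whose samples are disjoint and whose gene
#' panels are identical and identically ordered, mirroring the independent
#' training and validation populations of external-validation study designs.
#'
#' @param training,validation `labeled_dataset` objects.
#' @return An object of class `split_pair`.
#' @export
split_pair <- function(training, validation) {
  stopifnot(inherits(training, "labeled_dataset"),
            inherits(validation, "labeled_dataset"))
  if (!identical(gene_ids(training), gene_ids(validation))) {
    stop_ssnr("training and validation gene panels differ or are ordered differently",
              class = "ssnr_validation_error")
  }
  common <- intersect(sample_ids(training), sample_ids(validation))
  if (length(common) > 0L) {
    stop_ssnr("training and validation share samples: %s",
              paste(utils::head(common, 5L), collapse = ", "),
              class = "ssnr_validation_error")
  }
  structure(list(training = training, validation = validation),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("Split pair: %d training / %d validation samples, %d genes\n",
              ncol(x$training$dataset$x), ncol(x$validation$dataset$x),
              nrow(x$training$dataset$x)))
  invisible(x)
}
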