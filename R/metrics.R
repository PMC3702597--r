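# Core statistics: per-gene signal-to-noise ratio (SNR), its scale (SSNR),
# confusion counts, the Matthews correlation coefficient, and Pearson r.

#' Per-gene class means and standard deviations
#'
#' For each gene, the mean and sample SD (n - 1 denominator) of the log
#' expression within class 1 and class 2.  These are the ingredients of the
#' Golub-style SNR.
#'
#' @param data A [labeled_dataset()] on a log scale with >= 2 samples per
#'   class.
#' @return An object of class `class_summary`: list with numeric vectors
#'   `mu1`, `mu2`, `sd1`, `sd2` (named by gene) and the per-class counts
#'   `n1`, `n2`.
#' @export
class_summaries <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!data$dataset$log_scale) {
    stop_ssnr("SNR statistics require log-scale expression; load with log_transform = 'log2_with_offset' or declare log_scale = TRUE",
              class = "ssnr_validation_error")
  }
  cc <- class_counts(data)
  if (any(cc < 2L)) {
    stop_ssnr("each class needs >= 2 samples to estimate an SD (got %s)",
              paste(sprintf("%s = %d", names(cc), cc), collapse = ", "),
              class = "ssnr_class_size_error")
  }
  m <- expr_matrix(data)
  i1 <- data$labels == levels(data$labels)[1L]
  s1 <- row_mean_sd(m[, i1, drop = FALSE])
  s2 <- row_mean_sd(m[, !i1, drop = FALSE])
  structure(list(mu1 = s1$mean, mu2 = s2$mean, sd1 = s1$sd, sd2 = s2$sd,
                 n1 = cc[[1L]], n2 = cc[[2L]]),
            class = "class_summary")
}

#' Per-gene signal-to-noise ratio
#'
#' For gene i, `a_i = (mu1_i - mu2_i) / (sd1_i + sd2_i)`: the class-mean
#' difference of log expression relative to the summed within-class SDs.
#' Positive values mark genes more highly expressed in class 1, negative in
#' class 2; `a_i` is not confined to \[-1, 1\].
#'
#' @param summary A `class_summary` from [class_summaries()].
#' @param sd_floor Lower bound applied to `sd1 + sd2` so zero-variance genes
#'   yield finite values (default `1e-8`).
#' @param zero_sd `"floor"` (default) to apply `sd_floor`, or `"drop"` to
#'   remove genes with `sd1 + sd2 < sd_floor` from the result.
#' @return Named numeric vector of SNR values, one per gene.
#' @export
snr_vector <- function(summary, sd_floor = 1e-8, zero_sd = c("floor", "drop")) {
  stopifnot(inherits(summary, "class_summary"))
  zero_sd <- match.arg(zero_sd)
  if (!is.numeric(sd_floor) || sd_floor <= 0) {
    stop_ssnr("'sd_floor' must be a small positive number",
              class = "ssnr_validation_error")
  }
  denom <- summary$sd1 + summary$sd2
  if (zero_sd == "drop") {
    keep <- denom >= sd_floor
    a <- (summary$mu1[keep] - summary$mu2[keep]) / denom[keep]
  } else {
    a <- (summary$mu1 - summary$mu2) / pmax(denom, sd_floor)
  }
  a
}

#' Scale of a signal-to-noise-ratio vector (SSNR)
#'
#' The range `max(a) - min(a)` of the per-gene SNR vector: the numeric
#' difference between the largest positive and the smallest negative SNR.
#' SSNR is always >= 0 and is the package's index of endpoint predictability.
#'
#' @param a Numeric SNR vector (or an [snr_profile()] object).
#' @param ... Unused.
#' @return A single non-negative number.
#' @export
ssnr <- function(a, ...) UseMethod("ssnr")

#' @export
ssnr.default <- function(a, ...) {
  if (length(a) < 1L || !is.numeric(a)) {
    stop_ssnr("SSNR needs a non-empty numeric SNR vector",
              class = "ssnr_validation_error")
  }
  if (anyNA(a) || any(!is.finite(a))) {
    stop_ssnr("SNR vector contains non-finite values",
              class = "ssnr_validation_error")
  }
  max(a) - min(a)
}

#' @export
ssnr.snr_profile <- function(a, ...) a$ssnr

#' SNR profile of a labelled dataset
#'
#' Convenience wrapper: class summaries, per-gene SNR vector and its SSNR in
#' one classed object.
#'
#' @inheritParams class_summaries
#' @inheritParams snr_vector
#' @return An object of class `snr_profile`: list with `a` (named SNR
#'   vector), `ssnr`, `sd_floor`, and per-class counts.
#' @examples
#' d <- generate_dataset(n_samples = 40, p_genes = 50, m_informative = 5,
#'                       delta = 2, sigma = 0.5, seed = 1)$data
#' snr_profile(d)
#' @export
snr_profile <- function(data, sd_floor = 1e-8, zero_sd = c("floor", "drop")) {
  cs <- class_summaries(data)
  a <- snr_vector(cs, sd_floor = sd_floor, zero_sd = zero_sd)
  structure(list(a = a, ssnr = ssnr(a), sd_floor = sd_floor,
                 n1 = cs$n1, n2 = cs$n2),
            class = "snr_profile")
}

#' @export
print.snr_profile <- function(x, ...) {
  cat(sprintf("SNR profile over %d genes (class sizes %d / %d)\n",
              length(x$a), x$n1, x$n2))
  cat(sprintf("  SSNR = %.4f (max %.4f, min %.4f)\n",
              x$ssnr, max(x$a), min(x$a)))
  if (length(x$a) == 1L) {
    cat("  note: single-gene profile, SSNR is 0 by construction\n")
  }
  invisible(x)
}

#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives, with class 1 (the first level
#' of `truth`) as the positive class.
#'
#' @param truth Factor (or vector) of true labels; its first level (or the
#'   `positive` argument) defines the positive class.
#' @param predicted Vector of predicted labels on the same label set.
#' @param positive Positive-class label; defaults to the first level of
#'   `truth`.
#' @return An object of class `confusion_matrix`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = NULL) {
  if (length(truth) != length(predicted)) {
    stop_ssnr("truth (%d) and predicted (%d) lengths differ",
              length(truth), length(predicted), class = "ssnr_validation_error")
  }
  truth <- if (is.factor(truth)) truth else factor(truth)
  positive <- positive %||% levels(truth)[1L]
  tp <- truth == positive
  pp <- predicted == positive
  structure(list(TP = sum(tp & pp), TN = sum(!tp & !pp),
                 FP = sum(!tp & pp), FN = sum(tp & !pp)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' chance-corrected binary classification metric in \[-1, +1\] with 0
#' corresponding to random prediction.  When any marginal factor under the
#' radical is zero the value is defined as 0 (the standard convention for a
#' degenerate margin).
#'
#' @param x A `confusion_matrix`, or a truth vector (with `predicted` given).
#' @param ... Passed to methods.
#' @return A single number in \[-1, 1\].
#' @examples
#' mcc(confusion_counts(c(1, 1, 2, 2), c(1, 1, 2, 2)))
#' @export
mcc <- function(x, ...) UseMethod("mcc")

#' @rdname mcc
#' @export
mcc.confusion_matrix <- function(x, ...) {
  tp <- as.numeric(x$TP); tn <- as.numeric(x$TN)
  fp <- as.numeric(x$FP); fn <- as.numeric(x$FN)
  total <- tp + tn + fp + fn
  if (total == 0) {
    stop_ssnr("MCC undefined for an empty confusion matrix",
              class = "ssnr_validation_error")
  }
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' @rdname mcc
#' @param predicted Predicted labels (default method only).
#' @param positive Positive-class label (default method only).
#' @export
mcc.default <- function(x, predicted, positive = NULL, ...) {
  mcc(confusion_counts(x, predicted, positive = positive))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the validation this package's
#' reporting needs (used for the SSNR-versus-MCC association).
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop_ssnr("x and y lengths differ", class = "ssnr_validation_error")
  }
  if (length(x) < 3L) {
    stop_ssnr("need >= 3 paired observations for a correlation",
              class = "ssnr_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ssnr("correlation undefined: zero variance in x or y",
              class = "ssnr_degenerate_error")
  }
  stats::cor(x, y, method = "pearson")
}
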