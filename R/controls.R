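# Positive and negative control endpoints: internal-validation endpoints
# derived from an existing dataset, in the spirit of relabelling by a
# strongly expression-linked covariate (positive) or at random (negative).

#' Positive-control endpoint from a covariate
#'
#' Replaces the endpoint labels with the levels of an existing two-level
#' covariate (e.g. gender), leaving expression untouched.  A covariate with
#' a strong transcriptional signature should be highly predictable, bounding
#' what the data can support.
#'
#' @param data A [labeled_dataset()] carrying the covariate.
#' @param covariate_name Name of a two-level covariate; each level must have
#'   >= 2 samples.  The first factor level becomes class 1.
#' @return A [labeled_dataset()] with the covariate as endpoint.
#' @export
positive_control <- function(data, covariate_name) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.null(data$covariates) || !covariate_name %in% names(data$covariates)) {
    stop_ssnr("covariate '%s' not present (available: %s)", covariate_name,
              if (is.null(data$covariates)) "none"
              else paste(names(data$covariates), collapse = ", "),
              class = "ssnr_validation_error")
  }
  cov <- droplevels(factor(data$covariates[[covariate_name]]))
  if (nlevels(cov) != 2L) {
    stop_ssnr("positive control needs a two-level covariate; '%s' has %d level(s)",
              covariate_name, nlevels(cov), class = "ssnr_validation_error")
  }
  if (any(table(cov) < 2L)) {
    stop_ssnr("each level of '%s' needs >= 2 samples", covariate_name,
              class = "ssnr_class_size_error")
  }
  labeled_dataset(data$dataset, cov, covariates = data$covariates)
}

#' Negative-control endpoint by random relabelling
#'
#' Assigns exactly `round(n * prevalence)` samples to class 1 by a seeded
#' draw, leaving expression untouched.  Any downstream learning curve on a
#' negative control should stay flat near MCC 0 at every training size; this
#' guards the analysis against false positives.  Exact-count assignment
#' (rather than i.i.d. coin flips) keeps the prevalence controlled in small
#' pools.
#'
#' @param data A [labeled_dataset()].
#' @param prevalence Class-1 fraction in (0, 1), default 0.5.
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with random labels (levels
#'   `"class1"`, `"class2"`).
#' @export
negative_control <- function(data, prevalence = 0.5, seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  prevalence <- check_fraction(prevalence, "prevalence")
  n <- length(data$labels)
  n1 <- round(n * prevalence)
  if (n1 < 2L || n - n1 < 2L) {
    stop_ssnr("prevalence %.3f gives class sizes %d / %d; need >= 2 each",
              prevalence, n1, n - n1, class = "ssnr_class_size_error")
  }
  idx <- with_seed(seed, sample(n, n1))
  lab <- factor(ifelse(seq_len(n) %in% idx, "class1", "class2"),
                levels = c("class1", "class2"))
  labeled_dataset(data$dataset, lab, covariates = data$covariates)
}
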