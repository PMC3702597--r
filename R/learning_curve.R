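# Repeated-subsampling learning curves: external-validation MCC distributions
# over a grid of training sizes, 5-95% whisker summaries, the per-step
# marginal-value index nu, and near-optimal size determination.

#' Learning-curve configuration
#'
#' @param size_start First training size on the grid (default 20).
#' @param size_step Grid step (default 20).
#' @param size_max Largest size considered; capped at the training-pool size.
#' @param repetitions Subsampling replicates per size (default 100).
#' @param epsilon Threshold below which the marginal value nu of further
#'   samples is deemed negligible (default 0.05; "much smaller than 1").
#' @param seed Base seed; replicate r uses seed + r.
#' @param stratified Draw subsamples preserving the pool's class prevalence
#'   (default `TRUE`).
#' @return An object of class `curve_config`.
#' @export
curve_config <- function(size_start = 20, size_step = 20, size_max,
                         repetitions = 100, epsilon = 0.05, seed = 1,
                         stratified = TRUE) {
  size_start <- check_count(size_start, "size_start", min = 4L)
  size_step <- check_count(size_step, "size_step", min = 1L)
  size_max <- check_count(size_max, "size_max", min = size_start)
  repetitions <- check_count(repetitions, "repetitions", min = 1L)
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1) {
    stop_ssnr("'epsilon' must lie in (0, 1)", class = "ssnr_validation_error")
  }
  structure(list(size_start = size_start, size_step = size_step,
                 size_max = size_max, repetitions = repetitions,
                 epsilon = epsilon, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "curve_config")
}

#' Draw a training subsample from a pool
#'
#' Without-replacement draw of `n` samples.  In stratified mode the class
#' counts follow the pool prevalence by largest-remainder rounding and each
#' class must receive >= 2 samples.  Deterministic given `seed`.
#'
#' @param pool A [labeled_dataset()].
#' @param n Subsample size (>= 4, <= pool size).
#' @param seed Integer seed.
#' @param stratified Logical (default `TRUE`).
#' @return A [labeled_dataset()] of `n` samples.
#' @export
subsample <- function(pool, n, seed, stratified = TRUE) {
  stopifnot(inherits(pool, "labeled_dataset"))
  n <- check_count(n, "n", min = 4L)
  total <- length(pool$labels)
  if (n > total) {
    stop_ssnr("requested %d samples from a pool of %d", n, total,
              class = "ssnr_validation_error")
  }
  if (stratified) {
    cc <- class_counts(pool)
    quota <- n * cc / total
    take <- floor(quota)
    rem <- n - sum(take)
    if (rem > 0) {
      # largest fractional remainder first; ties to class 1
      ord <- order(-(quota - take), seq_along(quota))
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
    }
    if (any(take < 2L)) {
      stop_ssnr("stratified draw of %d would give class '%s' %d sample(s); use stratified = FALSE or a larger n",
                n, names(cc)[which.min(take)], min(take),
                class = "ssnr_class_size_error")
    }
    idx <- with_seed(seed, {
      unlist(lapply(seq_along(cc), function(k) {
        sample(which(pool$labels == names(cc)[k]), take[k])
      }), use.names = FALSE)
    })
  } else {
    idx <- with_seed(seed, sample(total, n))
  }
  subset_samples(pool, sort(idx))
}

#' Marginal value of a sample-size increase
#'
#' Relative MCC gain per relative increase in training size:
#' `nu = ((mcc_i - mcc_prev) / max(mcc_prev, floor)) / ((n_i - n_prev) / n_prev)`.
#' The previous MCC is floored (default 0.01) so the index stays stable when
#' performance hovers near zero.  This form is isolated here so alternative
#' definitions of the per-step index can be swapped in.
#'
#' @param mcc_i,mcc_prev Mean MCC at the current and previous size.
#' @param n_i,n_prev Current and previous training sizes.
#' @param floor Lower bound on the denominator MCC.
#' @return A single number (0 when performance is unchanged).
#' @export
nu_index <- function(mcc_i, mcc_prev, n_i, n_prev, floor = 0.01) {
  ((mcc_i - mcc_prev) / max(mcc_prev, floor)) / ((n_i - n_prev) / n_prev)
}

#' Evaluate classifier performance at one training size
#'
#' For each replicate: draw a training subsample of size `n` from the pool,
#' select and fit the best classifier by cross-validation, predict the
#' disjoint validation set, and record the MCC.  Summaries (mean, SD, 5th and
#' 95th percentiles by linear interpolation) are computed over the replicate
#' MCCs; every replicate is kept (failures raise, they are never dropped).
#'
#' @param pool Training pool, a [labeled_dataset()].
#' @param validation Disjoint validation set, a [labeled_dataset()] on the
#'   same gene panel.
#' @param n Training size.
#' @param config A [curve_config()].
#' @param classifier_config A [classifier_config()].
#' @return An object of class `size_evaluation`: list with `n_train`,
#'   `mcc_values`, `mean_mcc`, `sd_mcc`, `p5`, `p95`.
#' @export
evaluate_at_size <- function(pool, validation, n, config, classifier_config) {
  split_pair(pool, validation)  # validates disjointness and gene panels
  if (nlevels(droplevels(validation$labels)) < 2L) {
    stop_ssnr("validation set must contain both classes",
              class = "ssnr_single_class_error")
  }
  vals <- vapply(seq_len(config$repetitions), function(r) {
    rs <- derive_seed(config$seed, r)
    sub <- subsample(pool, n, seed = rs, stratified = config$stratified)
    cc <- classifier_config
    cc$seed <- derive_seed(rs, 104729L)  # fold shuffle decoupled from the draw
    model <- cross_validate_select(sub, cc)
    pred <- predict(model, validation$dataset)
    mcc(confusion_counts(validation$labels, pred))
  }, numeric(1L))
  qs <- stats::quantile(vals, c(0.05, 0.95), type = 7, names = FALSE)
  structure(list(n_train = n, mcc_values = vals, mean_mcc = mean(vals),
                 sd_mcc = stats::sd(vals), p5 = qs[1L], p95 = qs[2L]),
            class = "size_evaluation")
}

#' Build a learning curve over a training-size grid
#'
#' Runs [evaluate_at_size()] at `size_start, size_start + size_step, ...`
#' up to `size_max` (capped at the pool size) and computes the nu sequence
#' between consecutive sizes from the mean MCCs.
#'
#' @inheritParams evaluate_at_size
#' @return An object of class `learning_curve`: list with `evaluations`
#'   (per-size `size_evaluation`s, ordered), `nu` (length one fewer),
#'   `method`, `seed`, `config`.
#' @seealso [near_optimal_size()], [plot.learning_curve()]
#' @export
build_learning_curve <- function(pool, validation, config, classifier_config) {
  stopifnot(inherits(config, "curve_config"),
            inherits(classifier_config, "classifier_config"))
  top <- min(config$size_max, length(pool$labels))
  sizes <- seq(config$size_start, top, by = config$size_step)
  if (length(sizes) < 1L) {
    stop_ssnr("empty size grid: start %d exceeds pool size %d",
              config$size_start, top, class = "ssnr_validation_error")
  }
  evals <- lapply(sizes, function(n) {
    evaluate_at_size(pool, validation, n, config, classifier_config)
  })
  means <- vapply(evals, `[[`, numeric(1L), "mean_mcc")
  nu <- if (length(sizes) > 1L) {
    vapply(seq_along(sizes)[-1L], function(i) {
      nu_index(means[i], means[i - 1L], sizes[i], sizes[i - 1L])
    }, numeric(1L))
  } else {
    numeric(0L)
  }
  structure(list(evaluations = evals, nu = nu,
                 method = classifier_config$method,
                 seed = config$seed, config = config),
            class = "learning_curve")
}

#' @export
as.data.frame.learning_curve <- function(x, ...) {
  data.frame(
    n_train = vapply(x$evaluations, `[[`, numeric(1L), "n_train"),
    mean_mcc = vapply(x$evaluations, `[[`, numeric(1L), "mean_mcc"),
    sd_mcc = vapply(x$evaluations, `[[`, numeric(1L), "sd_mcc"),
    p5 = vapply(x$evaluations, `[[`, numeric(1L), "p5"),
    p95 = vapply(x$evaluations, `[[`, numeric(1L), "p95"),
    nu = c(NA_real_, x$nu)
  )
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve (%s, %d replicates per size, seed %d)\n",
              x$method, x$config$repetitions, x$seed))
  print(format(as.data.frame(x), digits = 4))
  invisible(x)
}

#' @export
summary.learning_curve <- function(object, ...) as.data.frame(object)

#' Whisker plot of a learning curve
#'
#' Mean validation MCC against training size with 5-95% percentile whiskers
#' over the subsampling replicates.
#'
#' @param x A `learning_curve`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.learning_curve <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::plot(df$n_train, df$mean_mcc, type = "b", pch = 19,
                 ylim = range(c(df$p5, df$p95, 0)),
                 xlab = "training samples", ylab = "validation MCC",
                 main = sprintf("Learning curve (%s)", x$method), ...)
  graphics::arrows(df$n_train, df$p5, df$n_train, df$p95,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Near-optimal training sample size from a learning curve
#'
#' The smallest grid size `N_i` such that (a) every subsequent step's nu is
#' below `epsilon` (additional samples have negligible marginal value from
#' there on) and (b) its mean MCC is within one replicate-SD of the best mean
#' MCC on the grid.  The last grid point never qualifies on its own: with no
#' step beyond it there is no evidence the curve has flattened.
#'
#' @param curve A `learning_curve` with >= 2 evaluations.
#' @param epsilon Threshold for nu; defaults to the curve's configured value.
#' @return The size as an integer, or `NA_integer_` when no size qualifies
#'   (not reached within the grid).
#' @export
near_optimal_size <- function(curve, epsilon = NULL) {
  stopifnot(inherits(curve, "learning_curve"))
  epsilon <- epsilon %||% curve$config$epsilon
  df <- as.data.frame(curve)
  k <- nrow(df)
  if (k < 2L) {
    stop_ssnr("need >= 2 evaluations to judge the curve",
              class = "ssnr_validation_error")
  }
  best <- which.max(df$mean_mcc)
  floor_mcc <- df$mean_mcc[best] - df$sd_mcc[best]
  for (i in seq_len(k - 1L)) {
    flat <- all(curve$nu[i:(k - 1L)] < epsilon)
    if (flat && df$mean_mcc[i] >= floor_mcc) {
      return(as.integer(df$n_train[i]))
    }
  }
  NA_integer_
}

#' SSNR-versus-MCC association report
#'
#' Pairs each endpoint's SSNR with its achieved validation MCC and reports
#' the Pearson correlation — the package-level analogue of checking that
#' SSNR tracks endpoint predictability.
#'
#' @param entries A data.frame with columns `endpoint`, `ssnr`, `mcc`
#'   (>= 3 rows).
#' @return An object of class `ssnr_mcc_report`: list with the `table` and
#'   the correlation `r`.
#' @export
ssnr_mcc_report <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("endpoint", "ssnr", "mcc")
  if (!all(need %in% names(entries))) {
    stop_ssnr("entries must have columns %s", paste(need, collapse = ", "),
              class = "ssnr_validation_error")
  }
  if (nrow(entries) < 3L) {
    stop_ssnr("need >= 3 endpoints to correlate SSNR with MCC",
              class = "ssnr_validation_error")
  }
  r <- pearson_r(entries$ssnr, entries$mcc)
  structure(list(table = entries[, need], r = r), class = "ssnr_mcc_report")
}

#' @export
print.ssnr_mcc_report <- function(x, ...) {
  cat(sprintf("SSNR vs MCC over %d endpoints: Pearson r = %.3f\n",
              nrow(x$table), x$r))
  print(format(x$table, digits = 4))
  invisible(x)
}
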