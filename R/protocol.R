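# The two-stage SSNR protocol for minimum training sample size: evaluate the
# SSNR distribution on subsamples of 60 (threshold 2), then if needed 120
# (threshold 1); failing both marks the endpoint as poorly predictable.

#' Protocol configuration
#'
#' @param n_stage1,n_stage2 Training sizes evaluated at stages 1 and 2
#'   (defaults 60 and 120).
#' @param threshold_stage1,threshold_stage2 SSNR thresholds the stage mean
#'   must strictly exceed (defaults 2 and 1).
#' @param repetitions Subsampling replicates per stage (default 100).
#' @param conservative If `TRUE`, a stage passes only when
#'   `mean - sd > threshold` rather than `mean > threshold`.
#' @param sd_floor Passed to the SNR computation.
#' @param seed Base seed.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_stage1 = 60, n_stage2 = 120,
                            threshold_stage1 = 2, threshold_stage2 = 1,
                            repetitions = 100, conservative = FALSE,
                            sd_floor = 1e-8, seed = 1) {
  n_stage1 <- check_count(n_stage1, "n_stage1", min = 4L)
  n_stage2 <- check_count(n_stage2, "n_stage2", min = n_stage1 + 1L)
  if (threshold_stage1 <= 0 || threshold_stage2 <= 0 ||
      threshold_stage2 >= threshold_stage1) {
    stop_ssnr("thresholds must be positive with threshold_stage2 < threshold_stage1",
              class = "ssnr_validation_error")
  }
  repetitions <- check_count(repetitions, "repetitions", min = 1L)
  structure(list(n_stage1 = n_stage1, n_stage2 = n_stage2,
                 threshold_stage1 = threshold_stage1,
                 threshold_stage2 = threshold_stage2,
                 repetitions = repetitions, conservative = isTRUE(conservative),
                 sd_floor = sd_floor, seed = as.integer(seed)),
            class = "protocol_config")
}

#' SSNR distribution over repeated subsamples
#'
#' Draws `repetitions` stratified subsamples of size `n` from the pool and
#' records each one's SSNR; reported as mean +/- SD, the convention used to
#' compare a stage against its threshold.
#'
#' @param pool A [labeled_dataset()].
#' @param n Subsample size.
#' @param repetitions Number of replicates.
#' @param seed Base seed (replicate r uses seed + r).
#' @param sd_floor Passed to [snr_profile()].
#' @param stratified Preserve pool prevalence in each draw (default `TRUE`).
#' @return An object of class `ssnr_distribution`: list with `n`, `values`,
#'   `mean_ssnr`, `sd_ssnr`, `repetitions`.
#' @export
ssnr_distribution <- function(pool, n, repetitions = 100, seed = 1,
                              sd_floor = 1e-8, stratified = TRUE) {
  stopifnot(inherits(pool, "labeled_dataset"))
  repetitions <- check_count(repetitions, "repetitions", min = 1L)
  vals <- vapply(seq_len(repetitions), function(r) {
    sub <- subsample(pool, n, seed = derive_seed(seed, r),
                     stratified = stratified)
    snr_profile(sub, sd_floor = sd_floor)$ssnr
  }, numeric(1L))
  if (repetitions == 1L) {
    warning("single replicate: SD of the SSNR distribution reported as 0",
            call. = FALSE)
  }
  structure(list(n = n, values = vals, mean_ssnr = mean(vals),
                 sd_ssnr = if (repetitions == 1L) 0 else stats::sd(vals),
                 repetitions = repetitions),
            class = "ssnr_distribution")
}

#' @export
print.ssnr_distribution <- function(x, ...) {
  cat(sprintf("SSNR over %d subsamples of size %d: %.2f +/- %.2f\n",
              x$repetitions, x$n, x$mean_ssnr, x$sd_ssnr))
  invisible(x)
}

stage_passes <- function(dist, threshold, conservative) {
  if (conservative) (dist$mean_ssnr - dist$sd_ssnr) > threshold
  else dist$mean_ssnr > threshold
}

#' Two-stage SSNR decision on minimum training sample size
#'
#' Stage 1 evaluates the SSNR distribution on subsamples of `n_stage1`
#' (default 60): a mean strictly above `threshold_stage1` (default 2) means
#' that many training samples suffice for a near-optimal classifier and the
#' anticipated performance tier is "excellent".  Otherwise stage 2 repeats
#' the evaluation at `n_stage2` (default 120) against `threshold_stage2`
#' (default 1): passing means `n_stage2` samples suffice ("moderate"
#' anticipated performance); failing both marks the endpoint as poorly
#' predictable, where collecting more samples is not worthwhile.  Stage 2 is
#' only computed when stage 1 fails.
#'
#' @param pool A [labeled_dataset()] with at least `n_stage1` samples.
#' @param config A [protocol_config()].
#' @return An object of class `protocol_decision`: list with `outcome`
#'   (`"SUFFICIENT_AT_STAGE1"`, `"SUFFICIENT_AT_STAGE2"`,
#'   `"POOR_PREDICTOR"`, or `NA` when the pool cannot reach stage 2),
#'   `tier`, `stage1`, `stage2` (absent unless evaluated),
#'   `stage2_unavailable`, `recommendation`, `config`.
#' @examples
#' sc <- generate_scenario("excellent", seed = 1)
#' stepwise_decision(sc$pair$training,
#'                   protocol_config(repetitions = 10, seed = 1))
#' @export
stepwise_decision <- function(pool, config = protocol_config()) {
  stopifnot(inherits(pool, "labeled_dataset"),
            inherits(config, "protocol_config"))
  n_pool <- length(pool$labels)
  if (n_pool < config$n_stage1) {
    stop_ssnr("pool has %d samples but stage 1 needs %d", n_pool,
              config$n_stage1, class = "ssnr_validation_error")
  }
  stage1 <- ssnr_distribution(pool, config$n_stage1,
                              repetitions = config$repetitions,
                              seed = config$seed, sd_floor = config$sd_floor)
  if (stage_passes(stage1, config$threshold_stage1, config$conservative)) {
    return(structure(list(outcome = "SUFFICIENT_AT_STAGE1", tier = "excellent",
                          stage1 = stage1, stage2 = NULL,
                          stage2_unavailable = FALSE,
                          recommendation = sprintf(
                            "%d training samples are sufficient.",
                            config$n_stage1),
                          config = config),
                     class = "protocol_decision"))
  }
  if (n_pool < config$n_stage2) {
    return(structure(list(outcome = NA_character_, tier = "undetermined",
                          stage1 = stage1, stage2 = NULL,
                          stage2_unavailable = TRUE,
                          recommendation = sprintf(
                            "Stage 1 did not pass and the pool (%d samples) cannot reach stage 2; collect >= %d samples and re-evaluate.",
                            n_pool, config$n_stage2),
                          config = config),
                     class = "protocol_decision"))
  }
  stage2 <- ssnr_distribution(pool, config$n_stage2,
                              repetitions = config$repetitions,
                              seed = derive_seed(config$seed, 2L * config$repetitions),
                              sd_floor = config$sd_floor)
  if (stage_passes(stage2, config$threshold_stage2, config$conservative)) {
    outcome <- "SUFFICIENT_AT_STAGE2"; tier <- "moderate"
    rec <- sprintf("%d training samples are sufficient.", config$n_stage2)
  } else {
    outcome <- "POOR_PREDICTOR"; tier <- "poor"
    rec <- "Expression-based prediction of this endpoint is expected to perform poorly; collecting more samples is unlikely to help."
  }
  structure(list(outcome = outcome, tier = tier, stage1 = stage1,
                 stage2 = stage2, stage2_unavailable = FALSE,
                 recommendation = rec, config = config),
            class = "protocol_decision")
}

#' @export
print.protocol_decision <- function(x, ...) {
  cat("SSNR sample-size protocol\n")
  cat(sprintf("  stage 1 (n = %d): SSNR %.2f +/- %.2f vs threshold %g -> %s\n",
              x$stage1$n, x$stage1$mean_ssnr, x$stage1$sd_ssnr,
              x$config$threshold_stage1,
              if (identical(x$outcome, "SUFFICIENT_AT_STAGE1")) "pass" else "fail"))
  if (!is.null(x$stage2)) {
    cat(sprintf("  stage 2 (n = %d): SSNR %.2f +/- %.2f vs threshold %g -> %s\n",
                x$stage2$n, x$stage2$mean_ssnr, x$stage2$sd_ssnr,
                x$config$threshold_stage2,
                if (identical(x$outcome, "SUFFICIENT_AT_STAGE2")) "pass" else "fail"))
  }
  cat(sprintf("  outcome: %s (anticipated performance: %s)\n",
              if (is.na(x$outcome)) "stage 2 unavailable" else x$outcome,
              x$tier))
  cat(sprintf("  %s\n", x$recommendation))
  invisible(x)
}

#' Anticipated classifier performance tier
#'
#' Maps a protocol outcome to the anticipated performance of the final
#' classifier — "excellent" for a stage-1 pass, "moderate" for a stage-2
#' pass, "poor" otherwise — with a rationale quoting the stage SSNR
#' mean +/- SD.
#'
#' @param decision A `protocol_decision`.
#' @return List with elements `tier` and `rationale`.
#' @export
anticipated_performance <- function(decision) {
  stopifnot(inherits(decision, "protocol_decision"))
  s <- decision$stage2 %||% decision$stage1
  thr <- if (is.null(decision$stage2)) decision$config$threshold_stage1
         else decision$config$threshold_stage2
  rationale <- sprintf(
    "SSNR at n = %d was %.2f +/- %.2f against threshold %g; anticipated classifier performance: %s.",
    s$n, s$mean_ssnr, s$sd_ssnr, thr, decision$tier)
  list(tier = decision$tier, rationale = rationale)
}

#' Machine-readable protocol report table
#'
#' @param decision A `protocol_decision`.
#' @return Data.frame with one row per evaluated stage: `stage`, `n`,
#'   `mean_ssnr`, `sd_ssnr`, `threshold`, `verdict`.
#' @export
protocol_table <- function(decision) {
  stopifnot(inherits(decision, "protocol_decision"))
  rows <- list(data.frame(
    stage = 1L, n = decision$stage1$n,
    mean_ssnr = decision$stage1$mean_ssnr, sd_ssnr = decision$stage1$sd_ssnr,
    threshold = decision$config$threshold_stage1,
    verdict = if (identical(decision$outcome, "SUFFICIENT_AT_STAGE1")) "pass" else "fail"))
  if (!is.null(decision$stage2)) {
    rows <- c(rows, list(data.frame(
      stage = 2L, n = decision$stage2$n,
      mean_ssnr = decision$stage2$mean_ssnr, sd_ssnr = decision$stage2$sd_ssnr,
      threshold = decision$config$threshold_stage2,
      verdict = if (identical(decision$outcome, "SUFFICIENT_AT_STAGE2")) "pass" else "fail")))
  }
  do.call(rbind, rows)
}
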