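#!/usr/bin/env Rscript
# Development-time calibration of the generate_scenario() presets.
#
# For each tier preset this measures, over independent seeds:
#   * the distribution of stage-1 / stage-2 SSNR means (protocol, reps = 25),
#   * the protocol decision frequencies,
#   * the full-pool cross-validated nearest-centroid classifier's validation
#     MCC.
# The preset parameters frozen in R/synthetic.R were chosen from these
# measurements; rerun after any generator change.
#
# Usage: Rscript scripts/calibrate_scenarios.R [n_seeds] [reps]

suppressPackageStartupMessages(library(ssnr))

args <- commandArgs(trailingOnly = TRUE)
n_seeds <- if (length(args) >= 1L) as.integer(args[1L]) else 20L
reps <- if (length(args) >= 2L) as.integer(args[2L]) else 25L

for (tier in c("excellent", "moderate", "poor")) {
  res <- lapply(seq_len(n_seeds), function(s) {
    sc <- generate_scenario(tier, seed = s)
    dec <- stepwise_decision(sc$pair$training,
                             protocol_config(repetitions = reps, seed = s))
    model <- cross_validate_select(sc$pair$training,
                                   classifier_config("ncentroid", seed = s))
    pred <- predict(model, sc$pair$validation$dataset)
    list(outcome = dec$outcome,
         s1 = dec$stage1$mean_ssnr,
         s2 = if (is.null(dec$stage2)) NA_real_ else dec$stage2$mean_ssnr,
         mcc = mcc(confusion_counts(sc$pair$validation$labels, pred)))
  })
  outcome <- vapply(res, `[[`, character(1L), "outcome")
  s1 <- vapply(res, `[[`, numeric(1L), "s1")
  s2 <- vapply(res, `[[`, numeric(1L), "s2")
  mccs <- vapply(res, `[[`, numeric(1L), "mcc")
  cat(sprintf("\n== %s (%d seeds, reps = %d) ==\n", tier, n_seeds, reps))
  print(table(outcome))
  cat(sprintf("stage-1 SSNR mean: %.3f (range %.3f-%.3f)\n",
              mean(s1), min(s1), max(s1)))
  if (any(!is.na(s2))) {
    cat(sprintf("stage-2 SSNR mean: %.3f (range %.3f-%.3f)\n",
                mean(s2, na.rm = TRUE), min(s2, na.rm = TRUE),
                max(s2, na.rm = TRUE)))
  }
  cat(sprintf("validation MCC: mean %.3f (range %.3f-%.3f)\n",
              mean(mccs), min(mccs), max(mccs)))
}
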