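# ssnr — how many training samples does an expression classifier need?

Binary outcome classifiers built from gene expression profiles (treatment
response, survival milestones, receptor status) are unreliable when trained
on too few samples, yet clinical samples are scarce and expensive. `ssnr`
implements a pragmatic planning tool for this trade-off: it scores how
strongly individual genes separate the two outcome classes and turns that
score into a two-stage minimum-sample-size decision, together with the full
resampling machinery needed to validate the decision on any dataset.

## The statistics at the core

For gene *i* with class means μ₁ᵢ, μ₂ᵢ and sample SDs σ₁ᵢ, σ₂ᵢ of the log
expression, the signal-to-noise ratio is

    aᵢ = (μ₁ᵢ − μ₂ᵢ) / (σ₁ᵢ + σ₂ᵢ)

and the **SSNR** (scale of the SNR vector) of a dataset is its range

    SSNR = max aᵢ − min aᵢ ≥ 0,

the distance between the strongest up- and strongest down-regulated marker.
Classifier performance is measured by the Matthews correlation coefficient

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)) ∈ [−1, 1],

0 corresponding to random prediction. The decision rule: evaluate the SSNR
over repeated subsamples of **60** training samples — a mean above **2**
means 60 samples suffice (anticipated performance *excellent*); otherwise
re-evaluate at **120** samples against threshold **1** (*moderate*); failing
both, the endpoint is a *poor* candidate for expression-based prediction and
more samples will not rescue it.

Around this rule the package provides repeated-subsampling learning curves
(MCC versus training size with 5–95% whiskers and a per-step marginal-value
index ν), three reference classifiers (nearest centroid, kNN with k = 3,
linear SVM) with cross-validated SNR-based feature selection,
positive/negative control endpoint constructors, and a calibrated synthetic
data generator.

## Worked example

```r
library(ssnr)

sc <- generate_scenario("moderate", seed = 42)   # 200 training / 150 validation

snr_profile(sc$pair$training)
#> SNR profile over 500 genes (class sizes 24 / 176)
#>   SSNR = 1.1645 (max 0.6606, min -0.5038)

stepwise_decision(sc$pair$training, protocol_config(repetitions = 25, seed = 42))
#> SSNR sample-size protocol
#>   stage 1 (n = 60): SSNR 1.52 +/- 0.14 vs threshold 2 -> fail
#>   stage 2 (n = 120): SSNR 1.21 +/- 0.13 vs threshold 1 -> pass
#>   outcome: SUFFICIENT_AT_STAGE2 (anticipated performance: moderate)
#>   120 training samples are sufficient.
```

The stage-1 mean SSNR of 1.52 fails the threshold of 2, so 60 samples are
not enough; at 120 samples the mean of 1.21 clears 1, so the protocol
recommends 120 and predicts moderate classifier performance. The empirical
learning curve agrees:

```r
curve <- build_learning_curve(
  sc$pair$training, sc$pair$validation,
  curve_config(size_start = 40, size_max = 180, repetitions = 25, seed = 42),
  classifier_config("ncentroid", seed = 42))
curve
#> Learning curve (ncentroid, 25 replicates per size, seed 42)
#>   n_train mean_mcc  sd_mcc       p5    p95      nu
#> 1      40   0.1333 0.15019 -0.05360 0.4120      NA
#> 2      60   0.2108 0.16929 -0.05079 0.4392  1.1639
#> 3      80   0.3080 0.19217 -0.01572 0.5497  1.3830
#> 4     100   0.3405 0.15324  0.11929 0.6024  0.4222
#> 5     120   0.3493 0.12417  0.14562 0.5323  0.1281
#> 6     140   0.4017 0.08809  0.30020 0.5460  0.9002
#> 7     160   0.3951 0.08809  0.24576 0.5217 -0.1148
#> 8     180   0.4163 0.06278  0.29518 0.5088  0.4293
```

Mean validation MCC climbs steeply up to about 100–120 training samples and
then levels off in the moderate band (0.35–0.42), exactly the behaviour the
stage-2 pass anticipates. (`near_optimal_size(curve)` returns `NA` here: at
25 replicates the late-curve means are noisy enough that the strict
"every subsequent ν < ε" criterion never locks in; at the default 100
replicates the curve is smoother.) The grid starts at 40 because with
prevalence 0.12 a stratified draw of 20 contains only two minority samples —
too few to cross-validate.

A command-line front end over the same functions ships in
`inst/cli/ssnr-tool.R` (subcommands `ssnr`, `learning-curve`, `protocol`,
`simulate`, `control`).

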