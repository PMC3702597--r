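---
title: "Sample-size determination for expression classifiers with SSNR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-size determination for expression classifiers with SSNR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnr)
```

## The problem

Outcome classifiers built from transcriptome profiles — treatment response,
survival milestones, receptor status — are only as reliable as the statistical
parameters estimated from their training samples. Clinical samples are scarce,
so the practical question is rarely "how good is my classifier" but "how many
training samples do I need before building one is worthwhile at all". This
package implements a pragmatic answer: measure how strongly any single gene
separates the two outcome classes, summarised by the *scale of the
signal-to-noise ratio* (SSNR), and read the required training size off a
two-stage decision rule. Alongside the rule it provides the full resampling
machinery needed to validate it on any dataset: repeated-subsampling learning
curves, three reference classifiers, and positive/negative control endpoints.

## The statistics

For gene $i$, with per-class means $\mu_{1i}, \mu_{2i}$ and sample standard
deviations $\sigma_{1i}, \sigma_{2i}$ of the log expression, the Golub-style
signal-to-noise ratio is

$$a_i = \frac{\mu_{1i} - \mu_{2i}}{\sigma_{1i} + \sigma_{2i}},$$

positive when the gene is higher in class 1. The SSNR of a dataset is the
range of this vector over all $p$ genes,

$$\mathrm{SSNR} = \max_i a_i - \min_i a_i \ge 0,$$

the numeric distance between the strongest up- and strongest down-regulated
marker. Classifier performance is measured exclusively by the Matthews
correlation coefficient,

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} \in [-1, 1],$$

with 0 corresponding to random prediction; when a marginal factor under the
radical is zero the value is defined as 0, the common convention for a
degenerate margin (the source of the statistic leaves this case open).

Two conventions in the SNR needed a decision because the defining formulas
leave them open. The SD uses the $n-1$ (sample) denominator — the
conventional estimator; the choice is recorded in output metadata. And
because a gene can have zero variance in both classes, the denominator
$\sigma_{1i}+\sigma_{2i}$ is floored at `sd_floor` ($10^{-8}$ by default);
alternatively such genes can be dropped (`zero_sd = "drop"`). A related open
point is the treatment of an SNR vector with no negative (or no positive)
entries: the prose description of SSNR speaks of the largest positive and
smallest negative values, while the defining expression is the scale of the
vector. We implement the range $\max - \min$ unconditionally, so a
single-gene profile has SSNR 0.

## The learning-curve engine

`build_learning_curve()` estimates performance as a function of training
size: at each size on a grid (20, 40, ... by default) it repeatedly draws a
training subsample from the pool (100 replicates by default), selects and
fits a classifier by stratified 5-fold cross-validation, predicts a disjoint
validation set, and summarises the replicate MCCs by mean, SD and the 5–95%
percentiles (linear interpolation between order statistics). Replicates are
never silently dropped: a degenerate draw raises an error, so every
`size_evaluation` holds exactly `repetitions` values.

The marginal value of moving from size $N_{i-1}$ to $N_i$ is summarised by

$$\nu_i = \frac{(\mathrm{MCC}_i - \mathrm{MCC}_{i-1}) / \max(\mathrm{MCC}_{i-1}, 0.01)}
{(N_i - N_{i-1}) / N_{i-1}},$$

the relative MCC gain per relative increase in sample count, with the
denominator MCC floored at 0.01 so the index stays finite when performance
hovers near zero. The exact algebraic form of this index is a design choice
of this package — the published description of such an index states only
that it balances relative performance gain against sampling cost — so the
form is isolated in `nu_index()` and can be swapped. `near_optimal_size()`
declares a grid size sufficient when every later step has $\nu < \varepsilon$
(default 0.05, configurable; the intent is simply "much smaller than 1") and
its mean MCC is within one replicate-SD of the best size's mean. The last
grid point never qualifies vacuously: with no step beyond it there is no
evidence the curve has flattened, so a strictly rising curve returns
"not reached" (`NA`).

Subsampling is stratified by default (largest-remainder rounding of the pool
prevalence, each class at least 2). At size 20 with prevalence 0.15 an
unstratified draw routinely contains fewer than two minority samples, which
would make SD estimation impossible; non-stratified mode remains available
for sensitivity analysis. Replicate seeds are `base_seed + r`, so extending
the size grid or the replicate count never changes the draws already made.

## Classifiers

Three reference methods are provided: nearest centroid (Euclidean distance
to the per-class mean vectors, ties to class 1), $k$-nearest neighbours
($k = 3$, majority vote), and a soft-margin linear SVM (cost 1, no nested
hyper-parameter search — nesting a second cross-validation inside each of
hundreds of replicates would multiply runtime for no clear gain, and the
protocol's conclusions are expected to be method-insensitive). Features are
selected per fold by SNR magnitude over a feature-count grid (5, 10, 25, 50,
100 by default, capped at $p$); ranking is recomputed on each fold's training
portion only, so the held-out fold cannot leak into selection. The selection
criterion is mean cross-validated MCC with ties resolved toward fewer
features. These selection details are package conventions consistent with
common practice for expression classifiers; they are deliberately simple and
fully configurable via `classifier_config()`.

## The two-stage protocol

`stepwise_decision()` operationalises the rule. Collect 60 training samples
and evaluate the SSNR distribution over repeated subsamples of that size
(100 replicates by default, reported as mean ± SD):

* mean SSNR > 2 — 60 samples are enough; anticipated classifier
  performance **excellent** (MCC around 0.8 or above).
* otherwise collect 120 samples and re-evaluate; mean SSNR > 1 — 120
  samples are enough; anticipated performance **moderate** (MCC roughly
  0.2–0.5).
* otherwise the endpoint is a **poor** candidate for expression-based
  prediction and collecting further samples is unlikely to help.

The stage comparison uses the replicate *mean* against the threshold with
strict inequality, matching the mean ± SD reporting convention that motivates
the rule; a conservative mode requiring mean − SD to clear the threshold is
available. Stage 2 is computed only when stage 1 fails. When the pool cannot
reach 120 samples the decision reports the stage-1 findings with an explicit
"collect more samples" recommendation rather than guessing. The rule is
intentionally a two-point step function — it does not interpolate or
extrapolate to other sizes.

## Controls

Any SSNR analysis should be bracketed by internal controls.
`positive_control()` relabels the samples by an existing two-level covariate
with a strong transcriptional signature (gender is the canonical choice):
the result should be highly predictable, bounding what the data support.
`negative_control()` relabels at random with an exact-count prevalence
(default 0.5; exact counts keep prevalence controlled in small pools): its
learning curve should stay flat near MCC 0 at every size, excluding false
positives from the analysis pipeline itself.

## The synthetic generator and what it does (not) show

`generate_dataset()` draws Gaussian log2 expression with homoscedastic
per-gene noise: gene $g$ in sample $s$ is
$b_g + \delta \cdot \mathbb{1}[g \text{ informative}] \cdot \mathbb{1}[s \in \text{class 1}] + \mathcal{N}(0, \sigma^2)$
with baselines $b_g \sim \mathcal{N}(7, 1)$, exact-count prevalence, and an
optional sign-mixing flag that shifts half the informative genes in the
other direction. This is the simplest model consistent with the mean/SD
parameterisation of the SNR, and it gives recovery tests a closed-form
target: an informative gene's population SNR is $\delta / (2\sigma)$.

`generate_scenario()` ships three frozen presets (500 genes, $\sigma = 0.5$,
350 samples split 200 training / 150 validation, stratified):

| tier | informative genes | $\delta$ | prevalence | designed behaviour |
|---|---|---|---|---|
| excellent | 50 | 2 | 0.50 | stage-1 pass; full-data nearest-centroid MCC near 1 |
| moderate | 2 (sign-mixed) | 0.62 | 0.12 | stage-2 pass; MCC in the 0.2–0.5 band |
| poor | 0 | 0 | 0.50 | both stages fail; MCC near 0 |

The presets were calibrated once by simulation
(`scripts/calibrate_scenarios.R` in the source repository) and then frozen;
over 30 seeds each tier reproduced its protocol decision in 30/30 runs at 25
replicates per stage. The moderate tier is structurally the hardest preset:
with independent genes the SSNR of a sign-mixed pair is $2a$ while the
achievable class separation grows as $2a\sqrt{2}$, so parameter choices that
reliably clear the stage-2 threshold also push the Bayes-optimal MCC toward
the top of the moderate band. The unbalanced prevalence (0.12) is what keeps
realised MCC centred near 0.34: MCC penalises errors on a rare class, and
the nearest-centroid midpoint rule ignores priors.

What the generator does *not* emulate — and hence what passing tests on it
cannot certify about real cohorts: correlated co-expression modules (real
informative genes are far from independent), heavy-tailed and
heteroscedastic noise, platform and batch effects, label noise, and
prevalence drift between training and validation populations. The synthetic
results validate the machinery and the internal consistency of the
rule, not its clinical calibration.

## Problem sizes and numerical choices

The default study conditions mirror the protocol's definition: size grids
from 20 in steps of 20, 100 replicates, 5-fold cross-validation. The package
test-suite runs the same machinery at reduced scale — typically 500 genes,
pools of 150–200 samples, 10–50 replicates, and 25 protocol replicates —
sizes chosen so the full statistical behaviour (null flatness, decision
recovery, SSNR–MCC association) is exercised with comfortable Monte-Carlo
margins. All randomness flows from explicit integer seeds; replicate seeds
are derived additively so results are reproducible and extensible. Quantiles
use R's default type-7 linear interpolation. Ties are deterministic
throughout (centroid ties to class 1, feature-count ties to the smaller
count, ranking ties lexicographic by gene id).

## A complete run

```{r example, eval = FALSE}
sc <- generate_scenario("moderate", seed = 42)

# Would 60 or 120 training samples be enough for this endpoint?
decision <- stepwise_decision(sc$pair$training,
                              protocol_config(repetitions = 25, seed = 42))
print(decision)
anticipated_performance(decision)$rationale

# Verify against the empirical learning curve.  The grid starts at 40 here:
# at prevalence 0.12 a stratified draw of 20 holds only two minority
# samples, too few to cross-validate.
curve <- build_learning_curve(
  sc$pair$training, sc$pair$validation,
  curve_config(size_start = 40, size_max = 180, repetitions = 25, seed = 42),
  classifier_config("ncentroid", seed = 42))
print(curve)
near_optimal_size(curve)
plot(curve)

# Bracket the analysis with a negative control
nc <- negative_control(sc$pair$training, seed = 4242)
flat <- build_learning_curve(
  nc, sc$pair$validation,
  curve_config(size_start = 40, size_max = 180, repetitions = 25, seed = 42),
  classifier_config("ncentroid", seed = 42))
```

## Known limitations

The SSNR is a single-gene summary: an endpoint predictable only through a
multivariate combination of individually weak genes will be underrated by
the protocol, and the thresholds (2 at 60 samples, 1 at 120) are empirical
conventions inherited from microarray-era cancer cohorts, not universal
constants. The rule deliberately answers only "60, 120, or don't bother";
for finer-grained planning, fit the learning curve directly. Multi-class
endpoints, survival outcomes treated as time-to-event (rather than a
milestone dichotomy), and batch correction are out of scope.
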