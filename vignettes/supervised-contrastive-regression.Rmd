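---
title: "Supervised contrastive regression for tabular tractometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised contrastive regression for tabular tractometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screg)
```

## The problem

Whole-brain diffusion-MRI tractography can be parcellated into on the order
of a thousand fiber clusters, and per-cluster microstructure measures —
fractional anisotropy (FA), mean diffusivity (MD), number of streamlines
(NoS) — form one tabular dataset per measure: subjects in rows, clusters in
columns. A continuous neurocognitive score (for example a principal-component
summary of a cognitive battery, spanning roughly $[-3, 3]$) is attached to
each subject, and the task is regression: predict the score from the
cluster-wise measures, then ask which clusters carried the prediction.

`screg` implements a supervised contrastive regression pipeline for this
setting, together with the surrounding protocol: per-measure ensembling,
repeated-split evaluation with paired tests, a grouped permutation
feature-importance algorithm for high-dimensional inputs, and a synthetic
tractometry generator so that every stage can be exercised and validated
without access to restricted imaging data.

## The model

### Pair determination from continuous labels

Supervised contrastive learning for classification treats two samples as a
*positive pair* when they share a class label. Continuous labels have no
shared classes, so the rule becomes a threshold on the label difference:
samples $i \ne j$ are a positive pair iff

$$|y_i - y_j| < \theta,$$

with strict inequality at the boundary. The default $\theta = 0.35$ is suited
to scores with roughly unit spread on $[-3, 3]$; accuracy is robust for
$\theta$ between about 0.1 and 0.5, which the acceptance checks exercise.

### Random feature corruption

Each training mini-batch $X$ (size $b$, default 2048) is augmented with a
corrupted copy $\tilde X$: per row, a random subset of $\mathrm{round}(c
\cdot d)$ feature positions (corruption rate $c$, default 0.5) is replaced by
values drawn from the same column of other rows in the batch. Column
marginals are preserved; row structure is broken; the corrupted copy keeps
its source row's label, so every anchor has at least its twin as a positive.
Subsets are drawn independently per row, and donors are drawn uniformly among
the other rows of the batch (not the whole training set), which keeps the
operation streamable; a replacement may coincidentally equal the original
value and is not redrawn.

### Loss, architecture, and two-phase training

The combined batch $R$ ($2b$ rows) is embedded by a four-layer encoder
$\mathrm{Enc}$ and a two-layer projector $\mathrm{Proj}$ (all hidden widths
256, rectifier activations), and the projector output is L2-normalized row
by row. The supervised contrastive loss is

$$L = \sum_{r \in R} \frac{-1}{|P(r)|} \sum_{p \in P(r)}
  \log \frac{\exp(z_r \cdot z_p / \tau)}
            {\sum_{a \in A(r)} \exp(z_r \cdot z_a / \tau)},$$

with $A(r) = R \setminus \{r\}$, temperature $\tau = 1$ by default, and an
anchor with no positives contributing zero. The implementation follows the
summed form over anchors exactly (a mean-over-anchors mode exists for
batch-size-independent logging), stabilizes the softmax by subtracting each
anchor's maximum logit, and is verified against a brute-force nested-loop
transcription of the formula to $10^{-6}$.

Training proceeds in two phases, both with Adam (learning rate $10^{-3}$) and
early stopping with patience 3 on a validation loss, returning the
best-validation-epoch parameters:

1. **Contrastive pretraining** of $\mathrm{Enc}$ and $\mathrm{Proj}$ on the
   loss above. The validation contrastive loss is evaluated with corruption
   drawn under a fixed seed, so every epoch is scored on the identical
   validation batch.
2. **Fine-tuning**: $\mathrm{Enc}$ is frozen (bit-identical parameters, an
   assertable contract), $\mathrm{Proj}$ is set aside, and a two-layer head
   $\mathrm{Reg}$ on the encoder output is trained with mean squared error at
   batch size 128.

Per-measure predictors are combined by an unweighted mean
(`scr_ensemble()`), and accuracy is the Pearson correlation between truth
and prediction over repeated 70/10/20 train/validation/test splits, compared
across methods with two-sided paired t-tests after an omnibus one-way
within-subject ANOVA (no sphericity correction; the split is the subject
factor). No multiple-comparison correction is applied by default.

## Numerical and design choices

* **Standardization.** Features are z-scored with training-split statistics
  (population standard deviation; zero-variance features get scale 1 and map
  to 0) before both phases. FA ($\sim$0–1), MD ($\sim 10^{-3}$ mm²/s) and
  streamline counts otherwise sit on incompatible scales, and corruption
  draws on the standardized table are scale-consistent. Labels are used
  as-is. Zero-filled empty-cluster entries are standardized like any other
  value.
* **Network wiring.** $\mathrm{Enc}$: $d \to 256 \to 256 \to 256 \to 256$
  with a rectifier after every layer; $\mathrm{Proj}$: $256 \to 256 \to 256$
  with a rectifier between and none after the final layer, then L2
  normalization; $\mathrm{Reg}$: $256 \to 256 \to 1$ with a rectifier
  between. The reference MLP (`mlp_fit()`) is the same encoder + head
  trained end-to-end with MSE from scratch.
* **Initialization.** Fan-in-scaled uniform,
  $U(\pm 1/\sqrt{\text{fan-in}})$, for weights and biases. The scale
  matters: with larger (He-style) initialization these over-parameterized
  networks memorize high-dimensional noise within one or two epochs, before
  patience-based early stopping can return anything useful; the conservative
  scale is also what mainstream deep-learning frameworks default to for
  dense layers.
* **Early stopping.** Strict improvement of the validation loss resets a
  counter; training stops after 3 consecutive epochs without improvement and
  the best epoch's parameters are kept. The epoch cap is 200; early stopping
  governs in practice. Fine-tuning starts a fresh optimizer; no state is
  shared between phases.
* **Splits.** Validation and test sizes are floored, the remainder goes to
  train; the split is a seeded permutation, and every downstream shuffle
  draws from the fit's own seeded stream, so whole fits are bit-reproducible.
* **Degenerate cases.** Batches that collapse below two rows are skipped;
  anchors with empty positive sets contribute zero loss; constant columns
  survive standardization; a paired comparison of identical per-split
  vectors returns $t = 0, p = 1$ while a constant nonzero difference raises
  a degenerate-case error rather than reporting an infinite statistic.

## Grouped permutation feature importance

Classical permutation importance shuffles one feature at a time, but with
$\sim$1000 input features the accuracy drop from a single shuffled column is
negligible. The grouped variant draws a random group (default 10% of
features, e.g. 95 of 953) per permutation, shuffles each selected column
independently across subjects (independent shuffles, rather than one shared
row permutation, so within-group covariance is destroyed too), records the
decrease in test Pearson r together with the selected indices, and repeats
many times. A feature's score is the mean decrease over the permutations
that included it; negative contributions are kept, never clipped. Inclusion
counts are conserved exactly: they sum to group size × permutations.

Two modes are provided, because the literal protocol — shuffle *training*
features, retrain, evaluate — costs one model fit per permutation, which at
tens of thousands of permutations is far beyond a desktop budget.
`mode = "retrain"` is that literal protocol and the default recommendation
for small runs; `mode = "test_permute"` shuffles the test rows of one fixed
fitted model and is the scalable surrogate used in the package's own checks.
The two answer subtly different questions (value for refitting vs reliance
of a fixed model), which is flagged in the documentation. When ensembling
across measures, scores are computed per member model; an ensemble-level
run can be obtained by passing the ensemble as the model.

Top-ranked clusters (`top_features()`, deterministic id tie-break) are
aggregated into the five anatomical categories of a whole-brain parcellation
(association, projection, commissural, cerebellar, superficial) with
`aggregate_by_category()`, giving the familiar counts-with-percentages
summary table.

## The synthetic data model

`synthetic_spec()` / `generate_dataset()` emulate the tabular face of
fiber-cluster tractometry:

* per measure, an $n \times d$ matrix (default $d = 953$) of i.i.d. standard
  normal latent features, affinely mapped to measure-typical scales (FA
  $\approx 0.5 \pm 0.08$, MD $\approx 8.5\times10^{-4} \pm 6\times10^{-5}$
  mm²/s, NoS $\approx 600 \pm 120$);
* a sparse planted linear signal: $k$ informative features (default 50),
  split across the measures so that ensembling has complementary
  information, with equal-magnitude random-sign weights normalized to unit
  signal variance — equal magnitudes so that every planted feature carries a
  detectable share, which is what a recovery test needs;
* label $y = \text{signal} + \varepsilon$, $\varepsilon \sim N(0,
  \sigma^2)$, rescaled to unit sample standard deviation (scores span
  roughly $[-3,3]$). The noise ceiling — the highest test correlation any
  predictor can reach — is $r_{\max} = 1/\sqrt{1 + \sigma^2}$ in closed
  form; `noise_sd_for_ceiling()` inverts it, and the default $\sigma$ gives
  $r_{\max} = 0.6$, in the range reported for neurocognitive prediction;
* optional zero-inflation (default 2% of entries, emulating empty clusters;
  applied after signal construction so zeros corrupt signal the way empty
  clusters would — set it to 0 when validating against the closed-form
  ceiling, which assumes no inflation), an optional `tanh` nonlinearity, and
  a random cluster-to-category map over the five anatomical categories.

### What the generator does and does not emulate

The generator reproduces the dimensions, scales, sparsity, label range and
zero-inflation of real tractometry tables, but deliberately **not** their
inter-cluster covariance: features are independent. That choice keeps every
ground truth in closed form, and it is the honest caveat for all results on
synthetic data. Real fiber-cluster measures are strongly correlated (clusters
within a tract, hemispheric homologues), so their intrinsic dimension is far
below $d$; representation learning exploits exactly that structure. With
independent features there is no low-dimensional structure to find:
compressing 953 independent coordinates into a 256-unit encoder necessarily
discards most of a sparse signal's variance, and a corrupted copy that
replaces half of the informative features no longer carries its original
label content, so the forced positive pairs are themselves label-noisy.
Consequently, on this generator's data at realistic sample sizes, contrastive
pretraining does not approach the noise ceiling the way sparse linear models
do (ElasticNet-style fits reach it), and the end-to-end MSE reference can
outperform the frozen-encoder pipeline. Passing tests on synthetic data
therefore certify the *mechanics* — the loss, pairing, corruption, freezing,
ensembling, importance bookkeeping and protocol — not the real-data accuracy
advantage of contrastive pretraining, which rests on covariance structure the
generator intentionally omits.

## Problem sizes used in the package's own checks

The bundled checks validate the loss against a nested-loop oracle on batches
of up to 12 samples; run the full pipeline at $n = 4000$, $d = 953$, 50
informative features and a 0.6 ceiling (three seeds, with the MLP reference
on identical splits, and a $\theta \in \{0.1, 0.35, 0.5\}$ /
$\tau \in \{0.5, 1, 5\}$ robustness sweep around the default); recover
planted features at $d = 100$ with 2000 permutations of groups of 10; and
keep unit tests at a few hundred subjects. The acceptance script
(`scripts/acceptance.R`) reports a three-measure ensemble run at $n = 1500$,
$d = 200$ — sizes chosen so a complete desktop run stays in the minutes
range while every quantity is still estimated from thousands of test
predictions.

## A worked example

```{r example, eval = FALSE}
library(screg)

ds <- generate_dataset(synthetic_spec(
  n_subjects = 1500, n_features = 200, n_informative = 30,
  n_measures = 3, zero_inflation = 0, seed = 7
))
split <- make_split(1500, seed = 7)

models <- lapply(names(ds$tables), function(m) {
  scr_fit(ds$tables[[m]], ds$scores, split, seed = 7, measure_name = m)
})
ens <- scr_ensemble(models)

test <- split$test
pred <- predict(ens, lapply(ds$tables, function(t) t[test, ]))
pearson_r(ds$scores$score[test], pred)

imp <- permutation_importance(models[[1]], ds$tables[[1]], ds$scores, split,
                              n_permutations = 1000, seed = 7)
aggregate_by_category(top_features(imp, 50), ds$category_map)
```

## Known limitations

* The synthetic features are independent; see the caveat above. Conclusions
  about the *relative* accuracy of contrastive pretraining versus supervised
  references on real tractometry cannot be drawn from this generator.
* The repeated-measures ANOVA is the uncorrected one-way within-subject
  form; no sphericity correction is applied, and it is labeled as such.
* `mode = "retrain"` importance at published permutation counts (tens of
  thousands) implies as many model fits and is not intended to run on a
  desktop; the surrogate mode is provided and clearly distinguished.
* Training runs on the CPU; the matrix work is delegated to BLAS, and a
  full-scale fit ($n = 4000$, $d = 953$) takes on the order of a minute per
  phase on one core.
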