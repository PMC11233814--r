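# screg — supervised contrastive regression for tabular tractometry

`screg` predicts continuous outcomes — typically neurocognitive component
scores spanning roughly [−3, 3] — from high-dimensional tabular neuroimaging
features such as fiber-cluster tractometry measures (one subjects × clusters
table per microstructure measure: FA, MD, NoS; ~953 clusters in a fine
whole-brain parcellation). It is aimed at researchers studying
brain-structure/cognition relationships who want a deep representation
learning pipeline, a defensible evaluation protocol, and an interpretation
method, all runnable and testable on synthetic data.

## The method

Supervised contrastive learning needs positive and negative sample pairs.
With continuous labels there are no shared classes, so pairs are determined
by a threshold on the label difference: samples *i*, *j* are a **positive
pair** iff

    |y_i − y_j| < θ        (default θ = 0.35, strict inequality)

Each training mini-batch *X* (size *b* = 2048) gains a corrupted copy *X̃*:
per row, a random `round(c·d)` of the *d* features (corruption rate *c* =
0.5) are replaced by draws from the same column of other rows. Both halves
are embedded by a 4-layer encoder `Enc` and a 2-layer projector `Proj`
(hidden width 256, ReLU), embeddings are L2-normalized, and the supervised
contrastive loss

    L = Σ_{r∈R} (−1/|P(r)|) Σ_{p∈P(r)} log[ exp(z_r·z_p/τ) / Σ_{a∈A(r)} exp(z_r·z_a/τ) ]

is minimized with Adam (lr 0.001, early stopping patience 3 on validation
loss). Then `Enc` is **frozen**, `Proj` discarded, and a 2-layer head `Reg`
is fine-tuned with MSE (batch 128). Per-measure predictors are ensembled by
an unweighted mean. Accuracy is Pearson's *r* between truth and prediction
over repeated 70/10/20 splits, with paired t-tests (after a repeated-measures
ANOVA) between methods. Interpretation uses **grouped permutation feature
importance**: shuffle a random 10% of features at once, record the drop in
test *r* with the shuffled indices, repeat thousands of times, and average
each feature's recorded drops.

The neural networks, the contrastive loss and its gradient, and the Adam
optimizer are implemented in base R on BLAS matrix products; fits are
bit-reproducible under a seed and run on one CPU core.

## Worked example

```r
library(screg)

# synthetic tractometry: 3 measures × 200 clusters, 30 informative features,
# label noise set for a noise ceiling of r_max = 0.6
ds <- generate_dataset(synthetic_spec(
  n_subjects = 1500, n_features = 200, n_informative = 30,
  n_measures = 3, zero_inflation = 0, seed = 7
))
split <- make_split(1500, seed = 7)

models <- lapply(names(ds$tables), function(m)
  scr_fit(ds$tables[[m]], ds$scores, split, seed = 7, measure_name = m))
ens <- scr_ensemble(models)

test <- split$test
pred <- predict(ens, lapply(ds$tables, function(t) t[test, ]))
pearson_r(ds$scores$score[test], pred)
#> [1] 0.187246

imp <- permutation_importance(models[[1]], ds$tables[[1]], ds$scores, split,
                              n_permutations = 1000, seed = 7)
glance(imp)
#>   baseline_r group_size n_permutations         mode n_unsampled
#> 1 0.07566735         20           1000 test_permute           0
```

The ensemble correlation (0.19) sits well below the generator's noise
ceiling (0.6): with *independent* synthetic features, a deep encoder's
200→256 compression discards most of a sparse signal's variance, and
corrupted positives are label-noisy — the vignette's honest-caveats section
quantifies this. In a denser-signal regime (100 features, 10 informative,
no label noise) the same pipeline reaches test r ≈ 0.95 and the grouped
importance recovers 10/10 planted features, which is what the bundled
checks assert. `autoplot()` methods visualize training history,
per-split accuracies, and top feature importances; `tidy()`/`glance()`
return tibbles ready for further dplyr work.

A thin CLI mirroring these steps (subcommands `simulate`, `train`,
`predict`, `evaluate`, `importance`) ships in `inst/cli/screg`.

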