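---
title: "Radiogenomic association and prediction with RadioLink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiogenomic association and prediction with RadioLink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RadioLink)
```

## The problem

Radiogenomics asks whether the quantitative appearance of a tumor on a
radiographic scan — its size, shape, texture, enhancement kinetics, wavelet
content — carries information about the tumor's molecular state, typically
summarized as normalized gene expression of a few hundred screened genes.
RadioLink operationalizes this question as a configurable pipeline over two
sample-by-feature CSV tables: correlation screening with multiple-testing
control, supervised prediction of one feature space from the other, a
per-label error decomposition, classification performance across expression
cutoffs, and permutation-based significance.

## Pipeline and model

A training run proceeds in two automated scenarios sharing one train/test
split.

**Scenario A (correlation-filtered).** Every (data feature, label) pair is
tested with Pearson or Spearman correlation *on the non-normalized matched
data* — filtering is a property of the raw measurements, not of any model
space. Spearman coefficients are Pearson correlations of average ranks;
two-sided p-values for both methods use the t-approximation
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom (accurate for the
sample sizes this pipeline targets, $n \gtrsim 30$). After adjustment
(BH by default; Holm, Hochberg, Hommel, Bonferroni and BY are available, and
"FDR" is accepted as an alias of BH following the convention of
`p.adjust`), a pair survives when $|r|$ strictly exceeds the coefficient
threshold (default 0.5) and the adjusted p is strictly below 0.05. A feature
survives when it belongs to at least one surviving pair. Setting the
threshold to −1 disables filtering and passes everything downstream.

**Scenario B (model-selected).** The correlation module is bypassed
entirely. A first model is trained on all features; each feature receives an
importance score (normalized split importance for trees, the L2 norm of its
coefficients across labels for linear families) and features scoring at or
above the mean score are kept — the conventional default of model-based
selection. A second model is retrained on the kept features; all of its
outputs are written beneath a `FeaturesSelFromModel/` subdirectory, and the
tests verify this round never touches any correlation output.

**Models.** Six regression families map the normalized data matrix X to the
normalized label matrix Y: ordinary least squares, lasso, elastic net, their
multi-task versions, and per-label decision trees. The regularized families
are fitted by coordinate descent via glmnet with the penalty expressed in
the parameterization users of the reference implementations expect:
`alpha` is the penalty strength $\lambda$ and `l1_ratio` the L1 mixing
weight, so the single-task objective is
$\frac{1}{2n}\lVert y - Xw\rVert^2 + \lambda\,(\text{l1\_ratio}\lVert w\rVert_1
+ \tfrac{1}{2}(1-\text{l1\_ratio})\lVert w\rVert_2^2)$,
and the multi-task penalty replaces the L1 term with the sum of per-feature
L2 norms across labels (group sparsity: a feature is dropped for all labels
or none). Convergence control is inherited from the fitting library
(threshold 1e-7, at most 1e5 passes) rather than translated numerically from
other ecosystems, because the convergence measures are not commensurable;
both are configurable (`tol`, `max_iter`). Trees grow to purity by default
(`cp = 0`, minimum split 2, minimum leaf 1, depth at most 30) and report
importances from primary splits only, normalized to sum to one per label, so
a feature never used in a split scores exactly zero. Cross-validation uses
contiguous folds by default (a seeded shuffled variant is available), scored
by negative MSE over all labels; grid search exhaustively evaluates the
candidate product by mean CV score, breaking ties in favor of the earlier
grid entry.

**Normalization.** Three scalers are supported: standard scaling (mean 0,
*population* standard deviation 1), min–max to [0,1], and division by the
maximum absolute value. By default the scaler is fitted *independently* on
the training and on the test set — deliberate behavior of the platform this
package reimplements, preventing any leak of training statistics into test
evaluation at the cost of a small distribution mismatch between the two
normalized spaces; `scalerFit = "train_only"` offers the conventional
fit-on-train/apply-to-test alternative. Constant features map to 0 with a
warning. Labels are normalized with the same configured scaler as the data,
and predictions are reported in normalized label space (an inverse transform
is available).

## Evaluation

For each label with observed test values $y$ and continuous predictions
$\hat y$:

$$v = \frac{\mathrm{RMSE}(y)}{\mathrm{std}(y)}
   = \sqrt{\frac{\frac{1}{n}\lVert y-\hat y\rVert^2}
                {\frac{1}{n}\lVert y-\bar y\rVert^2}}
   = \sqrt{\mathrm{SSL}/\mathrm{SST}},
\qquad R^2 = 1 - \mathrm{SSL}/\mathrm{SST} = 1 - v^2.$$

The package computes $R^2$ both directly from the sums of squares and
through the $1 - v^2$ identity; with the population (ddof = 0) standard
deviation convention — used everywhere in the package — the two agree to
machine precision, including $v > 1$ (negative $R^2$). This is why the
population convention matters: with the sample convention the identity
acquires an $(n-1)/n$ factor and the two routes diverge.

**AUC-vs-dt sweep.** To ask "at which expression cutoffs can the regression
output classify a label as high or low", observed values are min–max mapped
to [0,1] and binarized at each decision threshold in {0.1, …, 1.0}: a value
strictly below dt becomes 0, a value at or above it becomes 1 (the boundary
goes to the high class, reading "falling below" strictly). Predictions are
never binarized; they are sent through the same affine map, which leaves
their ranking — and hence every AUC — unchanged. This rescaling is applied
regardless of the model-space scaler, reconciling a standard-scaled model
space with a [0,1] threshold grid; it is a documented design choice for
predictions outside [0,1], not a claim about what any upstream platform
does. The AUC is the rank-based Mann–Whitney statistic with ties credited
0.5; thresholds leaving all samples in one class give NA, excluded from
summaries. The headline AUC of a label is the maximum defined AUC over the
grid, reported with the dt range attaining it.

## Significance

Labels with headline AUC strictly above 0.9 and test $R^2$ strictly above
0.25 are gated into a permutation test; the high gate focuses the expensive
refits on confidently predicted labels. Each permutation shuffles the
label's *training* values, refits the model from scratch, and re-evaluates
on the untouched test split — a stronger null than merely permuting test
predictions, because it propagates through training. For separable families
only the tested label's submodel is refit; multi-task models are refit
jointly. The p-value is the plain exceedance fraction
$p = \#(\text{stat}_{perm} \ge \text{stat}_{test})/n_{perm}$ without the +1
smoothing, so a statistic exceeding all permutations reports exactly 0; an
opt-in `smoothedP` gives $(k+1)/(n+1)$. The default $n_{perm} = 100$
resolves p to 0.01 while keeping runtime proportionate.

**Which p-value calls significance.** Both the AUC and the $R^2$ permutation
p-values are computed and reported, but the significance call uses the $R^2$
p-value. The reason is structural: the headline AUC is a maximum over the dt
grid, and on a test set of $n$ samples there is always a threshold leaving a
single positive, where a permuted model's random ranking achieves AUC = 1
with probability $1/n$. The AUC p-value therefore has an irreducible floor
of roughly $1/n_{test}$ per threshold and cannot resolve below ~0.05 on
small test sets even for perfect predictors. The $R^2$ statistic is
continuous and carries no such floor. The AUC p-value remains in every
summary for inspection.

## Synthetic data: what it emulates, and what it does not

`syntheticDesign()` / `generateSynthetic()` produce paired tables shaped
like desk-scale case studies (default 120 samples, 40 imaging features, 30
labels). Imaging features are independent standard normals. Each planted
label is driven by a single informative feature (assigned round-robin among
the `nInformative` features) with effect scaled so the population
correlation with its driver is `targetR` (default $\sqrt{3}/2$, i.e. a
signal-to-noise variance ratio of 3), plus Gaussian noise, then min–max
mapped to [0,1] so the dt grid is meaningful end to end. Decoy labels are
independent uniform noise. The single-driver design is deliberate: with the
same total signal spread equally over four features, each individual
feature–label correlation would be
$\beta/\sqrt{4\beta^2+\sigma^2} \approx 0.43$ — below any useful correlation
threshold — so a multi-driver design at this SNR cannot be studied in the
correlation-filtered scenario at all. `nullDataset()` draws every column
independently for calibration tests.

What passing tests on these data do **not** show: real radiomic features are
strongly inter-correlated (size/shape/texture families), expression is
heavy-tailed count-derived data rather than uniform noise, effects are not
single-feature linear, and batch structure exists. The generator validates
the machinery — thresholds, identities, calibration, artifact contracts —
not biological discovery performance.

## Numerical and design choices

* Population (ddof = 0) standard deviation everywhere; exact $R^2 = 1-v^2$.
* Strict inequalities at every threshold (|r|, adjusted p, the gate, dt
  boundary to the high class).
* Zero-variance features: correlation recorded as r = 0, p = 1 with a
  warning; constant features scale to 0.
* Heat-map ordering: average-linkage agglomeration on the profile distance
  $1 - |\mathrm{cor}|$ between rows (and columns) of the coefficient
  matrix; a zero-variance profile sits at distance 1 from everything.
* Ties in grid search resolve to the earlier grid entry; fold assignment is
  contiguous unless shuffling is requested.
* Missing values are rejected at load — a metrics pipeline should fail
  loudly rather than impute silently.
* Sample matching is exact and case-sensitive.
* Grid-search normalization happens once on the full training set before
  CV, not per fold.
* Models persist as an RDS container with a versioned metadata header
  (checked at load); tree objects make a pure-JSON payload impractical, and
  the round-trip prediction identity is tested instead.
* The test-suite study sizes (120 × 40 × 30 with 20 replicates for recovery,
  500 replicates for calibration) were chosen as the smallest designs where
  the binomial/KS bounds in the acceptance properties are meaningful.

## Case-study presets

The configuration surface mirrors the published case-study settings this
kind of analysis uses: Pearson correlation at threshold 0.6–0.7, BH < 0.05,
imaging as data and genes as labels, standard scaling for both, test size
0.2, cv 2–3, and FPKM screening "value ≥ 5 in ≥ 30 samples"
(`screenMinValue = 5, screenMinSamples = 30`). The synthetic study in the
tests and in `scripts/acceptance.R` uses exactly this preset with a
regularization-tempered tree (`max_depth = 4`, `min_samples_leaf = 5`) and a
weakly penalized elastic net (`alpha = 0.05`, `l1_ratio = 0.5`) — sensible
a-priori choices for ~100 training samples and a strong single-feature
signal.

## Limitations

* Correlation p-values use the t-approximation only; for $n \le 10$ an
  exact permutation p would be preferable.
* The independent train/test scaler fit (the default, kept for fidelity)
  slightly biases test metrics when train and test distributions differ;
  use `scalerFit = "train_only"` for orthodox evaluation.
* No partial correlations, batch correction, survival models, or
  uncertainty intervals on AUC.
* Multi-task permutation tests refit the joint model per permutation and are
  correspondingly slower.
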