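# afexplain

Interpretable, hand-crafted-feature classification of short single-lead
heart-rhythm recordings into **N**ormal sinus rhythm, **A**trial
fibrillation, **O**ther rhythms and noisy (**~**) records — built for
people who need to know *why* a classifier called a record AF, not just
that it did.

Atrial fibrillation shows up in the RR-interval series (the times
between consecutive heartbeats) as an irregularly irregular rhythm:
high dispersion, no serial correlation, no respiratory modulation.
`afexplain` provides the full pipeline around that observation:

* **Synthetic data** — a seeded generator of labelled RR sequences and
  56-column feature tables with the 5050/735/2456/284 four-class
  structure, per-class RR dynamics (AR(1) sinus rhythm, Gamma AF,
  ectopy-laden "other", implausible noise) and a ground-truth mask of
  informative features for recovery studies.
* **Rhythm features** — the 21 RR-based features of the canonical
  56-feature set: HRV statistics (AVNN, SDNN, RMSSD, pNN50, SEM),
  heart-rate fragmentation (PIP, IALS, PSS, PAS), Lorenz-plot evidence
  scores (AFE, OrC, IrE, PACe), the coefficient of sample entropy
  `CosEn = SampEn(m, r) + ln(2r) − ln(mean RR)`, variation/alternation
  ratios, bimodality, and outlier counts.
* **Models** — native CART trees and random forests (Rcpp core) that
  expose per-node class counts, impurities `G(τ) = 1 − Σ p_k²` and
  recorded split decreases `ΔG(τ) = G(τ) − p_l G(τ_l) − p_r G(τ_r)`;
  ridge-penalized IRLS logistic regression maximizing the Bernoulli
  log-likelihood; a three-stage cascade (N → A → O/~); and an adapter
  for external classifiers.
* **Global importance** — four rankings of the same features:
  standardized |coefficients| (LR), accumulated impurity decrease
  `I_G(θ) = Σ_T Σ_τ ΔG_θ(τ, T)` (Gini), permutation importance (mean
  per-sample accuracy decrease, held-out or out-of-bag), and global
  SHAP (mean |φ| per class, averaged over classes) — plus rank-based
  incremental feature-selection curves.
* **Local explanations** — exact Shapley values
  `φ_i = Σ_S |S|!(M−|S|−1)!/M! · [v(S∪{i}) − v(S)]` by subset
  enumeration (interventional and tree-conditional coalition values),
  a permutation-sampling estimator for larger feature sets, executable
  local-accuracy / missingness / consistency axiom checks, and tabular
  LIME (global Gaussian perturbations, exponential proximity kernel,
  K-sparse weighted-least-squares surrogate).
* **Evaluation** — micro/macro precision, recall and F-scores, the
  per-class F and challenge-style mean-F aggregates, rank-statistic
  ROC/AUC, repeated stratified k-fold cross-validation, and the paired
  Wilcoxon signed-rank comparison.

Everything is data-frame-in / tibble-out, with `tidy()` / `glance()`
methods and `autoplot()` for rankings, attributions, curves and
confusion matrices.

## Worked example

```r
library(afexplain)

tbl <- simulate_feature_table(generator_config(n_records = 400, seed = 1))
tbl[1:3, c("record_id", "CosEn", "AFE", "lv_rr", "PSS", "label")]
#> # A tibble: 3 × 6
#>   record_id CosEn   AFE lv_rr   PSS label
#>   <chr>     <dbl> <dbl> <dbl> <dbl> <fct>
#> 1 R00001    -1.73    12     0  57.1 N
#> 2 R00002    -1.81    -5     0  40   N
#> 3 R00003    -1.81   -11     0  54.5 N
```

Low `CosEn` and negative `AFE` are what regular sinus rhythm looks
like: the RR series is predictable (low sample entropy) and the Lorenz
scatter of successive differences collapses onto the origin.

```r
forest <- fit_forest(tbl, n_trees = 50, seed = 2)
head(tidy(forest), 5)[1:4]
#> # A tibble: 5 × 4
#>   method feature score  rank
#>   <chr>  <chr>   <dbl> <int>
#> 1 Gini   lv_rr    3.65     1
#> 2 Gini   SEM      2.23     2
#> 3 Gini   min_rr   2.17     3
#> 4 Gini   max_rr   2.00     4
#> 5 Gini   RMSSD    1.87     5
```

The forest's impurity-based ranking puts RR-variability features on
top — `lv_rr` (the fraction of beat-to-beat changes exceeding 20 %) is
exactly the kind of feature a cardiologist would accept as an AF
marker.

```r
cv <- crossval(tbl, function(d, l) fit_forest(d, l, n_trees = 50, seed = 2),
               k = 4, seed = 3)
cv$summary[c("f_micro", "f_macro", "f_mean")]
#> # A tibble: 1 × 3
#>   f_micro f_macro f_mean
#>     <dbl>   <dbl>  <dbl>
#> 1   0.973   0.982  0.981
```

(Synthetic tables are far cleaner than real ECG features; these scores
validate the machinery, not clinical performance.)

```r
att <- explain_record(forest, tbl, "R00002", method = "shap")
head(dplyr::arrange(subset(att, class == "A"), dplyr::desc(abs(phi))), 3)
#> # A tibble: 3 × 6
#>   record_id class feature      phi base_value output_value
#>   <chr>     <chr> <chr>      <dbl>      <dbl>        <dbl>
#> 1 R00002    A     min_rr  -0.0140      0.0768            0
#> 2 R00002    A     lv_rr   -0.00942     0.0768            0
#> 3 R00002    A     al_rr   -0.00769     0.0768            0
```

This is force-plot data: starting from the base rate of the A class
(0.077), the record's long minimum RR interval and lack of large
variations push the AF probability down to 0 — the attribution sums
with the base value to the predicted probability exactly (local
accuracy).

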