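# macp — Mondrian aggregated conformal prediction for binary toxicity endpoints

`macp` builds classifiers for imbalanced binary molecular endpoints (e.g.
"very toxic" vs rest, where the toxic class may be outnumbered 11:1) that
output *prediction sets* with a per-class error guarantee instead of bare
labels. It is aimed at computational toxicologists and cheminformaticians who
need minority-class sensitivity without resampling, class weighting or
cost-sensitive tricks — and who need to state, per class, how often the model
is allowed to be wrong.

## The method

For a compound $x$ and candidate class $c \in \{0,1\}$, the nonconformity
score is the inverse predicted probability of the base scorer (a random
forest by default):

$$\alpha_c(x) = 1 - \hat P(c \mid x).$$

An inductive conformal predictor splits the training pool into a
proper-training part (fits the scorer) and a calibration part. **Mondrian**
(class-conditional) calibration ranks a test compound only against
calibration compounds *of the candidate class*:

$$p_c(x) = \frac{\#\{i : \alpha_{c,i} \ge \alpha_c(x)\} + 1}{n_c + 1},
\qquad
\Gamma^\varepsilon(x) = \{c : p_c(x) > \varepsilon\}.$$

Under exchangeability, $P\!\left(y \notin \Gamma^\varepsilon \mid y = c\right)
\le \varepsilon$ for *each* class — the property that keeps sensitivity and
specificity balanced under heavy imbalance. Ten such predictors, each with
its own independent stratified split of the pool, are combined per compound
and class by the **median** of their p-values. A prediction set can be
`{0}`, `{1}`, `{0,1}` (always counts correct) or `{}` (always an error);
*validity* is the per-class fraction of sets containing the true label,
*efficiency* the per-class fraction of single-label sets, and a model is
flagged valid when its observed error exceeds $\varepsilon$ by at most 2.5
percentage points.

The package also ships the surrounding pipeline: SMILES standardization
(salt stripping, stereo removal, organic filter, neutralization,
InChI-based tautomer normalization — OpenBabel via ChemmineR/ChemmineOB),
a configurable physico-chemical descriptor calculator, ingestion of external
feature/score files, stratified ensemble splitting, metrics/reporting, and a
synthetic-data generator that reproduces the imbalance regimes of binary
acute-toxicity benchmarks for fully offline testing.

## Worked example

A very-toxic-like synthetic study — 11:1 imbalance, 5,000 training and 2,000
evaluation compounds, moderately informative features, 10 ensemble members:

```r
library(macp)
res <- run_experiment(list(seed = 1, epsilons = c(0.15, 0.2)))
print(res$report, digits = 3)
#>        dataset method significance validity_1 validity_0 efficiency_1
#> 1 synthetic_vt     rf         0.15      0.862      0.857        0.736
#> 2 synthetic_vt     rf         0.20      0.787      0.798        0.868
#>   efficiency_0    SE    SP    BA
#> 1        0.688 0.812 0.791 0.802
#> 2        0.846 0.755 0.761 0.758
```

Reading the $\varepsilon = 0.2$ row: the minority (toxic) class keeps 78.7%
of true labels in its sets (error 21.3% ≤ 22.5%, so the model is valid) and
86.8% of toxic compounds get a single, unambiguous label; sensitivity (0.755)
and specificity (0.761) are nearly equal *despite the 11:1 imbalance* — the
Mondrian guarantee at work. The full outcome-by-class contingency is kept on
each metrics row:

```r
attr(res$metrics[[2]], "contingency")
#>           outcome
#> true_class single_0 single_1 both empty
#>          0     1176      369  281     0
#>          1       37      114   23     0
```

Lower-level entry points: `standardize_dataset()` / `compute_descriptors()`
for molecules, `mondrian_acp()` / `predict()` for fitting and prediction sets,
`calibrate_external_scores()` to conformalize score files from externally
trained models, `cp_metrics()` / `report_table()` for Table-style reports.

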