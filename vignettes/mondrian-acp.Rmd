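---
title: "Mondrian aggregated conformal prediction for imbalanced toxicity endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mondrian aggregated conformal prediction for imbalanced toxicity endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Binary toxicity endpoints are routinely imbalanced: a "very toxic" class may
be outnumbered ten-to-one by the rest of the screening collection. Ordinary
classifiers trained on such data buy accuracy on the majority class at the
expense of sensitivity on the minority class — precisely the class a safety
model must not miss. The usual remedies (over/under-sampling, class weights,
cost-sensitive losses) distort the training distribution and need tuning.

Conformal prediction offers a different contract. Instead of a single label,
the model emits a *prediction set* — `{0}`, `{1}`, `{0,1}` or `{}` — together
with a user-chosen significance level $\varepsilon$, and guarantees (under
exchangeability of the data) that the set misses the true label for at most a
fraction $\varepsilon$ of compounds. The *Mondrian* (class-conditional)
variant calibrates each class separately, so the guarantee holds *per class*:
the minority class gets the same error bound as the majority class, with no
resampling or weighting anywhere. This package implements that construction
for binary molecular endpoints, end to end.

## The procedure

### Inductive conformal prediction with a Mondrian taxonomy

The training pool is split into a *proper training* part, which fits a base
scorer (by default a random forest with its standard settings), and a
*calibration* part, which is never seen by the scorer. For a compound $x$ and
candidate class $c$ the nonconformity score is the inverse predicted
probability

$$\alpha_c(x) = 1 - \hat P(c \mid x),$$

so confident members of a class have small scores. For each class $c$, the
calibration compounds *whose true label is $c$* contribute their own-class
scores $\alpha_{c,1}, \dots, \alpha_{c,n_c}$ to that class's calibration
multiset. A test compound's p-value for class $c$ is its calibrated rank:

$$p_c(x) = \frac{\#\{i : \alpha_{c,i} \ge \alpha_c(x)\} + 1}{n_c + 1}.$$

Ties count in the test compound's favour, which makes the p-value
conservative; an optional smoothed variant replaces the tie mass with a
seeded uniform draw when exact (rather than conservative) validity is wanted.
The prediction set at significance $\varepsilon$ is

$$\Gamma^\varepsilon(x) = \{c \in \{0,1\} : p_c(x) > \varepsilon\}$$

with strict inequality (a p-value exactly equal to $\varepsilon$ excludes the
class). Because each class is calibrated only against its own compounds, the
coverage guarantee $P(y \notin \Gamma^\varepsilon) \le \varepsilon$ holds for
each class separately — this is what keeps sensitivity and specificity in
balance on imbalanced data.

### Aggregation over an ensemble

A single inductive predictor wastes the calibration fraction of the training
pool and inherits the variance of one random split. We therefore build $K =
10$ members, each with its *own* independent stratified partition of the pool
into proper-training (72%), an optional deep-learning validation part (8%,
folded into training for base learners that do not need early stopping) and
calibration (20%) — proportions typical of an acute-toxicity modelling
campaign. Per compound and class, the members' p-values are combined by the
sample median (for even $K$, the mean of the two central order statistics).
The median of conformal p-values is no longer an exact p-value, so the
aggregated predictor's validity is approximate; the accepted practical rule,
which this package adopts as its validity flag, is that the observed error
rate may exceed $\varepsilon$ by at most 2.5 percentage points.

### Evaluation quantities

For each class, *validity* is the fraction of evaluation compounds of that
class whose set contains the true label (a both-label set is always correct,
an empty set always an error), and *efficiency* is the fraction receiving a
single-label prediction — the informative outcome — regardless of
correctness. Sensitivity, specificity and balanced accuracy are computed over
the single-label predictions only, with class 1 (the minority, toxic coding)
positive; restricting to singles is the standard convention when these
point-prediction metrics are reported next to efficiency at a fixed
$\varepsilon$, and both/empty compounds carry no single-label decision to
score. Zero denominators yield `NA`, and report rows for models that fail the
validity flag have their efficiency/SE/SP/BA cells blanked: efficiency is
meaningless when validity has not been established.

```{r}
library(macp)
syn <- generate_tabular(synth_config(regime = "vt", n_total = 7000, seed = 1))
pool <- rownames(syn$x)[1:5000]; eval_ids <- rownames(syn$x)[5001:7000]
fit <- mondrian_acp(syn$x[pool, ], syn$labels[pool], K = 10, seed = 1)
sets <- predict(fit, syn$x[eval_ids, ], type = "set", epsilon = 0.2)
cp_metrics(sets, syn$labels[eval_ids], dataset = "vt-like", method = "rf")
```

## Structure standardization

Input SMILES pass through a fixed chain before any descriptor is computed,
delegated to OpenBabel via ChemmineOB/ChemmineR:

1. **Salt stripping and stereo removal.** The largest fragment by heavy-atom
   count is kept (ties broken by lexicographically smallest canonical SMILES,
   so the choice is deterministic); stereochemistry and isotope labels are
   dropped, since the downstream descriptors are 2-D.
2. **Organic filter.** The kept fragment must contain carbon and only
   elements from a configurable organic set (default H, B, C, N, O, F, P, S,
   Cl, Br, I); silicon and metals are excluded as `inorganic`.
3. **Neutralization.** Simple +1/−1 charges are neutralized where chemically
   possible (carboxylates, alkoxides, protonated amines); quaternary
   ammonium centres cannot be neutralized and are *kept*, charged.
4. **Tautomer normalization.** Heteroatom proton tautomers (e.g.
   2-pyridone / 2-hydroxypyridine) are mapped to one canonical form by a
   round trip through standard InChI, whose mobile-hydrogen layer treats such
   tautomers as one compound. Carbon-bound tautomerism (keto–enol) is *not*
   normalized — consistent with standard InChI semantics — which is an
   accepted narrowing: such pairs are rare among curated screening
   collections.

Unparsable strings become `parse_failure` records; a configurable maximum
SMILES length (default 200 characters, a stand-in for the sequence limits of
SMILES-consuming neural models) yields `too_long`. Every record is either
kept or excluded with exactly one reason, and exclusion counts always sum to
the input size. The chain is idempotent on its own output, which the test
suite asserts over a shipped fixture of hand-curated molecules whose expected
standardized forms were verified once against an independent cheminformatics
toolkit and frozen. Canonical SMILES spelling is toolkit-specific, so the
frozen forms are OpenBabel's; equivalence to the independent toolkit was
checked at the InChI level.

## Descriptors

The descriptor arm computes a fixed-length physico-chemical vector per
standardized molecule: OpenBabel's property set (molecular weight, logP,
TPSA, molar refractivity, hydrogen-bond donor/acceptor counts), ring and
aromatic-ring counts, per-element atom counts, and functional-group counts —
31 descriptors by default. The list ships as a YAML file
(`inst/extdata/descriptors.yaml`) and is configuration, not code: swapping it
changes the feature set without touching the package. Molecules for which any
descriptor fails are dropped with a warning, never imputed — silent
imputation would distort the exchangeability between calibration and test
sets on which the coverage guarantee rests. Externally computed feature or
score files (e.g. learned embeddings, or the class scores of a separately
trained neural model) enter through `load_external_features()` and
`calibrate_external_scores()`; the latter is bitwise-identical to the
internal calibration path given the same scores, which the tests assert.

## The synthetic generator

`generate_tabular()` draws two multivariate-normal classes with identity
within-class covariance, mean vectors $\delta$ apart along a random unit
direction, class counts at a configurable majority:minority ratio, optional
independent label flips, and a final row shuffle. Rows are i.i.d., hence
exchangeable across any downstream split — exactly the precondition of the
conformal guarantee, and the reason the generator exists: every statistical
claim in the test suite is checked on data where the assumption holds by
construction. Two presets mirror the class structure of the binary
acute-toxicity endpoints the package targets: `"nt"` (1.6:1) and `"vt"`
(11:1). Default study sizes are 5,000 training and 2,000 evaluation
compounds with $\delta = 1.5$ (a moderately informative feature space,
held-out AUC ≈ 0.85) and 16 dimensions — large enough that the minority
class retains a usable calibration set (~80 compounds per member) at 11:1
imbalance, small enough that a 10-member forest ensemble fits in well under
a minute.

What the Gaussians deliberately do **not** emulate: the heavy-tailed,
strongly correlated covariance of real descriptor matrices, activity cliffs,
or any train/evaluation distribution shift. Passing coverage tests on this
generator therefore demonstrates that the implementation honours the
exchangeability contract — not that real screening data satisfy it.
`generate_score_fixture()` likewise emulates external classifier score files
with Beta-distributed scores whose separation scales with a `quality` knob.

## Numerical and design choices

* **Ties and boundaries.** Calibration ties count toward the test compound
  (conservative); class inclusion is strictly `p > eps`; the validity flag is
  `error <= eps + 0.025` with `<=` at the boundary.
* **Rounding of split sizes.** Largest-remainder apportionment within each
  class, so part sizes sum exactly to the pool and stratification is exact up
  to integer rounding.
* **Seed discipline.** One master seed; member split seeds, learner seeds,
  smoothing tie-break seeds and generator seeds are derived by a fixed affine
  map (`derive_seed()`) on separate streams. Reruns are byte-identical.
* **Per-member re-splitting.** Each ensemble member re-partitions the pool
  independently rather than sharing one calibration set: this is the standard
  aggregated-conformal construction, it is what makes the member p-values
  diverse enough for the median to be meaningful, and it uses every pool
  compound for calibration in some member.
* **Degenerate inputs.** Single-class calibration sets, parts with fewer than
  two compounds of a class, duplicate ids, non-finite features and
  out-of-range scores are all hard errors at the point of entry, never
  silent.

## Known limitations

* **Aggregated validity is approximate.** The median of valid p-values is not
  itself a p-value; with 10 members the observed per-class error can exceed
  $\varepsilon$ by a few points (hence the 2.5-point tolerance), and for a
  minority class with only a couple of hundred evaluation compounds the
  sampling noise of the error estimate is of the same order as that
  tolerance.
* **Efficiency is not monotone in class separation.** Per-class validity
  pins the error rate near $\varepsilon$ at every separation; what changes is
  how the errors materialize. At moderate separation the error-budget
  compounds are genuinely ambiguous and receive wrong *single* labels (which
  still count as efficient); at extreme separation the calibration
  nonconformity distribution collapses onto zero, the wrong class is always
  excluded, and the same error budget can only surface as *empty* sets —
  so efficiency first rises with separation, then falls back toward
  $1 - \varepsilon$. The test suite documents this: the efficiency-vs-delta
  sweep rises from $\delta = 0.5$ to $2$ and declines at $\delta = 4$.
* **Tautomer scope.** InChI-based normalization covers heteroatom proton
  tautomers only; keto–enol pairs remain distinct.
* **Descriptor set.** The default 31-descriptor physico-chemical set is the
  toolkit's, not a reproduction of any particular published descriptor list;
  results that depend on the exact feature set should ship their own YAML.
* **Problem sizes.** The shipped tests and the acceptance script run the
  studies at 5,000/2,000 compounds with $K = 10$ and, for sweeps, smaller
  single-member fits — the package's chosen balance between statistical
  resolution and a test suite that runs in minutes.
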