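---
title: "Two-step MIC feature selection: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MIC feature selection: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mctwo)
```

## The problem

Expression profiling yields far more features than samples: a study may
measure $k$ in the tens of thousands for $s$ of a few dozen subjects. Fitting
a classifier to all features over-fits badly, so the practical question is
which handful of features carries the phenotype signal. `mctwo` implements a
two-step hybrid selector for binary phenotypes:

1. **Filter (McOne-style).** Score every feature by its maximal information
   coefficient with the class label, $\mathrm{MIC}(F_j, C)$; keep features
   above an irrelevancy threshold $r$; then eliminate features *dominated*
   by a stronger feature.
2. **Wrapper.** Run a best-first search over the filter's survivors,
   scoring each candidate subset by the leave-one-out balanced accuracy of
   a 1-nearest-neighbour classifier, $\mathrm{BAcc} = (Sn + Sp)/2$.

The filter makes the wrapper affordable; the wrapper shrinks the surviving
subset down to the few features that actually classify well together.

## The MIC estimator

MIC measures dependence between two variables by maximising the normalised
mutual information of a 2-D grid over all grids with at most
$B(n) = \max(n^\alpha, 4)$ cells:

$$\mathrm{MIC}(x, y) = \max_{\,l \times q \,\le\, B(n)}
  \frac{I^*(x, y; l, q)}{\log_2 \min(l, q)} \in [0, 1],$$

symmetric, 0 for independent variables, 1 for a noiseless functional
relationship. The package ships its own estimator with two backends behind
one contract:

* **`backend = "approx"`** (default): the standard estimation algorithm —
  equipartition one axis into $q$ rows (ties never split), collapse the
  other axis to value *clumps* (maximal runs pure in one row), coarsen to
  at most `clumps` $\times\, l$ superclumps, and choose column boundaries
  by dynamic programming. Both orientations are tried and the maximum
  taken, so the estimate is exactly symmetric.
* **`backend = "exact"`**: exhaustive enumeration of every partition of
  the axis carrying $\min(l, q) \le \sqrt{B}$ bins, with the other axis
  solved exactly by dynamic programming over value groups. This is the
  true maximiser, feasible up to roughly $n = 60$, and serves as the
  oracle the approximation is tested against.

Because the approximation searches a strict subset of the exact backend's
grids, `approx` $\le$ `exact` always holds — a one-sided guarantee the test
suite asserts on every family it generates. The empirical shortfall at
$30 \le n \le 60$ is typically below 0.1 and at most about 0.3 for
independent pairs and smooth noisy relationships; strongly oscillatory
signals at such small $n$ can lose more, because the single equipartitioned
row layout cannot align with the oscillation. Crucially, **feature–label
screening is exact**: a binary 0/1 label admits exactly one two-row
partition, and for two rows the column optimisation is provably optimal, so
the approximation and the oracle coincide on every relevance score the
selector uses (asserted to $10^{-12}$ in the suite).

Parameters: `alpha = 0.6` (grid-size exponent) and `clumps = 15` (superclump
factor) are the customary defaults of MINE-family estimators; neither is
normally worth tuning. Ties in values are kept together and broken by
original index order, so the estimator is deterministic. Constant vectors
yield MIC 0 with a warning; screening treats them as 0 silently.

## The dominance filter and its tie conventions

A feature is **relevant** iff $\mathrm{MIC}(F, C) > r$ — strictly, so at
$r = 0$ a constant feature (score 0) still fails. Relevant features are
visited in decreasing relevance; a candidate $F_i$ is discarded iff some
already-kept $F_j$ satisfies

$$\mathrm{MIC}(F_j, C) \ge \mathrm{MIC}(F_i, C)
  \quad\text{and}\quad
  \mathrm{MIC}(F_j, F_i) \ge \mathrm{MIC}(F_i, C).$$

Both comparisons are deliberately **non-strict**. Under strict comparisons
an exact duplicate column could never be eliminated when its relevance ties
its parent's — and *always* survives when the pair separates the classes
perfectly, since then relevance and pairwise MIC are both exactly 1. A
selector that keeps duplicate features fails its purpose, so dominance here
follows the convention of fast correlation-based filtering: ties resolve in
favour of the feature kept first (deterministic greedy order). Strict and
non-strict dominance differ only on exact ties, which for continuous data
essentially arise in the saturated cases above.

Pairwise MIC values are computed lazily — only candidate-versus-kept — so
the filter performs $k$ label screens plus at most
$|\text{relevant}| \times |\text{selected}|$ pairwise evaluations. The
worst case is quadratic in $k$, but whenever the relevance screen or the
dominance step removes most features the realised count sits far below
$k^2$; both counters are recorded on every fit (`$counters`) and bounded in
the test suite.

One caveat worth knowing: at $s \approx 100$ samples the null distribution
of MIC against a binary label concentrates near 0.2, so the default
$r = 0.2$ passes many noise features through the *relevance* screen. The
dominance step then does most of the pruning, and the wrapper the rest.
With fewer samples a higher $r$ is advisable; `relevant_features()` lets
you inspect the screen directly.

## The wrapper

`loo_bacc()` scores a subset by predicting each sample from its single
nearest neighbour (Euclidean distance over the subset's columns, no
rescaling — expression matrices arrive on a common normalised scale) among
all other samples, and returning $(Sn + Sp)/2$ of the pooled predictions.
Balanced accuracy, not accuracy, is the objective because a degenerate
majority-class predictor on an imbalanced cohort scores a seductive
accuracy but exactly 0.5 balanced accuracy. Determinism requires two
conventions: distance ties go to the smaller training index, and a query
equidistant from *all* training samples (no usable signal, e.g. constant
features) is predicted negative.

`best_first()` seeds its open list with every single-feature subset (the
empty set has no classifier, and seeding all singletons rather than only
the best one costs little and protects against a weak best singleton),
repeatedly expands the best-scoring open subset by each unused candidate,
and stops after `max_stale = 5` consecutive expansions without improving
the best score — mirroring the customary backtrack allowance of best-first
feature search — or when the open list is exhausted (`max_stale = Inf`
yields provably exhaustive exploration, which the tests exploit on small
candidate sets). Score ties prefer the smaller subset, then the
lexicographically earlier feature set: when models tie, the simpler model
wins.

## Baseline rankers, classifiers, evaluation

* **TRank** — Welch (unequal-variance) two-sample $t$, ranked by ascending
  $p$; the safe default for expression data where group variances differ.
* **WRank** — Wilcoxon rank-sum via the Mann–Whitney $U$ with normal
  approximation and tie correction (no continuity correction), ranked by
  ascending $p$.
* **ROCRank** — AUC by the rank formulation (ties count ½), ranked by
  $|\mathrm{AUC} - 0.5|$ descending, a deterministic surrogate for AUC
  significance that preserves the intended ordering and catches both up-
  and down-regulation.

On tie-free data WRank and ROCRank order features identically (the
rank-sum/AUC equivalence), and both are invariant under strictly monotone
transforms while TRank is not — all property-tested. `top_k()` implements
the fairness protocol for comparing a ranker with a subset selector: take
exactly as many top-ranked features as the selector chose.

Downstream classifiers are evaluation instruments, not contributions: NN is
native (same tie rules as the wrapper); SVM (linear kernel), Gaussian naive
Bayes and a CART tree are adapters over `e1071` and `rpart` with default
settings.

`internal_cv()` / `external_cv()` re-run the full selector inside every
training fold — never on the held-out fold — with class-stratified folds
(each class must have at least `folds` samples; unstratified splitting on
small balanced cohorts risks one-class folds). Per-run metrics pool
confusion counts across the run's folds before averaging across runs:
pooling is the variance-stable aggregation when folds are small. When a
selector returns no features (routine on null data), the fold predicts the
training majority class (ties to negative), keeping the harness defined and
making the no-bias check sharp. `paired_comparison()` uses the closed-form
paired $t$ with two documented degenerate conventions: all-zero differences
give $t = 0, p = 1$; constant non-zero differences give $t = \pm\infty,
p = 0$. `ei(acc, p) = acc - p/100` trades accuracy against model size;
`comparison_triplet()` tallies win/tie/loss over datasets.

## The synthetic generator

`synth_data()` draws the structure the selector is built to exploit:
informative features `Normal(0,1)` vs `Normal(delta,1)` across classes,
redundant features as a parent plus `Normal(0, rho)` copy noise
(round-robin parents), and independent `Normal(0,1)` noise. Defaults —
$50+50$ samples, 2 informative at $\delta = 2$, 4 redundant at
$\rho = 0.3$, 194 noise — are the package's reference study conditions: a
moderate, realistic effect size in a 200-feature, 100-sample regime.

What it does *not* emulate: probe/batch effects, heteroscedasticity,
correlated noise blocks, heavy tails, non-Gaussian marginals. Passing the
planted-recovery suite therefore shows the machinery recovers clean
Gaussian class shifts with redundancy among independent noise; it does not
certify performance on real microarray pathology.

## Problem sizes and observed behaviour

The test suite and `scripts/acceptance.R` size their computations to run on
one CPU in a few minutes: 100 (suite) / 60 (script) randomised
filter-vs-oracle datasets of up to 10 features and 40 samples; 100 / 60
search-vs-enumeration instances with up to 8 candidates; MIC backend
comparisons up to $n = 60$; 50 / 30 seeds of the default study conditions
for planted recovery; a 100-sample, 100-noise-feature null dataset for the
selection-bias guard.

Two behaviours of the default study conditions deserve note, both visible
in the recovery suite:

* The wrapper's objective is the LOO score itself, so the search can chain
  small LOO improvements by adding noise features that happen to repair
  individual leave-one-out errors. At $\delta = 2$ with 194 noise features
  the final subset usually holds 3–6 features but occasionally grows to
  8–9. This is honest wrapper behaviour, not a defect of the filter: the
  reported objective is optimistically biased for exactly the reason
  external cross-validation exists.
* On label-free noise, in-fold selection may still pick spurious features;
  the held-out accuracy of a 1-NN on such features falls near the
  class-mix rate $\pi^2 + (1-\pi)^2$, *below* the majority rate. Selection
  bias would show as accuracy **above** the majority rate, which the guard
  bounds; deviation downward is variance, not optimism.

## Known limitations

* MIC is estimated, not exact, for feature–feature pairs; dominance
  decisions near the threshold inherit that noise.
* The default $r = 0.2$ is permissive at $s \gtrsim 100$ (see above);
  there is no data-driven default for $r$.
* The wrapper optimises LOO BAcc and therefore over-fits it; report
  held-out performance from `external_cv()`, never the search objective.
* Binary phenotypes only; multi-class labels and regression targets are
  out of scope.
* The exact MIC backend is exponential in the enumerated axis's bin count
  and is intended for validation at small $n$, not production screening.
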