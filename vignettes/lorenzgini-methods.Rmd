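---
title: "Lorenz-curve Gini ratios and Bayesian-network marker selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lorenz-curve Gini ratios and Bayesian-network marker selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lorenzgini)
```

This vignette is the package's own account of the method it implements: the
model and its assumptions, the parameters that matter, the numerical and
design choices that were genuinely open, and what the synthetic benchmark
does and does not demonstrate.

## The procedure

The pipeline behind `marker_fit()` has three stages.

**Preparation — discretization.** Each gene's continuous expression vector
is modelled as a univariate Gaussian mixture fitted by EM, the component
count chosen by BIC among `k_candidates`. The fitted mixture is converted to
cut points at the posterior crossings between adjacent
(ascending-mean-ordered) components, so range 0 always holds the lowest
values and codes are monotone in expression. The assumption is that a
biologically meaningful gene has a small number of expression regimes
(off/low/high) that are approximately Gaussian on the analysed scale; genes
whose values are unimodal collapse to a single range and drop out of the
ranking (score 0), which is exactly the behaviour one wants from a filter.

**Step 1 — ranking.** For each gene the range-by-class contingency table
yields the dataset impurity `gini(D)`, the weighted index
`gini_A(D) = Σ α_i δ(i) (|R_i|/d) gini(R_i)`, the splitting status, and the
Gini ratio `LorenzGini = (gini(D) − gini_A(D)) / split_A(D)`. The α weights
come from per-range Lorenz coefficients (class-order correction); δ measures
similarity to neighbouring ranges (value-order correction). The top `top_k`
genes (default 250) form the candidate pool.

**Step 2 — wrapper selection and the classifier.** Candidate subsets are
scored by cross-validated accuracy of a discrete Bayesian-network
classifier: the class node is a root and a parent of every gene node, and
each gene may gain up to `max_parents` gene parents, added greedily when
they lower the AIC (`−logLik + free parameters`). Greedy and best-first
searches in both directions are implemented; best-first keeps an open list
of scored subsets, always expands the best one, and stops after
`stale_limit` (default 5) consecutive non-improving expansions. The final
subset is refitted with structure search and evaluated by repeated
stratified k-fold cross-validation.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k_candidates` | 1–4 | mixture orders offered to BIC. Including 1 lets unimodal genes opt out of the ranking; without it, EM must split noise genes and tends to shave off tiny outlier ranges whose near-zero splitting status explodes the Gini ratio (see Limitations). Up to 4 covers the off/low/medium/high regimes seen in discretized expression tables. |
| `top_k` | 250 | pre-selection size; large enough to keep redundant signal blocks and their complements, small enough for wrapper search. |
| `stale_limit` | 5 | backtracking budget of best-first search. |
| `search_k`, `search_repeats` | 5, 3 | the CV protocol *inside* the goodness function. A fixed internal seed makes goodness a pure function of the subset (cacheable); the heavier protocol is reserved for final reporting because the search evaluates thousands of subsets. |
| `max_parents` | 1 (final model), 0 (inside search) | gene-parent budget of the AIC structure search. The naive backbone inside the search keeps the wrapper loop linear in subset size; the final refit allows one gene parent (a second parent, `max_parents = 2`, is available). |
| `smoothing` | 0.5 | CPT pseudo-count; keeps every posterior strictly positive and is a standard choice for discrete classifiers. |
| `k_values`, `n_seeds` | 5–9, 50 | final evaluation: every k from 5 to 9, each repeated over 50 fold seeds, accuracies averaged with equal weight. |
| `effect` (generator) | 2 | between-class mean shift in within-class SD units; two SDs is a strong but realistic microarray effect for a true marker. |

One master seed derives all stage seeds (`derive_seeds()`), so any stage can
be re-run in isolation and two fits from the same control object are
bit-identical.

## Numerical choices

* **EM initialization** is deterministic: means at the k mid-quantiles,
  common variance, uniform weights. A variance floor of `1e-6` times the
  sample variance prevents singular components. Log-likelihood is asserted
  non-decreasing per iteration in the tests; convergence is a relative
  log-likelihood change below `tol = 1e-6` (cap 500 iterations).
* **Range boundaries** are the posterior crossing points between adjacent
  components, found by root search between the two means; when the weighted
  densities do not cross there (heavily overlapping components) the
  precision-weighted midpoint is used. Cutting at single crossing points
  makes codes monotone in expression by construction. Ranges left empty are
  dropped and indices compacted.
* **Lorenz areas** are trapezoid integrals over the uniform grid
  `x = 0, 1/n, …, 1`; the Equality Polygon uses the dataset's class totals,
  each range curve its own counts, both in the single dataset-level class
  order (ascending totals, ties stable). Re-sorting per range would destroy
  exactly the order sensitivity the construction exists for.
* **α normalization**: the absolute coefficients `|g_i|` are rescaled to sum
  to m, so all-equal coefficients reduce the weighted index to the standard
  one; if every coefficient is zero (each range proportional to the class
  margin) the weights fall back to 1. The sign of `g_i` is kept in
  `gene_score$lorenz_coefficients` for diagnostics; a weight must be
  non-negative.
* **δ convention**: δ(i) is the *mean closeness* `1 − distance` to the
  existing neighbours (one at the ends, two inside), with distance the
  half-L1 between class-proportion vectors. This implements the stated
  intent — emphasize a range whose class profile resembles its neighbours'
  ("harmonic" value orderings) — and keeps δ in [0, 1]. A raw sum of
  distances would point the correction the opposite way.
* **Combination**: α and δ both modify the same index and are combined
  multiplicatively; with either vector forced to 1 the other acts alone, and
  with both uniform the standard index is recovered exactly (property-tested
  on 1000 random tables).
* **Degenerate inputs**: a gene that never splits has `split = 0` and scores
  0 by convention; constant genes yield one range; an all-zero count vector,
  an empty table, or a cyclic parent structure raise errors.
* **Tie-breaks** are all deterministic: ranking ties by gene id; class
  prediction ties by class-set order; equal-goodness subsets prefer the
  smaller subset, then the one earlier in ranking order (matching the
  preference for cost-effective marker sets).
* **AIC direction**: the score is `−logLik + #parameters` and is
  *minimized*; the free-parameter count is the standard
  `Σ_nodes (arity − 1)·Π(parent arities)` with the class node contributing
  `n_classes − 1`.
* **ROC**: tied scores are grouped; the trapezoid AUC then equals the
  Mann–Whitney probability (property-tested against pair counting). The
  standard error is Hanley–McNeil and the 95% CI is `auc ± 1.96·SE` clipped
  to [0, 1] — a deliberate, documented choice among the several SE recipes
  in use.

## Open design choices

* **Default search = best-first forward.** Backward searches start from the
  full 250-gene pool and evaluate hundreds of ~250-gene cross-validated
  candidates per step, which is computationally disproportionate for a
  default; all four strategy/direction combinations remain available
  (`run_all = TRUE` runs them all and keeps the overall best).
* **Discretization and ranking precede cross-validation** (the procedure's
  Step 1 precedes Step 2), so the default accuracy estimates share the
  discretization and the pre-selection across folds. A strict leakage-safe
  mode (`cross_validate(..., x = expression_matrix)`) refits the
  discretization inside every training fold; fold-wise *re-ranking* of the
  pool is not implemented — with the wrapper in the loop it multiplies the
  whole ranking stage into every goodness evaluation.
* **Stratified folds by default.** With a 17-sample class and k up to 9,
  plain random folds can lack a class entirely; stratification keeps every
  fold testable. Plain random folds are available (`stratified = FALSE`),
  and a class smaller than k degrades to random spreading with a warning.
* **Goodness inside the search uses the naive backbone** (`max_parents = 0`)
  so that a goodness call costs `|subset|` CPT fits per fold; the final
  model is refitted with structure search. Structure search inside every
  goodness call is available via `eval_config(max_parents = 1)` and is what
  the best-first tests use to expose interactions a naive model cannot see.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` emulates the statistical regime the method targets:
many genes, few samples, strongly unbalanced classes (default 139/21/20/17),
a few informative genes whose class means are separated by a stated effect
size, blocks of redundant informative genes sharing a class profile and a
latent factor (default correlation 0.8), Gaussian within-class noise, and an
optional log-normal transform. Ground truth is emitted alongside the data so
tests never re-derive it.

It does **not** simulate probe-level artifacts, batch effects, heavy-tailed
or count-distributed noise, class-dependent variances, or gene-gene
dependence beyond the shared-factor blocks. Passing the recovery benchmark
(all 20 planted genes in the LorenzGini top 50; end-to-end cross-validated
accuracy ≥ 0.95 with a handful of markers, at 1000 genes × 200 samples)
therefore shows that the implementation ranks and selects correctly under
its own model assumptions — not that it will match that accuracy on real
arrays, where the discretization model is at best an approximation.

Problem sizes used in the shipped tests and the acceptance script —
1000 genes × 200 samples for recovery, 10-seed property sweeps at 150
genes, 1000-table oracle sweeps — were chosen so the whole suite documents
the method at meaningful scale while remaining routine to run.

## Known limitations

* With the α normalization above, a range whose class profile matches the
  dataset margin gets weight ≈ 0. A gene split into one huge near-marginal
  range and one tiny range then has weighted index ≈ 0 and splitting status
  ≈ 0, so its Gini ratio can be very large: near-degenerate splits can top
  the ranking even on pure noise. Including `k = 1` among the mixture
  candidates removes most such genes (unimodal noise collapses to a single
  range), and the wrapper stage ignores the rest (their cross-validated
  accuracy is no better than the majority rate), but users reading the raw
  ranking table should treat entries with `split` near 0 as artifacts of
  this weighting, not as signal. The `split` column is exported for exactly
  this reason.
* For tables whose ranges are all pure (every range a single class), the
  weighted and standard indexes are both 0 and α/δ cannot influence the
  score; the two order-bias corrections act only through impure ranges. The
  δ and α vectors are exposed per gene as diagnostics.
* The classifier assumes discretized inputs; prediction on new samples uses
  the training-time boundaries, so samples far outside the training range
  are clamped into the extreme ranges.
* AIC-guided structure search is greedy over a fixed ordering (the ranking
  order by default) and will not find edges that only help in combination.
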