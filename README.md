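# lorenzgini

Biomarker discovery from gene-expression profiles: a Lorenz-curve
generalization of the Gini index for ranking genes, wrapper subset selection
scored by a discrete Bayesian-network classifier, and a repeated k-fold
cross-validation / ROC evaluation harness. The package targets the typical
transcriptomics regime — thousands to tens of thousands of genes measured on
a few hundred specimens spread over several, often strongly unbalanced,
diagnostic classes (for example lung-tumour subtypes versus normal tissue) —
where the goal is a *small* set of marker genes plus a prediction model.

## The ranking statistic

Each gene's continuous expression values are first discretized into ordered
ranges `R_1 … R_m` (univariate Gaussian-mixture EM, component count chosen by
BIC). Crossing the ranges with the `n` classes `C_1 … C_n` gives a
contingency table, from which the classical quantities are

    gini(R_i)   = 1 − Σ_j p_ij²          (impurity of range i)
    gini_A(D)   = Σ_i (|R_i|/d)·gini(R_i)   (Gini index of gene A)
    split_A(D)  = 1 − Σ_i (|R_i|/d)²        (splitting status)

The plain Gini index has two order blindnesses. First, ranges whose class
counts are permutations of one another contribute identically even though
they concentrate on different classes (class-order bias). The fix builds a
Lorenz curve for every range over cumulative class shares, with classes
sorted by ascending total size, compares its area against the Equality
Polygon of the whole dataset, and turns the resulting signed coefficients
`g_i` into non-negative weights `α_i` (|g_i| rescaled to sum to m). Second,
the index ignores whether adjacent expression ranges carry similar class
profiles (range-order bias); the weight `δ(i)` is the mean closeness
(1 − normalized L1 distance) of range i's class profile to its neighbours',
emphasizing "harmonic" value orderings. The weighted index is

    gini_A(D) = Σ_i α_i · δ(i) · (|R_i|/d) · gini(R_i)

and the ranking statistic is the Gini ratio

    LorenzGini(A) = [gini(D) − gini_A(D)] / split_A(D),

with `gini(D) = 1 − Σ_j (|C_j|/d)²`. Genes that never split score 0.

Because even the top-ranked genes are often mutually redundant, the final
marker set is found by wrapper search (greedy or best-first with
backtracking, forward or backward) over the top-250 pre-selection, each
candidate subset scored by the cross-validated accuracy of a discrete
Bayesian-network classifier (class node a parent of every gene node,
optional gene–gene edges found by greedy AIC search, CPTs estimated with
pseudo-count smoothing). The selected model is evaluated by stratified
k-fold cross-validation for k = 5…9, repeated over many random seeds.

## Worked example

```r
library(lorenzgini)

spec <- synthetic_spec(n_genes = 300L, class_sizes = c(60L, 60L, 50L, 30L),
                       n_informative = 10L, effect = 2, seed = 42L)
gen <- generate_synthetic(spec)
fit <- marker_fit(gen$matrix,
                  control = marker_control(top_k = 50L, n_seeds = 10L,
                                           seed = 42L))
print(fit)
#> marker_fit: 3 marker gene(s) of 50 ranked
#> markers: gene0009, gene0002, gene0003
#> cross-validated accuracy 0.8841 (sd 0.0019, 50 runs)

fit$ranking[4:6, c("gene_id", "lorenzgini", "delta_gini", "split")]
#>    gene_id lorenzgini delta_gini   split
#> 4 gene0009   1.579008  0.6871845 0.43520
#> 5 gene0002   1.410462  0.6646098 0.47120
#> 6 gene0004   1.386702  0.6566725 0.47355
```

All three selected markers are planted informative genes; the 0.884 mean
accuracy is the equal-weight average over 50 (k, seed) cross-validation
runs (k = 5…9 × 10 seeds), and `summary(fit)` additionally prints the
pooled confusion matrix and the per-k accuracy breakdown. `predict(fit,
newdata)` discretizes new samples with the stored range boundaries and
returns per-class posteriors. Lower-level entry points (`em_fit`,
`build_contingency`, `lorenzgini_score`, `bayesnet_fit`, `learn_structure`,
`greedy_search`, `best_first_search`, `cross_validate`, `roc_curve`,
`serialize_model`) expose every stage individually; a thin command-line
front end lives in `inst/scripts/lorenzgini-cli.R`.

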