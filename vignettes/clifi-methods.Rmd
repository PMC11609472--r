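---
title: "Directional class-based feature importance in tree ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional class-based feature importance in tree ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clifitree)
library(dplyr)
```

## The problem

Multi-class classification of omics feature matrices — for example
reversed-phase protein array profiles across many tumour types — is routinely
done with tree ensembles, but the standard Gini importance answers only *how
much* a feature matters, not *for which class* or *in which direction*.
clifitree implements a class-based integrated directional feature importance
(CLIFI) that is computed *during* tree construction from the class counts of
every split, so a fitted model explains itself without post-hoc attribution:
a value near +1 for (feature, class) means the class concentrates above the
split thresholds on that feature (high expression), near −1 below it, and
near 0 means the feature splits the class evenly (no information).

Four ensemble variants share this metric: a bagged forest (`clifi_forest()`,
a random forest), a one-vs-all gradient-boosted tree model (`clifi_boost()`),
and latent-variable ("LAVA") versions of both in which a candidate feature is
replaced, at each node, by the first principal-component score of the feature
together with its neighbours in a user-supplied interaction graph (for
proteins, typically a STRING-derived network). The LAVA step injects
topological inductive bias: correlated, pathway-linked features enter the
decision function jointly.

## The split statistic

For one class at one split, let $L$ and $R$ be the class's counts in the left
and right child, $P = L + R$ its count at the node, and $A$ its count at the
tree's root (the tree's training subsample). Each child contributes a partial
log-likelihood-ratio (G-test) term against the expected half-split,
$M_1 = 2L\ln(2L/P)$ and $M_2 = 2R\ln(2R/P)$ (zero-count children contribute
0, mirroring the G-test's restriction to positive observed counts). The
importance is the combined statistic normalised by the perfect-split value
$2P\ln 2$, scaled by $P/A$, and signed by which child dominates:

$$
\mathrm{CLIFI} \;=\; \frac{M_1 + M_2}{2A\ln 2}\;
\operatorname{sign}(M_2 - M_1).
$$

With $A$ taken from the tree's root, a root split that sends the whole class
one way scores exactly $\pm 1$, a balanced split scores exactly 0, and
$|\mathrm{CLIFI}| \le P/A \le 1$ always. The implementation
(`clifi_for_split()`) uses counts rather than proportions; the two are
equivalent because the statistic is invariant under uniform scaling of
$(L, R, P, A)$ — a property the test suite asserts on random count tuples,
along with mirror antisymmetry (swapping children flips the sign) and
monotonicity of the magnitude as the split becomes one-sided. `sign(0) = 0`,
so perfectly balanced splits contribute exactly zero rather than inheriting
an arbitrary direction.

Records are aggregated per (feature, class) by summation over all splits and
trees (aCLIFI) and normalised by the largest absolute entry (naCLIFI) so that
models of different sizes can be compared on one colour scale.

### Attribution under latent splits

A latent split belongs to a whole neighbourhood. Its value is distributed
over the member features proportionally to $|v_f| / \sum_g |v_g|$, where $v$
is the loading vector, and — by default — signed by $\operatorname{sign}(v_f)$
so that a feature entering the component negatively keeps a direction
congruent with its raw values. The unsigned alternative (every neighbour
inherits the split's sign) is available via `signed = FALSE`; the signed mode
is the default because directionality with respect to the measured value is
the property the metric is designed to expose.

### Boosted models and error labels

Inside a boosted regression tree the training target is a pseudo-residual,
not a class, so the tree's "classes" are the distinct residual values
(*error labels*; residuals are rounded to 10 decimal places first so that
float jitter does not split a label). CLIFI is computed per error label and
reconciled to true classes by $\mathrm{CLIFI}_h = \sum_i S_{hi}\,
\mathrm{CLIFI}_i$, where $S_{hi}$ is the share of class $h$'s samples
carrying label $i$ in that tree's training sample. Error labels are resolved
per tree; after the first round residuals are nearly sample-specific, so
late-round records are individually tiny and the early rounds dominate the
aggregate, which matches the stagewise logic of boosting.

## Tree growth and its parameters

Trees are CART: at each node `max_features` candidate anchors are drawn
without replacement (`"sqrt"` by default, the standard forest heuristic);
for each candidate the split search scans midpoints of adjacent sorted
distinct values and maximises the Gini decrease (classification) or the
total sum-of-squares decrease (regression). Ties in gain are broken towards
the lowest anchor index, then the lowest threshold, making trees fully
deterministic given their seed. Growth stops at purity, below
`min_samples_split` (default 2), or when no sampled candidate admits a valid
split; there is no depth limit. Constant columns return a no-split sentinel
rather than an error.

In LAVA mode the candidate's neighbourhood submatrix is column-centred on
the *node's* samples (not variance-scaled — the decomposition is of the
covariance structure, and features on one platform share units) and
projected onto its first right singular vector; the vector's sign is fixed
so its largest-magnitude element is positive, which pins down both routing
and the direction of importance attribution. Node-local centring is used
because the latent step is defined at the moment a split is evaluated; this
also makes routing self-contained (each split record stores its centre,
loadings and threshold). A zero-variance submatrix falls back to a unit
loading on the anchor with all-zero scores. Singleton neighbourhoods take
the plain-split path (loadings $[1]$, centre $[0]$), so a distance threshold
of $\theta = 0$ reproduces the plain models *bit for bit* — the package's
central equivalence invariant, asserted for forests, boosters and their
CLIFI tables.

Ensemble defaults mirror standard practice for this model family: forests
use 150 trees and an 80% per-tree subsample drawn *without* replacement
("80% of samples per tree" reads as subsampling; classic bootstrap is
available via `replace = TRUE`); boosters use all samples, 130 rounds and
learning rate 0.1, with the same per-split feature subsampling as the
forests. Boosting scores start at zero for every class and accumulate
$\eta\,\gamma$ leaf updates with the K-class Newton step
$\gamma = \frac{K-1}{K}\,\sum r \big/ \sum |r|(1-|r|)$; a zero denominator
yields 0 with a warning. Softmax probabilities are computed with a max
shift; arg-max ties resolve to the first class in the class list. Per-tree
seeds are derived from the master seed by a counter, so results do not
depend on evaluation order.

## The feature network

`parse_interaction_table()` reads STRING-style edge lists (two identifiers
plus a combined confidence score; 0–1000 scores are rescaled to 0–1),
keeps edges at or above the confidence threshold (default 0.7, the usual
"high confidence" STRING cut), and deduplicates undirected pairs.
`build_feature_distance_matrix()` joins the edges to a feature→gene map:
features sharing a gene, and features whose genes interact, are adjacent;
distances are shortest-path hop counts (the consistent completion of
integer-valued distance parameters over adjacencies), the diagonal is 0 and
unreachable pairs are `Inf`. Identifier matching is exact after whitespace
trimming; unmapped features degrade to self-only neighbourhoods with a
message. `neighbourhoods(D, theta)` thresholds the matrix into the
per-feature index sets used by the LAVA step; sets are monotone in
$\theta$, and $\theta$ has *no default* in the pipeline — sensible values
are data-dependent (1 restricts a protein to direct gene-level partners,
2 adds one further hop) and the choice materially changes which features
are pooled, so it must be stated explicitly.

## Synthetic data

`iris_with_noise()` appends three label-free noise columns to the four
Fisher Iris measurements — Gaussian (pooled mean and SD of the original
measurements), uniform (pooled min–max range) and bimodal (equal mixture of
two Gaussians centred $\pm 1.5$ pooled SD around the pooled mean, component
SD half the pooled SD; the constants are fixed and documented here). The
noise families probe the importance metric under different null marginals.
`permute_within_columns()` shuffles every feature column independently,
preserving marginals while destroying all label and inter-feature structure
— the standard negative control.

`synthetic_planted()` emulates the structure of a multi-class proteomics
matrix where ground truth is unknowable in real data: baseline Gaussian
features, class-specific shifts of $\pm 1.5$ noise-SD for planted
(feature, class) pairs (two per class by default), and correlated blocks
(shared latent factor, within-block correlation 0.7) pairing each
informative feature with an otherwise-null partner, mirroring how
interacting proteins co-vary. The generator emits the truth table and a
block-distance matrix, enabling direction-recovery checks and giving LAVA
models genuine neighbourhoods. The defaults (4 classes × 30 samples, 20
features) are sized so that a 100-tree forest recovers every planted
direction while the whole 10-replicate sweep stays fast. What these
generators do *not* emulate: missingness and imputation artefacts, batch
effects, heavy-tailed abundance distributions and class imbalance of real
tumour panels — passing tests on them demonstrates correctness of the
machinery, not field performance.

## Evaluation protocol

`stratified_three_way_split()` allocates each class proportionally with
largest-remainder rounding: 30% test, then 20% of the remainder for
validation (≈56/14/30 overall). `classification_report()` returns accuracy
and support-weighted precision/recall/F1 — weighted F1 is the primary
summary; macro F1 is emitted alongside because the two labels are easy to
conflate and both views are informative — plus per-class rows; a class never
predicted contributes precision 0. `hyperparameter_search()` is a plain grid
(trees 100–180 by 10; rounds 10–150 by 10; learning rates 0.1/0.2/0.3)
selected on validation weighted F1 with ties to the smaller model.
`proximity_matrix()` counts co-leaf frequencies over trees; it is exported
(CSV) for external embedding (e.g. UMAP) rather than embedded here.
`run_pipeline()` ties these together from a flat key–value config and
writes per-run and mean±SD metrics, CLIFI tables and the proximity matrix
as comma-separated artifacts. The `impute_k` key is accepted for provenance
only: matrices must arrive complete (impute upstream, e.g. k-nearest
neighbours with k=5, before the pipeline).

## Statistical evaluation of CLIFI distributions

`class_difference_tests()` applies a Kruskal–Wallis omnibus test per
feature across classes, follows significant features (BH-adjusted at 0.05)
with pairwise Wilcoxon rank-sum tests, and BH-adjusts all p-values. A
caution that shaped the package's own evaluation design: split-level
records are *dependent* within a tree and within a data draw, so feeding
per-split records of a single fitted model to rank tests is
anti-conservative — with a hundred trees re-measuring the same finite
sample, even label-permuted data yields "significant" class differences.
The sound unit is one aggregated value per independent replicate (fresh
data draw and model seed), built with `new_clifi_table()` from per-replicate
aCLIFI values; the acceptance suite evaluates the no-signal behaviour this
way, with 20 replicates, mirroring the repeated-initialisation protocol
under which such distributions are usually reported. On that design the
noise features show no significant class differences while the real Iris
measurements remain highly significant.

A related caveat applies to the location of null distributions: with
n = 150 samples a single noise draw carries a finite-sample association
with the labels, so one model's record mean for a noise feature fluctuates
by a few hundredths around zero from draw to draw; only averages over
independent draws converge to zero. The acceptance suite's ±0.02 bound on
20-replicate means sits within this sampling noise (≈1.3 SD for the
bimodal noise feature), so that check can fail for individual seeds without
indicating a defect.

## Numerical and design choices

* Thresholds are midpoints of adjacent distinct values; degenerate nodes
  (all-zero counts) raise errors; constant columns return sentinels.
* The SVD falls back to an eigendecomposition of the cross-product on the
  rare non-convergence; both paths produce identical loadings up to the
  sign rule.
* Model JSON serialisation writes doubles at 17 significant digits, the
  minimum that round-trips IEEE doubles exactly; reloaded models reproduce
  predictions, proximities and CLIFI tables identically.
* Problem sizes used by the test and acceptance suites — 100-tree forests
  and 7-round boosters on the 150-sample Iris fixtures, 20 evaluation
  replicates, 10 direction-recovery replicates of the default planted
  design — were chosen as the smallest sizes at which the stochastic
  claims stabilise.

## Known limitations

* Oblique splits are restricted to the first principal component of a
  neighbourhood; no pruning, no surrogate splits, no missing-value
  handling.
* Boosting has no early stopping, shrinkage schedule or regularisation
  beyond the learning rate.
* The RF-vs-boosting performance ordering on small benchmarks is
  protocol-sensitive: with fully grown regression trees a few boosting
  rounds can match a forest, so comparisons should average over full
  replicates (data draw, split and model seed), as the acceptance suite
  does.
* CLIFI explains the *model on its training data*; out-of-sample
  explanation (ancestor counts taken from a test set) is a natural
  extension but is not implemented.
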