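---
title: "Walk-back signature removal: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walk-back signature removal: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(walkback)
```

## The problem

Astrocytes (and glia generally) resist the classification machinery that
works so well for neurons.  Their transcriptomes are dominated by
*functional-state* programs — inducible metabolic and activity signatures
shared across the whole organ — while the *regional* programs that tie a
cell to its anatomical origin (e.g. one hypothalamic nucleus such as the
ARC, PVN or SCN) are faint.  Clustering such data recovers states, not
places.  The walk-back strategy inverts the usual feature-selection logic:
instead of keeping the most variable genes, it identifies the gene programs
that vary most *consistently across many dataset pairings* — which is
exactly the signature of a shared state program — and removes them, so that
the residual signal available to a classifier is enriched for regional
identity.

`walkback` implements this strategy end to end: quality control, cell
selection, normalization, pairwise integration, rank aggregation of anchor
genes into a shared signature, signature subtraction, microclustering for
grouped cross-validation, two-stage feature selection with an SVM region
classifier, and the statistical machinery used to compare models.  A
synthetic-data generator with planted region and state programs makes every
stage testable against ground truth.

## The generator (and what passing tests do and do not show)

Counts are negative binomial,

$$x_{cg} \sim \mathrm{NB}\!\left(\mu_{cg},\ \theta_{\mathrm{sim}}\right),
\qquad
\mu_{cg} = (1-a)\, L_c\, b_g\, 2^{f\cdot \mathrm{act}(c,g)}\, \beta_{dg}
          \;+\; a\, A_g\, L_c ,$$

with per-cell library size $L_c$ (log-normal, median ~5,000 UMI over a
2,000-gene universe), baseline relative abundances $b_g$ (log-normal,
normalized to proportions), per-dataset per-gene batch factors
$\beta_{dg}$ (log-normal, sd 0.1), ambient fraction $a$ added as a
pseudo-bulk profile $A_g$ (the normalized baseline mean — ambient *removal*
is out of scope, so contamination is modeled in its simplest useful form),
and `act(c,g)` indicating whether gene $g$ belongs to the cell's region or
state program.  Doublets are sums of two random same-dataset cells and
inherit the first parent's region label: they are meant to be removed by
QC, not classified.

The default benchmark plants 4 regions (25 genes each, log2 fold-change
1.0) and 3 states (60 genes each, log2 fold-change 2.5) across 4 regional
datasets (1,200 cells each) and 2 whole-organ references (2,500 cells
each).  The literature this emulates states the state-dominance regime
qualitatively but gives no quantitative effect sizes; the defaults are
benchmark conventions chosen once — a 2-fold regional signal under a
5.7-fold state signal with moderate NB dispersion ($\theta_{\mathrm{sim}}
= 10$) — and are not tuned per experiment.

Two caveats follow.  First, in this design each regional dataset carries
one region, so dataset-level batch structure is partially confounded with
region — as it is in the real multi-dataset setting; the permutation null
(shuffled labels give MCC ≈ 0) shows the pipeline does not manufacture
signal, but high benchmark MCC should not be read as a field-accuracy
forecast.  Second, the generator omits several real-data features (gene
length effects, cell-size covariation with state, spatially graded rather
than discrete regions), so passing tests demonstrate internal correctness
and recoverability in a controlled regime, not performance on tissue.

## Normalization

Counts are normalized to analytic Pearson residuals under an NB null with
fixed overdispersion, $r_{cg} = (x_{cg}-\mu_{cg}) / \sqrt{\mu_{cg} +
\mu_{cg}^2/\theta}$ with $\mu_{cg} = n_c g_g / T$, clipped at
$\pm\sqrt{n}$.  The residual approach is named by the upstream methodology
without an explicit $\theta$ or clipping rule; we fix $\theta = 100$ (the
analytic-residual convention) and clip after computation, both
config-exposed.  All-zero genes get residual 0 rather than NaN.  HVGs are
ranked by residual variance with lexical tie-breaks so orderings are
deterministic.

## Integration and the shared signature

Each regional dataset is paired with each reference dataset.  Per pair:
joint Pearson residuals on shared genes, PCA (randomized SVD, 30
components), then iterative soft k-means with a batch-diversity penalty
and per-cluster ridge-estimated batch offsets subtracted from the
embedding — a deliberately simple linear corrector in the spirit of
soft-clustering integration methods, written here from scratch (it is part
of the contribution, not a wrapper).  A cluster-independent ridge-shrunk
per-batch centering runs first, since a batch-pure clustering would
otherwise leave a constant offset untouched.  Convergence is declared when
fewer than 0.1% of cells change their argmax cluster.

The pair's *anchor ranking* is all shared genes ordered by descending
residual variance on the concatenated pair (truncated at 2,000).  Robust
rank aggregation then scores each gene by
$\rho = \min_k \mathrm{Beta}(r_{(k)};\,k,\,m-k+1)$ over its sorted
normalized ranks $r_{(k)}$, with absent genes assigned the worst rank 1
(the standard convention for partial lists); the reported score is the
Bonferroni-style $\min(1, m\rho)$.  Aggregation is two-stage: per
reference dataset over its regional pairings, then globally over the
per-reference orderings.  Genes consistently near the top of every pairing
are shared state programs — the walk-back target.

Subtraction removes the top-$T$ signature genes (default $T = 100$; 250
and 500 are the other conventional choices) plus every remaining gene with
$|r| > 0.5$ Pearson correlation to a removed core gene.  The correlation is
computed on the Pearson residuals of the target data — the same layer the
variance ranking uses — and per target dataset; whether the upstream
procedure applied its correlation filter per pair or once globally is
ambiguous in its description, so the per-target choice is exposed as
configuration rather than guessed.

## Graphs and microclusters

Cells are embedded (first 6 integrated components, cosine metric), joined
into a `ks = 20` nearest-neighbor graph, reduced to mutual edges, and
reconnected with minimum-spanning-tree edges: `"min_tree"` adds only the
MST edges needed to connect components (the default; the upstream work
tested both variants without stating its final choice, so both are
provided), `"full_tree"` adds all of them.  Vertices under `k = 10`
neighbors are topped up with their nearest remaining candidates; the
result is connected by construction.  Fuzzy simplicial weighting assigns
$w_{ij} = \exp(-\max(0, d_{ij}-\rho_i)/\sigma_i)$ with $\sigma_i$ solved by
binary search so neighbor weights sum to $\log_2 k$, symmetrized by
$w + w' - ww'$.

Microclusters come from Leiden optimization of the constant Potts model
$Q = \sum_c [w_c - \gamma n_c(n_c-1)/2]$ at $\gamma = 0.0112$, run to
convergence from several seeded restarts (the best-quality partition is
kept; on small graphs this reaches the exhaustive optimum, which the test
suite verifies).  Resolution scans are scored by neighbor-resolution
adjusted Rand stability — a surrogate for multi-resolution reconciled-tree
indices, whose exact reconciliation machinery is out of scope — with a
0.05 tolerance window inside which the higher-quality partition wins, and
ties resolved toward the lowest resolution.  Several graph layers sharing
one vertex set can be partitioned jointly (`leiden_cpm_multiplex()`):
because CPM is linear in edge weights, the multiplex optimum is computed
exactly as the single-layer optimum of the weight-summed graph at
resolution $\gamma L$.  Cluster-level connectivity follows the
degree-product expected-weight convention, clipped to [0, 1].

## Feature selection and the classifier

Stage one unions the winners of three filter criteria — chi-square on
min-max-scaled values (non-negativity is required by that statistic), ANOVA
F, and a nearest-neighbor (3-neighbor) mutual-information estimator with a
tiny seeded jitter to break UMI ties — each tuned over (K, C) by repeated
stratified CV of an RBF SVM on weighted F-measure.  Filter scores are
computed once on the training matrix rather than refit inside each CV
fold; the final feature sets are identical (the winner is refit on the
full training data either way) and the CV's only job here is picking
(K, C).  Stage two ranks genes by model-based importance — maximum
absolute one-vs-rest L1-logistic coefficient, or boosted-tree gain — keeps
the top N, and fits an RBF SVM with scaled gamma
($1/(p\,\mathrm{Var}(X))$) and inverse-frequency class weights, compared
across the grid by stratified *grouped* 10-fold CV scored by multiclass
MCC, with every microcluster confined to one fold.  Grouping by
microcluster is the package's reading of the upstream grouped-CV setup,
whose groups are exactly the microclusters it constructs.  The upstream
description "encoded region classes as sorted proportions of each class"
is ambiguous; it is implemented as inverse-frequency class weighting with
a config switch, rather than guessing intent.  Ties in the grid go to the
smaller feature count, then the smaller C.  The ad hoc refit restricts the
universe to genes expressed in more than 10 cells in every reference
dataset (strict inequality) before re-running selection.

The train/test split assigns each cell to training with probability
$p = \min(1, \max(0.9, 1000/N))$; for $N \le 1000$ this reaches 1 and the
test set is empty, which the implementation allows with a loud warning
rather than silently resampling.

## Statistics

Model comparisons use the corrected resampled t-test,
$t = \bar d / \sqrt{(1/J + n_{\mathrm{test}}/n_{\mathrm{train}})\, s_d^2}$
with $J-1$ degrees of freedom and a right-tailed alternative, and its
Bayesian counterpart: a Student-t posterior for the mean difference with
the same corrected scale, reporting P(better), P(worse) and P(practically
equivalent) within a ROPE of half-width 0.01 on the MCC scale (the
upstream account reports the three-way comparison without a width; 0.01
is this package's default).  Multiclass MCC uses the Gorodkin
confusion-matrix form with the 0/0 → 0 convention.  The marker test is a
per-gene logistic LRT per cluster with BH correction and an FDR < 0.001
flag; the hurdle test combines a 2×2 detection G-test with a Gaussian LRT
on detected values (χ², 2 df), deliberately omitting the
cellular-detection-rate covariate of richer hurdle models (a config flag
away, not a default).

## Numerical choices and degenerate inputs

Randomized SVD (10 oversamples, 2 power iterations, deterministic sign
convention) backs every PCA.  Zero-distance edges from duplicate points
are kept in sparse graphs via a tiny positive sentinel.  Fuzzy calibration
targets are reached within 1e-5 by 64 bisection steps; unreachable targets
(fewer distinct neighbor distances than the target requires) saturate at
the largest bracket.  EM for the mitochondrial mixture falls back to
keeping all cells on non-convergence; a constant mitochondrial fraction
short-circuits to "keep all".  Detection means raw count > 0 throughout
("detected" is not thresholded upstream).  Gene matching across datasets
is by gene id, duplicates are an error (collapsing by summation would
corrupt signatures), and absent metadata columns are created as
`"unknown"` so unlabeled reference data flows through.

## Problem sizes

The shipped benchmark runs the full pipeline on the default collection
(~9,800 simulated cells before QC, 2,000 genes) with grids pared to the
configurations that matter at this scale: chi2/F/MI prefilter with K ∈
{500, 250} at C = 10 under 3-fold CV, and L1-logistic selection with two
feature budgets at C = 10 under grouped 10-fold CV.  The full grids of the
procedure (K up to 2,000, C up to 1,000, boosted-tree parameter sweeps)
remain available through `prefilter_grid()` and `model_grid()` for larger
runs.  Oracle-equivalence tests run at deliberately tiny sizes (graphs of
≤ 8 vertices against exhaustive partition enumeration; rank aggregation
against direct binomial-tail enumeration for ≤ 5 lists over ≤ 20 genes)
because exactness, not scale, is what they certify.

## Known limitations

The integration corrector is linear per cluster and will not remove
nonlinear batch distortions.  The complexity filter default (0.80) is
calibrated for genome-scale universes and should be disabled or lowered
for small panels.  The benchmark's dataset-per-region design cannot
separate batch from region — a property of the emulated study design, not
of the estimator.  QC thresholds of the emulated workflow were per-dataset
and unpublished; defaults here are config-exposed starting points, not
reconstructions.  The shipped 22/59-gene inclusion/exclusion panels under
`inst/extdata/` are synthetic examples keyed to the generator's gene ids
(the originals are not printed in the upstream source); users supply their
own panels as one-gene-per-line text files.
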