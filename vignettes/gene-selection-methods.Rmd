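---
title: "Ranking genes in two-class expression profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking genes in two-class expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneRanker)
```

## The problem

A two-class expression study measures thousands of genes on a few dozen
samples — classically a leukemia subtype panel (~7000 genes, 72 bone-marrow
samples) or a prostate tumor/normal panel (~12600 genes, 102 samples). Only
a handful of genes carry class information; the rest are noise. Gene
selection reduces the matrix to a small, informative subset before any
classifier is trained, both to avoid overfitting and because the top-ranked
genes are themselves the biological product of the study.

`geneRanker` implements eight selection methods for a genes × samples
matrix with `+1`/`-1` sample labels, a repeated random 3-fold SVM benchmark
of the resulting gene sets, and a synthetic-data generator that plants
known differential genes so that every method can be validated without
external data.

All methods share one preprocessing step, `normalize_genes()`: each gene
row is centered and scaled to mean 0, SD 1 (population SD; the choice of
divisor rescales every row by the same factor per row and therefore cannot
change any ranking). Zero-variance rows map to all zeros rather than
erroring — real chips contain constant probes, and every scorer has an
explicit policy for them.

## The scores

Write $\mu_\pm, \sigma_\pm, m_\pm$ for the class means, SDs and sizes of
one gene.

**Parametric (higher score = more informative).**

* SNR: $|\mu_+ - \mu_-| / (\sigma_+ + \sigma_-)$, population SDs.
* t: $|\mu_+ - \mu_-| / \sqrt{\sigma_+^2/m_+ + \sigma_-^2/m_-}$, the
  Welch unpaired form with sample SDs.
* LSD (Fisher criterion): $(\mu_+ - \mu_-)^2 / (\sigma_+^2 + \sigma_-^2)$.

Denominators are floored at $\varepsilon = 10^{-12}$ so constant genes
score finitely; a gene constant in both classes with equal means scores
exactly 0. The absolute values make all three symmetric under label swap;
using a signed SNR would segregate up- and down-regulated genes into
opposite tails, whereas published top-25 lists mix both directions.

**Nonparametric (lower score = more informative).**

* TNoM: the minimum number of misclassified samples over all single
  threshold rules $\mathrm{sign}(ax+b)$ — every cut between distinct
  expression values, both orientations. Bounded by $\min(m_+, m_-)$ (the
  trivial rule that puts everyone on one side).
* MDMR: sort the samples by expression and count the minimum number of
  adjacent swaps needed to reach a perfect class split, i.e. the
  cross-class inversion count, minimized over the two modal targets (all
  `+` first / all `-` first).
* WEPO: robust z-score the gene, $z = (x - \mu)/\mathrm{MAD}$ with MAD the
  *mean* absolute deviation (that wording is deliberate — not the median
  form), then sum $|z_i - z_j|$ over every cross-class pair in the wrong
  order, minimized over the two orientations. This is a z-gap-weighted
  version of MDMR's swap count: each swap MDMR would need is punished by
  the amount of expression overlap it spans. The exact published
  punishment expression is not reproduced in the sources available to this
  package, so the implemented form is documented as a reconstructed
  instantiation and validated against its own exhaustive-enumeration
  oracle.

Tied expression values: a real threshold cannot separate equal values, so
TNoM only cuts between distinct values; for MDMR/WEPO ties contribute no
inversions (equivalently, the most favorable tie ordering is taken, which
is well defined and orientation-symmetric). Separability is one property:
TNoM = 0, MDMR = 0 and WEPO = 0 coincide for any gene with positive MAD,
and the test suite asserts this on a thousand random genes.

**RFGS** (random forest gene selection) borrows the "random subset + best
split" idea, not Breiman's full classifier: each cycle partitions *all*
genes into `n_groups` random groups (balanced sizes, a chunked uniform
permutation), builds a decision stump per group, and marks the group's
root gene — the gene whose best threshold split minimizes weighted Gini
impurity. Hits are accumulated over `n_cycles` cycles and averaged over
`n_runs` independent runs. Defaults follow the genome-scale protocol
(`n_groups = 1000`, `n_cycles = 100`, `n_runs = 10`, top 25 reported).

Implementation note: the root of a group depends only on each gene's own
best-split impurity, which the grouping never changes, so the impurity
vector is computed once and each cycle reduces to a partition plus a
per-group argmin. `root_gene()` exposes the stump search directly and is
tested against a brute-force scan of every (gene, cut, orientation)
triple. Impurity comparisons are rounded to 10 significant digits so that
mathematically tied splits compare as exact ties regardless of summation
order; ties go to the lowest gene index for determinism. Per run exactly
`n_cycles * n_groups` hits are distributed — the suite asserts this
conservation law on every run it touches.

**SVST** (support vector sampling technique) filters *samples* rather than
genes first: fit a linear soft-margin SVM (penalty $C = 1$) on all
samples, keep only the support vectors ($\alpha_i > 0$), and compute the
SNR ranking on that subset. The reasoning: samples far from the decision
boundary ($\alpha_i = 0$) only dilute the class statistics, while
on-margin ($0 < \alpha_i < C$) and violating ($\alpha_i = C$) samples
carry the classification-relevant signal. The default keeps all support
vectors; `policy = "unbounded_only"` restricts to on-margin samples, since
the geometric argument singles them out. Class statistics are recomputed
on the reduced set without re-normalizing rows (a `renormalize` flag
exposes the alternative). The recorded `gamma = 1/genes` parameter is
inert under a linear kernel and stored only for protocol fidelity.

The SVM fit itself is standard machinery and is delegated to libsvm via
e1071 (solver tolerance $10^{-8}$); the model is re-expressed as
`alpha`, `w`, `b` on the package's own label coding and the suite checks
dual feasibility, the KKT conditions at $10^{-4}$, agreement with an
independent QP solver (kernlab), the hand-solved two-point toy problem,
and the classical property that refitting on the support vectors alone
reproduces the hyperplane.

## The benchmark

`evaluate_method()` reproduces the repeated random 3-fold protocol: in
each of `n_repeats = 100` repeats the samples are split into 3 random
folds (stratified by class — unstratified 3-fold on 72 samples can produce
single-class validation folds); each fold serves once for validation while
the top-`k` genes are selected on the remaining folds and a linear SVM
($C = 1$) is trained on them. Reported per `k`: mean, min and max of the
300 fold accuracies, rendered in the `".95(.88 to 1)"` table style.

Gene selection happens *inside* the training folds by default
(`selection_scope = "per_fold"`). Selecting on the whole dataset before
cross-validating overestimates accuracy — the selection-bias problem — and
the package keeps that variant available (`"whole_dataset"`) precisely so
the asymmetry can be demonstrated: on pure-noise data the per-fold scope
stays at chance while the whole-dataset scope climbs well above it. One
subtlety the test suite documents: even the honest scope, *conditioned on
one finite noise dataset*, wanders around chance (measured 0.40–0.66
across dataset draws at 500 genes × 30 samples), because a finite dataset
contains accidentally label-correlated genes and re-folding the same data
never averages them away. Null checks therefore average over independent
null datasets, which restores the 0.5 level.

## The synthetic generator

`simulate_expression()` draws i.i.d. Gaussian noise
$N(\mathrm{baseline}, \mathrm{noise\_sd}^2)$ for every gene × sample and
shifts the `+1`-class mean of each planted gene by $\delta$ SD units in a
chosen direction. Presets `golub_like()` (7129 × 72, 47/25 split) and
`singh_like()` (12600 × 102, 52 tumor → `-1` first, 50 normal → `+1`)
emulate the two classical dataset shapes with 30 planted genes at
$\delta \in [1, 3]$.

What it does *not* model: gene–gene correlation, per-sample intensity
effects, batch structure, heavy-tailed microarray noise (available only as
explicit `df` / `sd_jitter` options for robustness checks). Two practical
consequences for interpreting results: recovery tests show that the
methods find mean-shifted genes in independent noise, not that they cope
with correlated probe sets; and on near-orthogonal synthetic data of this
kind essentially *every* sample becomes a support vector of the linear
SVM (so SVST coincides with SNR there), whereas correlated real data
yields the small support-vector subsets (tens out of ~100 samples) that
make SVST distinctive. Support-vector counts on real accessions are
dataset properties and are deliberately not acceptance quantities.

## Study conditions and test sizes

The validation protocol plants 10 genes at $\delta = 2$ among 500 genes
with 20 + 20 samples and requires each method to place at least 8 of the
10 in its top 25, over 50 generator seeds; RFGS runs at `n_groups = 50`
(≈10 genes per group, the genome-scale group-size regime scaled to 500
genes), `n_cycles = 50`, `n_runs = 3`. The single-plant RFGS check uses
$\delta = 3$, 50 genes, `n_groups = 10`, `n_cycles = 50`, `n_runs = 5`
over 20 seeds. Exhaustive oracles run at small sample counts
(every label sequence to $s = 8$ for MDMR's BFS swap-distance oracle;
500 random genes at $s \le 12$ for TNoM's cut enumeration; 200 for
WEPO's pair enumeration). These sizes were fixed as part of the test
design together with the effect sizes; they are the conditions under
which the pass/fail statements hold.

A related design note: per-realization monotonicity of RFGS hits in the
planted effect size is *false* — a $\delta = 0$ gene can separate the
classes by accident, and a weak real shift ($\delta = 1$) partially
destroys that accidental separation (measured in 5 of 20 paired seeds).
The suite therefore asserts monotonicity of the seed-averaged hit count
(measured 6.6 → 17.3 → 30.0 at $\delta$ = 0, 1, 3), which is the
well-defined expectation-level property.

## Numerical and policy choices

* Ranking ties (equal scores): broken by ascending gene index, stably, in
  every method — rankings are bit-reproducible.
* $\varepsilon = 10^{-12}$ floors score denominators; MAD below
  $\varepsilon$ marks a gene `degenerate` in WEPO output (score 0).
* Support-vector detection uses an $\alpha$ tolerance of $10^{-6} C$;
  numeric solvers leave dust at both bounds.
* Label files: the first class name in a CLS header maps to `+1` unless
  `positive_class` overrides it (the tumor/normal studies use
  normal → `+1`, tumor → `-1`).
* Duplicate gene IDs are rejected by default (`dedup = "suffix"` opts into
  disambiguation) because rankings are reported by ID.
* Per-sample (array-level) intensity rescaling is out of scope; only the
  per-gene z-step is implemented, and inputs are assumed already
  array-normalized.
* RNG: every stochastic entry point takes a `seed`; one root seed spawns
  per-run/per-repeat streams, so results are reproducible and runs remain
  independent.

## Limitations

Two-class designs only; no missing-value handling (impute upstream); no
p-values or multiple-testing control — these are *ranking* scores, not
tests; no nonlinear kernels; and the "biological relevance" of top genes
on real data is a literature question outside the package's computational
scope.
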