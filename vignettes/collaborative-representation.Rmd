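---
title: "Collaborative representation classification for expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative representation classification for expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcgene)
```

## The model

A gene-expression profile is a vector of thousands of per-gene measurements,
while a typical labeled cohort has only tens of samples per class. crcgene
classifies a query profile `y` by *coding* it as a linear combination of the
pooled training samples of **all** classes at once. With the training samples
as the columns of a dictionary `X = [X_1, ..., X_K]` (one contiguous block
per class, every column scaled to unit Euclidean norm), the code is the
ridge-regularized least-squares solution

    rho = argmin ||y - X rho||^2 + lambda ||rho||^2
        = (X'X + lambda I)^{-1} X' y .

Because the coding operator `P = (X'X + lambda I)^{-1} X'` does not depend
on the query, it is computed once per training set and reused for every
sample to be classified; coding a query is then a single matrix-vector
product. The class decision compares, per class, the regularized residual

    r_i = ||y - X_i rho_i|| / ||rho_i|| ,

where `rho_i` is the sub-vector of the code belonging to class `i`. The
numerator measures how well class `i`'s own atoms reconstruct the query from
the *joint* code; the denominator folds in a second discriminative signal —
the correct class tends to absorb most of the coding energy. The predicted
class is the argmin, with ties broken toward the lowest class index
(deterministic and testable). If a class's sub-code is exactly zero its
residual is an infinite sentinel; if every class hits the sentinel (a query
orthogonal to the whole training span) the classifier falls back to the
unregularized residual, which is then `||y||` for all classes, and reports
the first class with a warning.

The pooled, l2-regularized coding is what distinguishes this *collaborative*
scheme from the classical sparse-representation classifier (SRC), which
codes the query with a sparsity constraint. crcgene ships SRC as a baseline:
the code is produced by orthogonal matching pursuit (OMP) — greedily adding
the atom most correlated with the current residual and refitting least
squares on the selected support — and the decision uses the unregularized
per-class error `e_i = ||y - X_i alpha_i||`. The regularized ridge route
needs only one Gram-matrix factorization for any number of queries, which is
the practical argument for collaborative coding on expression panels where
`n` (samples) is far below `m` (genes).

### Why lambda matters

With more atoms than dimensions the Gram matrix `X'X` is singular, so the
unregularized least-squares code does not exist; `lambda > 0` is structural,
not cosmetic. The default is `lambda = 1e-3`: small enough that coding is
close to the least-squares limit in the under-complete (more genes than
samples) regime, large enough to keep the factorization well conditioned
when a projection makes the dictionary over-complete. The package refuses
`lambda <= 0`. Sensitivity can be explored by refitting `fit_crc()` over a
lambda grid; on the synthetic study conditions below, predictions are stable
across `1e-4 .. 1e-1`.

Numerically, `P` is obtained by a Cholesky solve of
`(X'X + lambda I) Z = X'` rather than an explicit inverse; the unit tests
pin the result to an independent QR solve of the augmented system
`[X; sqrt(lambda) I]` at 1e-8 relative tolerance.

### Query preparation

Dictionary columns are unit-normalized, and queries are passed through the
same projection (if any) and unit normalization, so training and test
vectors live on the same sphere. This makes the decision exactly invariant
to positive rescaling of a query — residual numerators and coding norms both
scale linearly, so every `r_i` ratio is unchanged. Expression units
therefore only matter through preprocessing (see the filter and the
`log2(x+1)` transform below), never through the decision rule itself.

## Compressive dimensionality reduction

To cut the cost of coding at microarray dimensions, features can first be
projected with a very sparse random sensing matrix. Entries are drawn as
`sqrt(rho) * {+1, 0, -1}` with probabilities `1/(2 rho)`, `1 - 1/rho`,
`1/(2 rho)`; `rho = 1` gives a dense Rademacher matrix and `rho = 3` the
classic sparse construction, both of which satisfy the
Johnson–Lindenstrauss lemma, so pairwise distances between sparse vectors
are approximately preserved with high probability. With `rho = 3` two
thirds of the entries are zero, and the matrix is stored sparsely — only a
uniform random generator is needed to build it.

Two scalings are offered because "distance preservation" must be stated on
a scale. The default divides by `sqrt(M)` so each entry has variance `1/M`
and `E||Rx||^2 = ||x||^2`; squared distances before and after projection are
then directly comparable and the restricted-isometry-style audit
(`estimate_distortion()`) checks
`(1-eps)||x1-x2||^2 <= ||Rx1-Rx2||^2 <= (1+eps)||x1-x2||^2` literally. The
alternative mode rescales every row to unit norm; the two differ only by
per-row scale, and the audit is meaningful on the default scale. The
projection is data independent, so one matrix (regenerated deterministically
from its seed) is shared across cross-validation folds; because the gene
prefilter can change the input dimension per fold, the matrix is rebuilt
from the same seed at the fold's dimension — folds with equal dimension
share an identical matrix. A flag redraws it per repetition instead.

## Preprocessing

Two standard steps precede classification:

* **Gene prefilter.** Per-feature two-sided two-sample t-test (Welch by
  default; pooled variance behind a flag) at `alpha = 0.05`, keeping
  features with `p < alpha`. With more than two classes the same screen is a
  one-way ANOVA F-test — an extension chosen because the two-sample test
  does not generalize directly. Constant features get `p = 1` and are never
  selected. No multiple-testing correction is applied by default (the
  screen is a preprocessing heuristic, not an inference); BH adjustment is
  available behind a flag. During cross-validation the filter is refit on
  each training fold by default so no information from held-out samples
  leaks into feature selection; a `global` mode reproduces the classical
  dataset-wide protocol, and the two can differ noticeably on weak signals.
* **log2(x+1) transform** for non-negative count-like units such as RPKM,
  applied before everything else when the input is on a raw scale.

## The synthetic study conditions

All quantitative claims in the tests are made on generated data, because
they are the only data whose ground truth is known exactly. The generator
emulates a labeled expression panel: `K` classes, a small informative block,
and Gaussian noise at `noise_sigma`. Informative features follow a
*marker-gene layout*: the block is split into K near-equal sub-blocks and a
marker is elevated by `effect_size * noise_sigma` in its own class only.
This keeps every pairwise class distance over the block equal, and — more
importantly — keeps the class signal subspaces distinct. (A symmetric
"+/- gap/2" layout looks natural but makes the two class directions
collinear, which no representation-based classifier can separate; marker
sub-blocks are also how real panels separate classes.) The default
conditions are 2 classes, 20 samples per class, 500 features with 20
informative, a 5-sigma gap: comfortably separable, and both classifiers
reach 100% leave-one-out accuracy there, while an `effect_size = 0` null
collapses to chance within binomial error.

An optional low-rank mode replaces independent features with
`loadings %*% latent factors + noise`: the noiseless part has rank at most
`redundancy_rank`, so features are highly redundant and the class signal
survives aggressive projection. The reduced-dimension audit uses this mode
with `redundancy_rank = 10` and a *dominant* class factor
(`effect_size = 100`). The dominance is deliberate: when the data are
projected to `M = 3` dimensions, the two projected class-mean directions are
frequently near-collinear by chance, and the accuracy profile stays flat at
such tiny `M` only when the within-class angular spread is much smaller than
the projected class separation. With a moderate factor the profile at
`M = 3` is seed-dependent; with a dominant factor it is flat to the full
dimension at every seed we generate, which is the regime the flat-profile
claim describes. Everything the generator does is Gaussian (a log-normal
switch exists for heavier tails); real microarray data have correlated
probes, batch effects and outliers that these fixtures do not model, so
passing tests demonstrate correctness of the algorithms under their stated
assumptions, not field performance on any particular clinical dataset.

```{r demo}
es <- generate_dataset(synthetic_spec(seed = 42))
es
loocv(es, crc_pipeline())
```

## Evaluation protocol

Accuracy is the fraction of correctly labeled samples — for two classes,
`(TP + TN) / (TP + FN + TN + FP)` with the first class as positive; the
multiclass case is the same overall fraction, with per-class counts also
reported. Leave-one-out CV rebuilds the dictionary (and, by default, the
gene filter) for each held-out sample and is fully deterministic for a fixed
pipeline. Repeated k-fold CV shuffles samples into k near-equal folds —
stratified by class by default so per-class proportions hold within one
sample per fold — and pools all folds' predictions into one per-repetition
accuracy (`correct / n`), which coincides with the per-fold average for
equal folds and stays well defined for unequal ones. The conventional
repetition count is 100; the examples and tests use fewer repetitions of
the same machinery, with problem sizes (40 samples, 500–1000 features)
chosen so the entire suite runs in a couple of minutes on a laptop.
The reduced-dimension sweep re-runs the chosen CV scheme at each target
dimension `M` and tabulates mean accuracy against `M`.

Degenerate cases are defined, not crashed on: a class with a single sample
cannot be classified correctly under LOOCV by construction (it is evaluated
anyway, with a warning); folds whose training portion cannot support the
filter fall back to all features; all-zero columns stay zero with a warning
and contribute nothing to any coding; dimensions exceeding the feature count
are skipped with a warning; duplicate sweep dimensions are deduplicated.

## Reproducibility

Every stochastic component — the generator, the sensing matrix, fold
shuffles — takes an explicit integer seed, and identical seeds give
bit-identical results. A cross-validation result serializes to a
per-repetition accuracy table plus a JSON sidecar of the complete pipeline
configuration; a projection serializes as its generator arguments (the
matrix is rebuilt, never stored). The `crcgene` command-line shim
(`exec/crcgene`) exposes `simulate`, `crossval` and `sweep` subcommands over
the same functions with a single top-level seed.

## Known limitations

* The classifier is linear in the dictionary atoms; no kernelized or
  weighted variants, and no dictionary learning.
* SRC's coder is OMP only, with a support budget defaulting to the smallest
  class size; exhausting the support would collapse the sparse code onto
  ordinary least squares and void the decision rule's premise.
* The l1-regularized coding objective is intentionally absent: the closed
  form this package is built around solves the l2 problem, and the sparse
  route is served by OMP.
* The gene screen is a marginal (per-feature) test; interacting features
  that are only jointly informative will not be retained.
* No batch correction, quantile normalization or probe-level modeling; the
  package expects a cleaned expression matrix.
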