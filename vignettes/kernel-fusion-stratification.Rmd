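---
title: "Kernel-fusion dimensionality reduction for patient stratification"
author: "fmkldr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-fusion dimensionality reduction for patient stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmkldr)
```

## The problem

Cohort studies increasingly observe the same patients through several
heterogeneous views: multi-omic assays (expression, methylation, miRNA),
or anatomical measures summarized over brain regions.  Each view has its
own scale, dimensionality and informativeness, and no single view
classifies patients best.  `fmkldr` integrates such views by learning a
weighted combination of per-view kernel matrices together with a
supervised low-dimensional embedding, and evaluates how well the fused
representation stratifies patients with a support vector machine.

## The model

Each view contributes one or more base kernels $K_1, \dots, K_M$ over the
same $N$ training samples.  Sample $i$ is represented by its slice matrix
$\mathbb{K}^{(i)} \in \mathbb{R}^{N \times M}$, whose $(n, m)$ entry is
kernel $m$ evaluated between training sample $n$ and sample $i$.  With a
kernel weight vector $\beta \in \mathbb{R}^M$ and a sample-coefficient
matrix $A \in \mathbb{R}^{N \times P}$, sample $i$ embeds as

$$ z_i = \big(A^\top \mathbb{K}^{(i)} \beta\big)^\top \in \mathbb{R}^P. $$

$A$ and $\beta$ are chosen by a graph-embedding criterion with the linear
discriminant graphs: the intrinsic affinity $w_{ij} = 1/n_c$ for
same-class pairs (class size $n_c$) penalizes within-class spread, while
the constraint affinity $w'_{ij} = 1/N$ anchors total spread.  The
induced scatter matrices are

$$ S^A = \sum_{i,j} w_{ij}\, (\mathbb{K}^{(i)} - \mathbb{K}^{(j)})^\top
   A A^\top (\mathbb{K}^{(i)} - \mathbb{K}^{(j)}), \qquad
   S^\beta = \sum_{i,j} w_{ij}\, (\mathbb{K}^{(i)} - \mathbb{K}^{(j)})\,
   \beta \beta^\top (\mathbb{K}^{(i)} - \mathbb{K}^{(j)})^\top, $$

with primed versions under $w'$.  Training alternates two generalized
eigenproblems: given $\beta$, the columns of $A$ are the eigenvectors of
$S^\beta a = \lambda S'^\beta a$ with the $P$ smallest eigenvalues
(normalized $A^\top S'^\beta A = I$); given $A$, $\beta$ is the smallest
generalized eigenvector of $S^A b = \lambda S'^A b$, scaled to unit norm
with nonnegative entry sum and, by default, clipped to the nonnegative
orthant so the weights read as convex-combination coefficients over the
base kernels.

## Why the chain ordering, and why the Laplacian identity

Each scatter term is a four-matrix chain product whose cost depends
strongly on parenthesization: the $(M, N, P, N, M)$ chain costs
$MNP(N + M) $-ish left to right but far less when grouped as
$\big((\cdot)^\top A\big)\big(A^\top (\cdot)\big)$.  `chainOrder()`
implements the classic $O(n^3)$ dynamic program over scalar-multiplication
counts $F(i,j)$ with the smallest-split tie-break; because the two chain
shapes never change across iterations, the trainer orders each exactly
once before the loop — an instrumented counter
(`chainOrderCallCount()`) verifies the "2 invocations per training run"
claim.  Costs are held in doubles, which represent integers exactly up to
$2^{53}$, far beyond any product count reachable at feasible $N$; an
arbitrary-precision type would add a dependency for an unreachable
overflow.

Even optimally ordered, the literal double sum over $(i, j)$ has $N^2$
terms.  Assembly therefore uses the graph-Laplacian identity
$\sum_{ij} w_{ij} (u_i - u_j)(u_i - u_j)^\top = 2\,U L U^\top$ with
$L = D - W$, which evaluates each scatter in one pass ($O(N^3)$ overall).
The chain-ordered double sum is retained (`method = "chain"`) and both
routes are tested against a naive double-sum oracle to $10^{-8}$
relative Frobenius error; they agree to round-off.

## Numerical choices

**Singular pencils.**  The constraint scatters are rank-deficient by
construction: the all-pairs graph centres the data (its Laplacian
annihilates the constant vector), and degenerate base kernels contribute
joint null directions.  A plain ridge on $S'$ makes those joint-null
directions the *smallest* eigenvectors (ratio $\approx 0/\varepsilon$),
which is exactly the wrong selection.  The solver instead restricts the
pencil to the numerical range of $S'$ (spectral cut at $10^{-10}$ of the
top eigenvalue) and whitens, so directions carrying no constraint
scatter — which cannot discriminate — are excluded outright.

**Embedding canonicalization.**  Both scatter forms are functions of
pairwise differences, so the embedding is defined only up to a
per-dimension offset, and the eigenvector normalization fixes its scale
arbitrarily.  The SVM harness therefore centres the training embedding
and rescales it to unit mean squared row norm before forming the fused
kernel $Z Z^\top$, applying the same affine map to held-out points.
Without this, a constant offset thousands of times the class gap can
dominate the kernel and collapse a fixed-cost SVM.

**Kernel bandwidths.**  A historical five-point Gaussian bandwidth grid
$\sigma \in \{10^{-6}, 10^{-3}, 1, 10^{3}, 10^{6}\}$ is provided as the
`kernelGrid()` default.  On features rescaled to $[-1, 1]$ this grid is
degenerate: small bandwidths give (near-)identity kernels and large ones
give all-ones-plus-$10^{-5}$ kernels.  An identity-like kernel is a
perfect in-sample overfitter — it can drive within-class scatter to zero
for *any* labels while carrying zero information about new samples — so
no in-sample criterion can rank views through it, and the alternating
optimization can oscillate between views.  For rescaled data the package
therefore recommends (and its synthetic studies use) the median
heuristic: one Gaussian kernel per view at the median pairwise distance
(`medianSigma()`, `medianKernelStack()`, `pipelineConfig(sigmas =
"median")`), which places every kernel at the scale of its view.  The
grid remains available for unscaled inputs and for counting-style checks.

**Fixed iterations.**  Training runs a fixed number of alternating
iterations (default 10) with no early stop; the per-iteration trace-ratio
objective is recorded in the model history.  Initialization is either the
$P$ leading eigenvectors of $\sum_m K_m$ (`init = "A"`, the default;
converges in practice in a few iterations) or the uniform weight vector
$1/\sqrt{M}$ (`init = "beta"`); both reach similar fits.

**Degenerate inputs.**  Constant feature columns map to the rescaling
midpoint rather than erroring, keeping dimensionality stable across
views; held-out values outside the training range are clipped into the
target interval; features missing in any sample are removed, never
imputed.  Ties in the chain-order split and in the best-repetition and
best-dimension selections always break toward the smallest index, for
determinism.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `P` | 5 | embedding dimension; must not exceed the constraint-pencil rank (2-class data offer one strongly discriminative direction, $c$ classes offer $c - 1$) |
| `nIter` | 10 | alternating iterations, fixed count |
| `init` | `"A"` | initialization of the alternation |
| `nonneg` | `TRUE` | clip kernel weights to the nonnegative orthant |
| `sigmas` | grid / `"median"` | Gaussian bandwidths per view |
| `cost` | 1 | SVM soft-margin cost (C-SVC, equal class weights) |
| `trainFraction` | 2/3 | holdout training fraction, unstratified draws |
| `nReps` | 20 | holdout repetitions |
| `level` | 0.95 | one-sided lower t confidence bound on the mean accuracy |

The reduced dimension doubles as the scan variable of
`dimensionScan()`, which tabulates mean accuracy against candidate
dimensions; the curve need not be monotone, and the winning dimension is
reported with a smallest-value tie-break.

## The evaluation protocol

`repeatedHoldout()` draws, in each repetition, a random 2/3 of the cohort
for training, fits *everything* on that split — feature removal is
structural, but rescaling statistics, kernels, the embedding and the SVM
are all training-only — and scores the held-out third.  The report
carries per-repetition accuracy and AUC (rank-statistic form, ties one
half), the best and mean accuracy, the one-sided lower t bound
$\bar x - t_{0.95, n-1}\, s / \sqrt{n}$ over the repetition accuracies,
and the ROC points of the best repetition.  The confidence level is a
parameter because both 90% and 95% reporting conventions occur in
practice.  The headline machine-readable metric is the mean.

## What the synthetic cohorts emulate — and what they do not

`makeMultiviewCohort()` draws class-conditional Gaussian views: a random
half of each view's features carries a mean shift of `effectSize[v]`
noise standard deviations between consecutive classes; views are scaled
by `scale[v]` to emulate heterogeneous magnitudes (the defaults differ a
thousand-fold, which min-max rescaling must undo); a `missingRate`
fraction of feature columns receives one missing cell, mimicking
features absent in a few subjects that are subsequently dropped (at the
default 3% rate, matching what feature removal typically costs in
practice).  The reference conditions are 90 samples in two balanced
classes and two 50-feature views of which only the first is informative
(effect size 4).  `makeRegionMeasures()` draws per-region Gaussian
measures around region-specific baselines, optionally class-shifted on
half the regions, as the fixture for the individual-network builder
(complete graph, edge weight $1/(|m_i - m_j| + 1)$; 78 regions give 3003
edge features, 12 give 66).

Gaussian class-conditional views make the linear-discriminant embedding
Bayes-consistent, so parameter-recovery tests are analytically
interpretable: the informative view should dominate the kernel weights
and a 4-standard-deviation shift should be perfectly separable.  Real
omics data are *not* Gaussian (counts, beta-values, batch effects,
survival-linked censoring are all absent here), so passing these tests
demonstrates the correctness of the optimization and plumbing, not
expected field performance.

## Problem sizes

The test-suite and the structural checks run at deliberately small
scale — cohorts of 20–100 samples, views of 6–200 features, kernel
stacks up to 60 matrices at $N = 100$, scatter-equivalence instances at
$N \le 12$, and 200 random chains of up to six matrices against
exhaustive parenthesization — sizes at which every fast path can be
compared against its brute-force oracle exactly.

## Known limitations

* Only the linear-discriminant graph pair is implemented; other graph
  embeddings (locality preserving, marginal Fisher) would slot into the
  same scatter machinery but are out of scope.
* Binary tasks are first-class; multi-class cohorts are handled by the
  embedding, but the evaluation harness is designed around explicit
  binary contrasts rather than one-vs-rest scaffolding.
* With two classes the pencil offers a single strongly discriminative
  eigendirection; additional embedding dimensions come from a (near-)
  degenerate eigenspace and are reproducible only as a subspace, not
  coordinate-wise.
* Whether the kernel weights should be nonnegative or merely the
  smallest generalized eigenvector is genuinely underdetermined in the
  method family; both behaviours are implemented (`nonneg`), with the
  convex-combination reading as the documented default.
* No imputation, batch correction, count transformations, or
  cross-validation variants; splits are unstratified by design, with
  redraw protection against single-class training sets.
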