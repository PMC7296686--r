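# fmkldr — fast multiple-kernel-learning dimensionality reduction

`fmkldr` stratifies patients from heterogeneous feature matrices — several
multi-omic assays, or ROI-network features built from per-region anatomical
measures — by fusing one or more kernel matrices per view into a single
supervised low-dimensional embedding, then classifying in that embedding
with a support vector machine.  It is aimed at biostatisticians integrating
multi-view cohort data where no single view classifies best.

## The method

Each view yields base kernels `K_1 … K_M` over the `N` training samples.
Sample `i` is represented by the slice matrix `𝕂⁽ⁱ⁾` (N × M, column m =
kernel m against all training samples) and embedded as

```
z_i = (Aᵀ 𝕂⁽ⁱ⁾ β)ᵀ ∈ ℝᴾ
```

where `β` (length M, unit norm, nonnegative by default) weights the
kernels and `A` (N × P) carries sample coefficients.  Both are optimized
alternately under a linear-discriminant graph embedding: the intrinsic
graph `w_ij = 1/n_c` (same-class pairs) is minimized against the
constraint graph `w′_ij = 1/N`, each step a generalized eigenproblem on
scatter matrices of the form

```
Sᴬ  = Σ_ij w_ij (𝕂⁽ⁱ⁾−𝕂⁽ʲ⁾)ᵀ A Aᵀ (𝕂⁽ⁱ⁾−𝕂⁽ʲ⁾)        (M × M)
Sᵝ  = Σ_ij w_ij (𝕂⁽ⁱ⁾−𝕂⁽ʲ⁾) β βᵀ (𝕂⁽ⁱ⁾−𝕂⁽ʲ⁾)ᵀ        (N × N)
```

The four-matrix chains inside these sums are parenthesized by a
dynamic-programming matrix-chain ordering (MCMO, `chainOrder()`), computed
exactly once per chain shape per training run, and the sums themselves are
evaluated through the graph-Laplacian identity `2 U L Uᵀ`, giving cubic
total cost.  The fused embedding feeds a precomputed-kernel C-SVC
(cost 1), and a repeated random holdout harness (2/3 train, 20
repetitions by default) reports per-repetition accuracy/AUC, the best and
mean, and the one-sided lower t confidence bound of the mean.

## Worked example

A synthetic two-view cohort (90 samples, two balanced classes; only view 1
carries class signal at effect size 4, view 2 is noise a thousand-fold
larger in raw scale):

```r
library(fmkldr)

cohort <- makeMultiviewCohort(simSpec(seed = 1))
views  <- lapply(cohort$views, function(v) minmaxRescale(dropIncompleteFeatures(v)))
stack  <- medianKernelStack(views)     # one Gaussian kernel per view
stack
#> KernelStack: M = 2 kernels over N = 90 samples
#>   gaussian: 2

model <- trainFMKLDR(stack, cohort$labels, P = 5, nIter = 10)
model
#> MKLDRModel: N = 90 training samples, M = 2 kernels, P = 5
#>   view weights: view1=1.000 view2=0.000
#>   final objective: 0.8 after 10 iterations
```

The kernel weights land entirely on the informative view — the noise
view is switched off.  (The trace-ratio objective of 0.8 reflects one
essentially zero-scatter discriminative dimension out of P = 5; two
classes admit exactly one.)  The full holdout evaluation:

```r
report <- repeatedHoldout(cohort$views, cohort$labels,
                          SplitScheme(nReps = 20, seed = 1),
                          pipelineConfig(sigmas = "median"))
report
#> EvalReport: 20 repetitions
#>   mean accuracy: 1.0000   best: 1.0000
#>   lower 95% confidence bound of mean: 1.0000
#>   mean AUC: 1.0000
```

At a 4-standard-deviation shift the cohort is perfectly separable, and
the pipeline recovers that: every held-out third is classified without
error in all 20 repetitions.  The chain-ordering component can also be
used standalone:

```r
ord <- chainOrder(c(4, 100, 5, 100, 4))   # the Sᴬ chain shape at M=4, N=100, P=5
ord
#> ChainOrder over 4 matrices (dims 4x100x5x100x4): minimal cost 4,080
```

against 5,600 scalar multiplications left-to-right.

A thin command-line front end over the same functions lives at
`inst/scripts/fmkldr-cli.R` (`simulate`, `evaluate`, `scan` subcommands);
`runPipeline()` drives the whole evaluation from a JSON config and writes
the report, per-repetition table, ROC points and a manifest.

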