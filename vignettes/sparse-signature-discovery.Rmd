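---
title: "Sparse mutational signature discovery with a fixed background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse mutational signature discovery with a fixed background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsesigs)
```

## The model

Somatic point mutations in a tumor genome carry the imprint of the
mutational processes that produced them. Each single-base substitution is
strand-collapsed so the mutated reference base is a pyrimidine, giving six
substitution types; together with the 16 combinations of 5' and 3'
flanking bases this yields 96 trinucleotide categories. A cohort of N
tumors is summarized by an N x 96 count matrix M.

Classical signature analysis factorizes M into non-negative exposures and
signatures, M ≈ αβ. This package fits the extended model

  M ≈ α₀ β₀ + α β,

where β₀ is a *fixed*, dense background signature representing clock-like
replication-error mutagenesis (SBS5-like / germline-like) and α₀ its
per-tumor exposures. The remaining K signatures β are estimated under a
non-negative LASSO penalty by minimizing

  ‖M − (α₀β₀ + αβ)‖²_F + λ‖β‖₁   subject to α₀, α, β ≥ 0.

Fixing β₀ prevents the flat background from being re-learned badly and
from contaminating the discovered signatures; the L1 penalty drives noise
entries of β to exact zeros so that discovered signatures are sparse and
well differentiated. The objective is not jointly convex but is biconvex,
so the solver alternates two exact subproblem solves:

* **exposures**: per-sample non-negative least squares over (α₀, αᵢ),
  solved by an active-set (Lawson–Han­son) method on the Gram system;
* **signatures**: a non-negative LASSO in β with α fixed, solved by
  cyclic coordinate descent; β₀ is never penalized or updated.

Both half-steps decrease the penalized objective, so the recorded
objective trace is non-increasing — a property the test suite checks on
randomized problems.

## The penalty scale

For any data set there is a smallest penalty Λ ("lambda_max") at which the
β-subproblem's minimizer collapses to the zero matrix. With the
squared-Frobenius loss written without a ½ factor, stationarity at β = 0
gives Λ = 2·max(αᵀR)₊ with R = M − α₀β₀. User-facing penalties are
expressed as a *fraction* of Λ (`lambda_fraction` in `[0, 1)`), which
makes values comparable across data sets and across K. Λ is computed once
per fit from the initial exposures and held fixed, so a single fit
optimizes one well-defined objective; recomputing Λ every iteration would
silently change the objective mid-fit.

## Initialization

Initial signatures come from repeated plain NMF (multiplicative updates,
best of `restarts` random starts by reconstruction error), seeded
deterministically. When a background is supplied, the NMF runs on the
non-negative part of the background residual M − α₀β₀ (α₀ from the
background-only NNLS fit) rather than on M itself. This is a deliberate
design choice: running the NMF on M wastes one component on the already
known background and, empirically, strands the alternating solver in
basins where one discovered signature stays mixed with the background. On
noiseless rank-(K+1) test data the residual initialization recovers the
generating factors essentially exactly, while initialization on M
plateaus near cosine 0.96 for one signature. The final fit still
optimizes the full model on M; only the starting point changes.

## Choosing K and λ: repeated bi-cross-validation

Neither the number of signatures K nor the penalty weight can be chosen
by training error — more signatures and less shrinkage always fit better.
Instead, a random 1% of matrix *cells* is held out, set to zero, and the
model fitted on the remainder; held-out cells are then predicted by
α₀β₀ + αβ, imputed back, and the fit repeated (5 rounds by default, which
stabilizes the predictions; later rounds warm-start from the previous
round's signatures, which accelerates convergence without changing the
fixed point). The mean squared error on the held-out cells at the last
round scores the (K, λ) pair. Fresh masks are drawn for each of the
repetitions (10 by default); within a repetition the same mask is used
for every grid pair so pairs are compared on identical held-out data.

Selection follows "lowest error in most repetitions": the modal
per-repetition argmin, with ties broken by lower median MSE, then smaller
K, then larger λ. A median-MSE rule is available as an alternative
(`select_model(..., rule = "median")`), since medians over repetitions
are the natural tabulated summary.

Throughout, `K` counts *non-background* signatures; totals reported to
the user add one when a background is fixed, and every serialized
artifact names this convention in its header.

## The background presets

Two presets ship with the package: `"germline"` (default), patterned on
the human germline de novo mutation spectrum, and `"sbs5"`, patterned on
the ubiquitous flat SBS5-like spectrum. Both have the four `N[C>T]G`
rates overwritten by their `N[C>T]A` counterparts (then renormalized to
sum 1 — the vector is used as a probability spectrum, and exposures
absorb scale), so that deamination of methylated CpG remains available to
a dedicated discovered signature. **The packaged vectors are synthetic
stand-ins**: the published preset tables are not redistributable with
this package, so dense clock-like spectra were constructed with the same
documented properties — full support over the 96 categories, C>T and T>C
dominance, CpG adjustment, and a mutual cosine similarity of 0.998, the
published value for the real pair. Analyses of real cohorts should
substitute an authoritative background via `make_background()` or
`read_background()`.

## The synthetic-cohort generator

`simulation_preset()` states the benchmark worlds used by the test and
acceptance suites:

| preset | n | signatures | noise |
|--------|---|-----------|-------|
| sim1 | 116 | background + 3 fixed sparse profiles | Poisson only |
| sim2 | 116 | as sim1 | Poisson + additive/subtractive |
| sim3 | 100 | background + 3 random catalog rows, presence U(0.2, 1) | Poisson only |
| sim4 | 100 | as sim3, dense rows only (>75% of categories contribute) | Poisson only |
| sim5 | 100 | as sim3, sparse rows only (<50% contribute) | Poisson only |
| sim6 | 100 | background + 7 random catalog rows | Poisson only |

Per-sample burdens are log-uniform on [10³, 10⁴·⁵] mutations —
whole-genome scale, above the 1000-mutation filter threshold. Each
non-background signature is switched on per sample with its presence
fraction; active weights are Dirichlet-distributed (concentration 3 for
the background, 1.5 otherwise, making the background the typically
dominant process as in real genomes) and scaled to the burden. Counts are
Poisson per cell. "Contribution" of a category to a signature, for the
dense/sparse split, means probability above 1/960 (1% of uniform); the
threshold is a parameter.

The optional extra noise adds, to a random 10% of cells,
Poisson(rate × mean expected cell value) counts, and symmetrically
subtracts with flooring at zero (`additive_subtractive`); the default
rate is 0.1. These magnitudes are the package's own stated defaults: the
benchmark literature specifies noise only in supplementary material not
reproduced here, so the generator is documented as an *emulation* of the
published designs, not a transcription. Similarly, the packaged signature
catalog (`synthetic_catalog()`: 5 dense + 7 sparse profiles named
`SYN-*`) is constructed, not copied from any published catalog; presets
accept a user-supplied catalog TSV for work with real signatures.

What a green simulation test establishes, therefore, is that the
implementation recovers the structure its own generator planted —
identifiable sparse signatures over a fixed dense background under count
noise. It does not establish performance on real cohorts, where burdens,
contamination, and the true background deviate from these idealizations.

## Numerical choices

* Coordinate descent converges on relative objective change below 1e-8,
  with a cancellation-noise floor of 64·eps·‖R‖²_F (the objective is
  evaluated as a difference of large quantities, so near-exact fits are
  otherwise never "converged") and a coordinate-movement criterion of
  1e-12 relative; exceeding the sweep cap raises an error carrying the
  partial estimate.
* Exposure NNLS is solved exactly per sample via the Gram matrix; a
  singular active set falls back to the pseudoinverse.
* Signature rows are renormalized to sum 1 only at output, with exposure
  columns rescaled so αβ is unchanged; rows driven entirely to zero by
  the penalty are kept as structural zeros and reported via
  `effective_k`, never silently dropped (dropping would change the model
  dimension selected by cross-validation).
* Holdout masks that would remove every nonzero cell of a sample row are
  resampled (bounded retries), since such a row carries no signal.
* All randomness flows from a single integer seed through a fixed
  derivation, so fits, cross-validations, and simulated cohorts are
  bit-reproducible; derived seeds stay within the 32-bit integer range.
* Degenerate inputs error early with messages naming the offending
  record: non-SNVs, ambiguous trinucleotide contexts (skipped and
  counted), reference mismatches (error by default, skip-and-log with
  `strict = FALSE`), all-zero matrices, empty grids.

## Scope and limitations

* One fixed background at most; no penalty on the exposure matrix; no
  Kullback–Leibler loss. These are deliberate non-goals.
* Indels, doublet substitutions, and extended (1536-context)
  classifications are out of scope.
* `one_to_one` signature matching uses an exact assignment search capped
  at 20 estimated signatures.
* The per-true-best matching convention (default) allows one estimated
  signature to absorb several true ones; that is the benchmark
  convention, and `one_to_one` is offered for robustness analyses.
* Cross-validation cost grows as |K grid| × |λ grid| × repetitions ×
  imputation rounds; the defaults reflect the published protocol, and
  desk-scale analyses should shrink the grids, not the holdout fraction.

## A worked example

```{r example, eval = FALSE}
library(sparsesigs)

# 1. simulate a benchmark cohort (or build one from VCFs with run_count)
spec <- simulation_preset("sim1")
sim <- simulate_dataset(spec, seed = 1)

# 2. select K and lambda by repeated bi-cross-validation
bg <- load_background_preset("germline")
cv <- cross_validate(sim$counts, bg, k_grid = 2:8,
                     lambda_grid = c(0.01, 0.05, 0.1),
                     repetitions = 5, seed = 1)
select_model(cv)

# 3. refit on the full matrix at the selected pair and evaluate
sel <- select_model(cv)
fit <- fit_signatures(sim$counts, bg, K = sel$K,
                      lambda_fraction = sel$lambda, seed = 1)
match_signatures(sim$true_signatures, fit$signatures)
fit_diagnostics(sim$counts, fit)
```
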