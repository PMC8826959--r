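---
title: "Methods: predicting parallelism and testing divergence in evolve-and-resequence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting parallelism and testing divergence in evolve-and-resequence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pardiv)
```

`pardiv` analyses gene-by-population matrices of de novo mutation counts from
experimental evolution. This vignette documents the statistical models, the
numerical choices, the design decisions taken where several defensible options
existed, and what the simulation-based validation does and does not establish.

## The sampling model for parallelism

A population that acquired `n_tot,j` mutations in total is modelled as having
distributed them over genes independently, hitting gene `i` with probability
`p_i`. Conditional on the total, the count in gene `i` is binomial
(equivalently, the counts arise from independent Poisson processes conditioned
on their sum). Because mutation count data are sparse, the natural summary is
*occupancy*: the fraction of the `M` replicate populations with at least one
hit in the gene.

**Estimator choice.** The per-gene probability must be estimated from the data
itself. Estimating it within a single population would be circular (the
plug-in estimate of a single observation reproduces that observation), so we
pool across all `M` replicates: `p̂_i = Σ_j n_ij / Σ_j n_tot,j`. This makes
the occupancy prediction

`o_i = 1 − (1/M) Σ_j (1 − p̂_i)^(n_tot,j)`

a genuine zero-free-parameter prediction. A leave-one-out variant (pooling
over the other `M − 1` populations when predicting population `j`) differs
from full pooling at order `1/M`; we use full pooling for simplicity and
symmetry. Populations with `n_tot,j = 0` contribute absence deterministically
(the empty product is 1).

**The geometric alternative.** As a contrast we also compute occupancy under a
geometric count distribution on {0, 1, 2, …}, uniquely pinned down by matching
the Poisson model's per-population mean `μ_ij = p̂_i · n_tot,j`, giving
absence probability `1/(1 + μ_ij)`. Mean-matching preserves the
zero-free-parameter property, so the two models are compared on equal footing.
The comparison reports mean absolute occupancy error (MAE) for both models and
the fraction of genes where the Poisson error is strictly smaller; genes where
the two absolute errors tie (common when both predict 0) are excluded from
both numerator and denominator and the tie count is reported.

**Which genes enter the MAE.** Genes with zero pooled mutations are predicted
and observed at exactly 0, so including them deflates the MAE without
informing model fit. By default only genes with at least one pooled mutation
are summarized (`include_zero_genes = FALSE` in `occupancy_fit()`).

**Subsampling.** `subsample_error_curve()` redraws subsets of populations
without replacement and recomputes the entire fit within each subset,
including re-pooling `p̂`. All randomness flows from an explicit seed and the
caller's RNG state is restored afterwards.

## The covariance test

The occupancy model assumes genes are independent. To test that assumption
globally — individual gene-pair covariances are hopeless at these sparsity
levels, and we do not attempt them — counts are first corrected for gene
target size via the *multiplicity* `m_ij = n_ij · L̄/L_i`, where `L_i` is the
gene's number of nonsynonymous sites and `L̄` is the mean over **all** genes
in the annotation (the genome), not just mutated genes. The global statistic
is the largest eigenvalue `E_1` of the population-level spectrum of the
(gene-centered, by default) multiplicity matrix, normalized as
`e_1 = M·E_1/Σ_m E_m` so the spectrum sums to `M`, then centered and scaled as
`ẽ_1 = (e_1 − μ)/σ` with

- `μ(M, N) = (√(N−1) + √M)² / N`
- `σ(M, N) = ((√(N−1) + √M)/N) · (1/√(N−1) + 1/√M)^(1/3)`

the standard Tracy–Widom constants for sample covariance spectra (expressed on
the sum-to-`M` scale, i.e. divided by `N`). For an uncentered matrix of
independent entries this normalization places `ẽ_1` at the Tracy–Widom bulk,
which the test suite verifies against the published TW₁ mean by Monte Carlo.
Gene-centering removes one degree of freedom and shifts the statistic slightly
relative to the TW location; this is immaterial for inference because
significance never relies on the TW limit:

**The null is a randomization null.** Null tables are drawn *uniformly over
integer matrices with exactly the observed row sums (per-gene totals) and
column sums (per-population totals)* under the conditional independence model,
using Patefield's algorithm (`stats::r2dtable`). Randomization operates on raw
integer counts — the margin constraints are mutation totals — and the
multiplicity correction is applied after each draw, exactly as for the
observed matrix. Since observed and null statistics share the same
normalization, any centering-induced offset cancels. The P value uses the
add-one estimator `(1 + #{null ≥ observed})/(1 + permutations)`, which is
valid at finite permutation counts and never zero. Genes with zero total
mutations carry no variance and are dropped before the eigen-analysis (their
number is recorded in the result).

`detection_vs_replication()` mirrors the question "how much replication does
covariance detection need": at each subsample size it compares the observed
statistic against a single fixed-margin draw and reports the fraction of
repetitions where the observed value is larger. For independent genes this
fraction is 1/2 *in expectation over datasets*; within one dataset the
repetitions share the dataset's realized spectrum and are strongly correlated,
so validation averages over independent simulated datasets.

## The divergence test

For two environments, the per-gene statistic is the absolute difference of
summed counts `|Δn_i|`. Under the null each environment's counts are Poisson
with uniform per-gene rates `λ_k = n_tot⁽ᵏ⁾/N_genes`; the difference of two
independent Poissons is Skellam, and its fold onto nonnegative integers has
pmf (for `k > 0`, merging the two Bessel terms via `I_k = I_{−k}`)

`Pr[k] = e^(−(λ1+λ2)) · I_k(2√(λ1λ2)) · ((λ1/λ2)^(k/2) + (λ2/λ1)^(k/2))`

and `Pr[0] = e^(−(λ1+λ2)) I_0(2√(λ1λ2))`. Gene target size is deliberately
*not* used in this null (a length-weighted variant would be a different test;
the uniform-rate form keeps the null interpretable and conservative for short
genes). `N_genes` defaults to the annotation size (genome-wide) when an
annotation is supplied, else to the matrix rows; it is recorded in the report
header because the rates depend on it.

**Numerics.** The pmf is evaluated in log space. `log I_k(x)` uses the
exponentially scaled Bessel function while `k ≤ x`; for `k > x`, where the
scaled Bessel underflows, the ascending series
`I_k(x) = Σ_m (x/2)^(2m+k)/(m!(m+k)!)` is summed in log space (it converges
rapidly in that regime). When one rate is zero the fold degenerates to a pure
Poisson law, handled as an explicit branch because the `(λ1/λ2)^(k/2)`
prefactor is otherwise 0/0; when both are zero it is a point mass at 0.
P values are upper tails summed directly from `k_obs` upward; once the
term-to-term ratio falls below 1/2 and the current term is below `1e−15` of
the accumulated mass, a geometric majorant bounds the remaining tail by twice
the next term, which is added before stopping. P values are therefore accurate
to roughly `1e−14`, and the suite checks them against a brute-force
convolution oracle at `1e−9`.

**Discrete FDR.** Because the statistic is integer-valued, only a discrete set
of P-value levels is achievable — one per observed `|Δn| = k ≥ n_min`. The
expected number of genes reaching level `P` under the null is
`N̄(P) = N_genes · Σ_{k ≥ n_min} θ(P − P(k)) · Pr[k]`; since `P(k)` is
strictly decreasing in `k`, the Heaviside sum collapses to a single tail,
`N̄(P) = N_genes · P(max(k*(P), n_min))`, which the tests verify against
literal term-by-term summation. The critical level `P*` is the **largest**
achievable level with `N̄(P*)/N(P*) ≤ α` (equivalently the smallest qualifying
`k`), maximizing discoveries at the stated FDR; if no level qualifies, nothing
is significant. `n_min` (default 1, i.e. every gene with any difference is
eligible) exists only to reduce the number of discrete tests; raising it can
change `P*` because fewer levels are scanned.

**Multiple environments.** With `T > 2` treatments, all `T(T−1)/2` pairwise
reports are computed and a gene is assigned to treatment `t` only if it is
significant with direction `t` in *every* pair involving `t` (so a gene is
assigned to at most one treatment). No additional correction is applied across
pairs; the intersection requirement is itself a stringent filter.

## The synthetic-data generator

`simulate_counts()` draws each population's total (fixed, or Poisson with a
given mean) and allocates it multinomially over genes — exactly the sampling
frame of the occupancy model, and equivalent to independent Poissons
conditional on totals, which keeps margin bookkeeping exact. Per-gene relative
rates are symmetric-Dirichlet distributed (concentration 1 by default, giving
the strong rate heterogeneity and sparse counts typical of real experiments;
`Inf` gives uniform rates). Treatment-specific enrichment multiplies chosen
genes' rates by a fold change and renormalizes; covariance is injected by a
shared log-normal latent multiplier (`exp(σZ_j)`, one draw per population) on
a gene set, renormalized, which preserves nonnegativity and has an
interpretable strength parameter. Gene target sizes are log-normal
(median ≈ 700 nonsynonymous sites, `sdlog` 0.5 — the scale of a typical
bacterial gene) and independent of rates by default, since the divergence null
ignores length. Ground truth (rates, enriched and covarying gene identities,
drawn totals) is returned for recovery tests. All outputs are pure functions
of the configuration, including its seed.

The generator emulates the *count-level* statistical structure only: there is
no fitness, drift, clonal interference, linkage or recombination. Passing
validation on generated data therefore shows the machinery is correct and
calibrated *under the model's own assumptions*; it cannot show that real
experiments satisfy those assumptions.

## Validation design and the study conditions

The test suite validates each component at fixed problem sizes chosen to be
representative while keeping the default run fast:

- *Occupancy self-consistency*: 100 genes, Dirichlet(1) rates, totals
  ~ Poisson(20), `M ∈ {25, 100, 500}`, 20 simulations per size; mean MAE must
  decrease strictly in `M` and fall below 0.02 at `M = 500`.
- *Divergence calibration*: 200 null treatment pairs with 500 genes, 6
  populations per treatment, totals ~ Poisson(50), **uniform** rates — the
  calibration is against the test's own null model, whose rates are uniform by
  construction. The rate of any false discovery at `α = 0.05` must stay ≤ 0.10.
- *Divergence power*: one gene 10-fold enriched among 200 genes, 6 populations
  per treatment, totals ~ Poisson(100); recovery with correct direction in
  ≥ 90 of 100 simulations. The totals were fixed by pilot simulation (at
  ~50 mutations per population the planted signal sits at the detection
  boundary; ~100 puts it clearly inside) and then frozen.
- *Covariance size and power*: 300 genes; size at `M = 50` over 50 independent
  datasets (≤ 0.10 at `α = 0.05`); power at `M = 100` with a latent factor of
  strength `σ = 2` over 20 genes (≥ 0.8), an effect size likewise fixed by
  pilot runs and frozen; and a rising detection-fraction curve over
  `M′ ∈ {5, …, 100}` at `σ = 1.5`, where the curve rises without saturating.
- *Sampler exactness*: margins are asserted exactly on every draw; on small
  margins admitting ≤ 20 tables, 10,000 draws are tested against the exact
  conditional distribution by chi-square goodness of fit.

`scripts/acceptance.R` re-runs the same computations end to end from a single
command-line seed and reports the measured quantities as JSON.

## Known limitations

- **Rate heterogeneity.** The divergence null spreads each environment's total
  uniformly over genes. When true rates are strongly heterogeneous, a high-rate
  gene has `|Δn|` variance above the null's even with no divergence, so the
  test is anticonservative in that regime (visible in the README example). The
  uniform null is the method's deliberate first-principles choice; a
  length-weighted extension hook exists but is off by default.
- **Occupancy error saturates.** On real data the MAE does not shrink to zero
  with replication — unmodelled structure (gene–gene covariance, selection)
  sets a floor. On generator output it does shrink, because there the model is
  exactly true.
- **The covariance test is global.** A significant result says the spectrum is
  incompatible with margin-constrained independence; it does not localize
  which genes covary, and treatment structure or planted enrichment also
  registers as covariance.
- **The Tracy–Widom constants are a normalization, not the inference.** P
  values always come from the fixed-margin randomization; the TW limit only
  motivates the centering/scaling and makes statistics comparable across
  `(M, N)`.
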