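# pardiv

Statistical analysis of gene-level mutation counts from microbial
evolve-and-resequence experiments: quantify **parallel evolution** among
replicate populations within one environment, and identify the genes driving
**divergent evolution** between environments.

## The problem

When replicate microbial populations are propagated under defined conditions
and sequenced, the data reduce to a sparse gene-by-population matrix of de
novo (typically nonsynonymous) mutation counts `n_ij`. Two questions follow:

1. *Parallelism.* Do the same genes get hit repeatedly across replicates, and
   can that recurrence be predicted without fitting anything?
2. *Divergence.* Which genes accumulated significantly more mutations in one
   environment than in another?

## The models

**Occupancy prediction (zero free parameters).** Each population `j` with
total count `n_tot,j` is modelled as allocating its mutations over genes as a
Poisson process, so the count in gene `i` is binomial with the pooled
probability `p̂_i = Σ_j n_ij / Σ_j n_tot,j`. The predicted occupancy (the
fraction of the `M` populations with ≥ 1 hit in gene `i`) is

    o_i = 1 − (1/M) Σ_j (1 − p̂_i)^(n_tot,j)

with no fitted parameters. A mean-matched geometric alternative
(`absence probability 1/(1 + p̂_i · n_tot,j)`) is computed alongside for model
comparison, and a subsampling curve traces prediction error against the number
of replicates.

**Global covariance test.** Counts are rescaled to multiplicities
`m_ij = n_ij · L̄ / L_i` (with `L_i` the gene's nonsynonymous target size) and
summarized by the largest eigenvalue of the population-level spectrum,
normalized so the eigenvalues sum to `M` and then centered/scaled by the
Tracy–Widom constants `μ(M, N) = (√(N−1) + √M)²/N` and
`σ(M, N) = ((√(N−1) + √M)/N)(1/√(N−1) + 1/√M)^(1/3)`. Significance comes from
a randomization null: integer tables drawn with *fixed row and column margins*
(Patefield's algorithm), so the test conditions on each gene's total and each
population's total.

**Divergence test.** For two environments with per-gene summed counts
`n_i⁽¹⁾, n_i⁽²⁾`, the statistic is `|Δn_i| = |n_i⁽¹⁾ − n_i⁽²⁾|`. Under the
null, counts in each environment are Poisson with uniform rates
`λ_k = n_tot⁽ᵏ⁾ / N_genes`, so `|Δn|` follows the folded **Skellam**
distribution

    Pr[|Δn| = k] = e^(−(λ1+λ2)) I_k(2√(λ1λ2)) [(λ1/λ2)^(k/2) + (λ2/λ1)^(k/2)]   (k > 0)

with `I_k` the modified Bessel function of the first kind. P values are
discrete upper tails; the critical level `P*` is the largest achievable level
at which the expected-to-observed ratio of discoveries stays below the target
FDR `α`. With more than two environments, genes significant toward the same
treatment in *every* pairwise comparison are reported as treatment-specific
candidates of adaptation.

## Worked example

```r
library(pardiv)

cfg <- sim_config(
  n_genes = 200, m_per_treatment = 6, treatments = c("biofilm", "planktonic"),
  total_law = list(law = "poisson", mean = 100),
  enrichment = data.frame(gene = 1, treatment = "biofilm", fold = 10),
  seed = 42)
sim <- simulate_counts(cfg)

occupancy_fit(sim$matrix)
#> Occupancy prediction over M = 12 populations, 200 genes (161 summarized)
#>   MAE (Poisson):   0.04687
#>   MAE (geometric): 0.08526
#>   Poisson better on 82.6% of genes (0 ties excluded)

covariance_test(sim$matrix, sim$annotation, permutations = 999, seed = 1)
#> Gene-gene covariance randomization test
#>   M = 12 populations, 161 mutated genes (39 zero-count genes dropped)
#>   Observed normalized largest eigenvalue: 21.1993
#>   P = 0.001 (999 fixed-margin randomizations, seed 1)

pair <- collapse_by_treatment(sim$matrix)[[1]]
divergence_test(pair, alpha = 0.05, n_min = 1)
#> Divergence test: biofilm vs planktonic
#>   Null rates: lambda_1 = 2.875, lambda_2 = 2.91 (N_genes = 200)
#>   Tested 139 genes with |delta n| >= 1 at FDR alpha = 0.05
#>   P* = 0.000731 (|delta n| >= 9): 3 significant gene(s)
#>     gene0001 (biofilm, |delta n| = 48)
#>     gene0022 (biofilm, |delta n| = 9)
#>     gene0102 (planktonic, |delta n| = 9)
```

The Poisson model predicts occupancy about twice as accurately as the
geometric alternative. The covariance test rejects here because the planted
treatment-specific enrichment itself induces structure across populations.
The divergence test recovers the planted gene (`gene0001`, 10-fold enriched in
the biofilm environment, `|Δn| = 48`) decisively; the two borderline
discoveries at `|Δn| = 9` reflect the heterogeneous per-gene rates in this
simulation, which the uniform-rate null deliberately ignores (see the methods
vignette for why the test is anticonservative under strong rate
heterogeneity).

## Command line

```sh
Rscript inst/cli/pardiv.R simulate  --config config.yaml --out-prefix sim
Rscript inst/cli/pardiv.R occupancy --counts sim_counts.tsv --out occ.tsv
Rscript inst/cli/pardiv.R covtest   --counts sim_counts.tsv --annotation sim_annotation.tsv --permutations 1000 --seed 1 --out cov.tsv
Rscript inst/cli/pardiv.R divtest   --counts sim_counts.tsv --treatments sim_treatments.tsv --all-pairs --out div
```

All outputs are TSVs with `#`-commented metadata headers (package version,
seed, parameters); identical seeds reproduce outputs byte for byte.

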