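# netstrat — network-based stratification of tumor mutation cohorts

`netstrat` stratifies a tumor cohort into molecular subtypes using only
somatic mutation profiles and a protein-protein interaction network. It
is aimed at cancer genomics analysts who have a MAF-like mutation table
and a STRING-style scored edge list and want reproducible, testable
subtype calls with biomarkers and clinical association statistics —
without stitching together propagation, factorization, consensus and
classification code by hand.

## The method

Raw mutation profiles are too sparse to cluster: a patient-by-gene 0/1
matrix `X` (1 = at least one somatic mutation) has a few dozen nonzero
entries per row and clinically identical patients often share none.
`netstrat` works on network-smoothed profiles instead:

1. **Random walk with restart.** For each patient, a walk seeded
   uniformly on their mutated in-network genes is iterated to its
   stationary distribution,

   `p_{t+1} = (1 − r) W p_t + r p_0`,   `r = 0.75`,

   where `W` is the column-normalized adjacency of the network
   restricted to edges with confidence score > 0.7, stopping when the
   L1 change drops below 1e-6.

2. **Graph-regularized NMF consensus clustering.** The 500 most
   variable smoothed genes (median-centered, shifted and rescaled to a
   nonnegative matrix `A`, genes × patients) are factorized as
   `A ≈ U Vᵀ` by minimizing

   `‖A − U Vᵀ‖²_F + λ · tr(Vᵀ L V)`,   `λ = 150`,

   with multiplicative updates, where `L` is the Laplacian of a
   5-nearest-neighbor patient graph. For each candidate cluster count
   `k`, many random restarts are summarized in a consensus matrix; the
   `k` with the largest cophenetic correlation wins, and samples with
   silhouette width > 0.20 on the consensus distance form the core set.

3. **Elastic-net subtyping.** A multinomial elastic net
   (penalty `λ[(1−α)/2 ‖β‖₂² + α ‖β‖₁]`) is tuned by leave-one-out
   (jackknife) over an `(α, λ)` grid on the core samples; genes with
   nonzero coefficients are each subtype's biomarkers.

4. **Clinical associations.** Subtype labels are tested against
   clinical covariates: Kruskal-Wallis (grade, node counts, PSA),
   chi-square with Yates correction exactly and only for 2×2 tables
   (stage, nodal status), and Kaplan-Meier/log-rank for survival.

A planted-partition synthetic cohort generator (`synthetic_spec()`,
`generate_cohort()`) reproduces the statistical structure this pipeline
assumes — sparse binary profiles, hypermutators spanning orders of
magnitude in burden, modular driver neighborhoods, subtype-shifted
clinical covariates — so the whole pipeline is testable offline.

## Worked example

```r
library(netstrat)

cohort <- generate_cohort(synthetic_spec(seed = 1))
fit <- netstrat(cohort, k_range = 2:5, n_runs = 20,
                alpha_grid = c(0.5, 1), nlambda = 12, seed = 1)
print(fit)
```

```
Network-based stratification fit
  300 patients x 2000 network genes smoothed (r = 0.75)
  top 500 genes, consensus over k = 2..5 (20 runs each)
  selected k = 3 (cophenetic 1.0000); subtype sizes: 97/97/106
  core samples: 300 of 300 (silhouette > 0.20)
  jackknife accuracy 96.33% (alpha = 1.00, lambda = 0.1668)
```

The cohort was simulated with three planted subtypes; the consensus
clustering recovers them (cophenetic coefficient maximal at `k = 3`,
fitted subtype sizes 97/97/106 matching the planted 106/97/97 groups up
to label order), and
the jackknifed elastic net reclassifies core samples with 96% accuracy.

```r
fit$k_table
#>   k cophenetic
#> 1 2  0.9421545
#> 2 3  1.0000000
#> 3 4  0.9955168
#> 4 5  0.9883373

signif(fit$battery$p_values, 3)
#>                           k2       k3       k4       k5
#> gleason             9.75e-17 9.29e-24 6.83e-23 4.41e-22
#> positive_node_count 9.55e-03 5.39e-02 1.09e-01 1.86e-01
#> psa                 1.93e-05 4.62e-08 1.26e-07 2.21e-07
#> path_n              8.66e-02 3.34e-02 7.60e-02 1.10e-01
#> path_t              9.93e-03 7.32e-03 1.73e-02 3.47e-02
#> clin_t              9.86e-01 8.34e-01 8.88e-01 1.21e-01
#> lymph_status        3.94e-02 1.01e-01 1.87e-01 2.99e-01
#> survival            1.75e-01 1.58e-01 2.76e-01 4.22e-01
```

The association battery finds the covariates the generator shifted by
subtype (grade, PSA, stage) significant and leaves survival — simulated
independent of subtype — non-significant, as it should.

Single statistics work on plain tables, e.g. the nodal-stage contrast
between two subtypes from published per-subtype counts:

```r
chi_square(matrix(c(145, 40, 107, 13), 2, byrow = TRUE))
#> Chi-square (Yates): statistic = 5.173 (df = 1), p = 0.0229
```

Real data enter through `read_maf()`, `read_string_edges()` and
`pipeline_config()` / `run_pipeline()`, which writes every stage output
(smoothed matrix, gene list, per-k consensus labels, silhouettes,
biomarkers, association table) plus a JSON run manifest.

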