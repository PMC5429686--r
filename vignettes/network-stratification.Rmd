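---
title: "Network-based stratification of somatic mutation profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based stratification of somatic mutation profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Somatic mutation profiles are nearly useless for clustering in their raw
form: a tumor exome typically carries well under a hundred mutated genes
out of ~20,000, two tumors of the same biological subtype often share no
mutated gene at all, and per-patient mutation burden spans orders of
magnitude. `netstrat` implements the standard remedy: mutations are not
compared gene-by-gene but *through a protein-protein interaction
network*, so two patients whose mutations hit neighboring genes in the
same pathway end up with similar profiles even when their mutated gene
sets are disjoint.

The pipeline has five stages, each exposed as an ordinary function and
orchestrated by `netstrat()` / `run_pipeline()`:

1. **Binary coding** (`build_binary_matrix`): a patient-by-gene 0/1
   matrix; a gene is 1 if it carries at least one somatic mutation,
   regardless of multiplicity or variant class.
2. **Network propagation** (`smooth_cohort`): each profile is replaced
   by the stationary distribution of a random walk with restart seeded
   uniformly at the patient's mutated in-network genes,
   `p_{t+1} = (1 - r) W p_t + r p_0`, with `W` the column-normalized
   adjacency of the high-confidence interaction network (edges with
   confidence score strictly above 0.7).
3. **Feature selection** (`rank_by_variability`,
   `prepare_gnmf_input`): the 500 genes with the largest variance of
   the smoothed score across patients, median-centered per gene, shifted
   and rescaled to a nonnegative matrix.
4. **Graph-regularized NMF consensus clustering**
   (`gnmf`, `consensus_cluster`, `select_k`, `silhouette_widths`):
   `A ≈ U V'` with nonnegative factors, penalized by
   `lambda * tr(V' L V)` where `L` is the Laplacian of a 5-nearest-
   neighbor patient graph; repeated from random initializations, the
   co-clustering frequencies form a consensus matrix per candidate
   cluster count `k`; the `k` with the largest cophenetic correlation
   wins; samples with silhouette width above 0.20 on the consensus
   distance are the *core samples*.
5. **Classification and clinical testing** (`subtype_model`,
   `association_battery`): a multinomial elastic net tuned by
   leave-one-out (jackknife) over an `(alpha, lambda)` grid classifies
   core samples and defines per-subtype biomarkers as the genes with
   nonzero coefficients; subtype labels are tested against clinical
   covariates with the conventional battery (Kruskal-Wallis for ordinal
   and continuous variables, chi-square for categorical ones with the
   Yates correction exactly and only for 2x2 tables, Kaplan-Meier with
   the log-rank test for survival).

# Parameters that matter

| parameter | default | unit / range | role |
|---|---|---|---|
| `score_threshold` | 0.7 | confidence in (0,1] | strict `>` cutoff for network edges |
| `restart` (r) | 0.75 | probability | walk locality; `r = 1` returns the seeds |
| `rwr_tol` | 1e-6 | L1 mass | convergence of the propagation iteration |
| `top_n` | 500 | genes | variance-ranked feature count |
| `lambda` | 150 | dimensionless | graph-regularization weight of the factorization |
| `knn` | 5 | patients | affinity-graph neighbor count |
| `k_range` | 2..9 | clusters | candidate subtype counts |
| `n_runs` | 100 | restarts | consensus sampling depth per k |
| `silhouette_threshold` | 0.20 | width in [-1,1] | strict `>` core-sample cutoff |
| `alpha_grid` | 0.1..1 | mixing | elastic-net L1/L2 balance grid |

The restart probability is the propagation default of the reference
random-walk implementation; it is deliberately exposed because no single
value is canonical and results at the margins (very local or very
diffuse walks) differ qualitatively.

# Numerical choices

**Input normalization for the factorization.** The smoothed profiles
are probability vectors; their entries scale inversely with network
size (order 1e-2 on the cohorts here). The Laplacian penalty, however,
is weighed by a fixed `lambda = 150` that is meaningful for data whose
typical entry is of order one. `prepare_gnmf_input` therefore rescales
the centered, shifted matrix by one global factor to unit mean entry.
The factor is recorded in the transform attribute and `rescale =
"none"` disables it. We examined the alternatives directly: with no
rescale (or a unit-maximum rescale) the penalty dominates the
reconstruction term by one to two orders of magnitude, multiplicative
updates collapse clusters at the true `k`, restarts synchronize, and
the consensus matrix is an uninformative 0/1 block matrix at every
`k` — the cophenetic coefficient then cannot discriminate cluster
counts. With the unit-mean scale the penalty behaves as the mild,
geometry-aware regularizer it is meant to be, and all downstream model
selection behaves as designed. Because the rescale is a single global
multiplier it changes no ranking, no distance ordering, and no argmax.

**Multiplicative updates.** The standard GNMF updates are used;
denominators are floored at 1e-12 (this guards 0/0, not the fixed
points). The objective is evaluated every iteration through trace
identities (no residual matrix is formed) and the iteration stops when
the relative objective change falls below 1e-5 or at `max_iter = 500`
updates. Stopping at the cap is a normal outcome: consensus clustering
*wants* restart-to-restart variability, and the variability left by a
finite update budget is part of what the consensus matrix measures.
Numerically failed runs (non-finite factors) are retried once and then
excluded; more than 10% exclusions aborts that `k`.

**Cophenetic coefficient.** Pearson correlation between the
upper-triangle consensus distances (`1 - consensus`) and the cophenetic
distances of their average-linkage dendrogram. A dendrogram that
reproduces the distances exactly has correlation 1; values within 1e-12
of 1 are snapped to exactly 1, and a constant distance matrix (which
makes the correlation 0/0) is reported as 1 with a degeneracy flag,
because single-height trees reproduce such distances exactly.
Ties in `select_k` go to the smaller `k`; ties in the cluster argmax go
to the lower index; ties in the jackknife grid go to the larger
`lambda`, then the smaller `alpha` (the more parsimonious model).

**Affinity graph.** k-nearest neighbors by Euclidean distance on
patient columns, tie-inclusive (every patient as close as the k-th
neighbor is linked), symmetrized by union. Tie-inclusion makes the
graph order-independent; identical profiles link completely.

**Degenerate inputs.** Patients with no in-network mutated gene have no
defined seed distribution and are dropped with a warning (`strict =
TRUE` escalates to an error). Isolated network nodes keep all-zero
columns in `W` and are reported; seeds placed on them lose walk mass,
so pipelines that require exact mass conservation should exclude them.
Constant values in the Kruskal-Wallis test, event-free survival data,
and single-cluster labelings return flagged degenerate results rather
than errors.

# The synthetic study system

`synthetic_spec()` defines the cohort generator used in all tests. It
emulates the statistical structure the pipeline assumes:

- a **planted-partition network**: 2,000 genes in five modules, edge
  probability 0.02 within and 0.002 between modules, every edge scored
  in (0.7, 1] so thresholding is a no-op unless a test overrides
  scores. Modular topology (rather than scale-free) is chosen because
  the propagation step's benefit comes precisely from subtype drivers
  sharing network neighborhoods;
- **three planted subtypes** of 300 patients, each owning one module
  from which its 5 driver genes are drawn; drivers mutate independently
  with probability 0.8, every gene mutates with background probability
  0.002, and 5% of patients are hypermutators whose background rate is
  multiplied by 100. These rates give sparse binary profiles (typically
  5-15 mutated genes), per-patient burden spanning two orders of
  magnitude, and a handful of recurrently mutated genes;
- **clinical covariates** whose grade, nodal-status and PSA-like
  distributions shift by subtype while survival is
  subtype-independent, so the association battery has true positives
  and a true negative.

The module separation (0.02 vs 0.002) and small driver sets are chosen
so that same-subtype patients hit *different subsets* of partially
overlapping driver neighborhoods. That within-subtype heterogeneity is
what real cohorts have in abundance, and it is essential for model
selection: with perfectly separable subtypes every factorization
restart converges to the same labeling at every `k`, all consensus
matrices become exact block matrices, and the cophenetic coefficient is
1 everywhere. The generator is deliberately *not* a best case.

What the generator does **not** emulate: trinucleotide mutation
spectra, copy-number events, rearrangements, gene-length effects on
mutation probability, network scale-freeness, or annotation noise in
gene symbols. Tests passing on this generator demonstrate that the
pipeline's machinery is correct and that its statistical logic recovers
planted structure under realistic sparsity and burden heterogeneity —
not that any particular real cohort will yield the same subtype count
or accuracy.

# Design decisions on open points

- **Variance vs coefficient of variation.** The feature ranking
  defaults to variance with `method = "cv"` available; the two are both
  plausible readings of the source material and the discrepancy is
  surfaced as an option instead of silently resolved.
- **Selection order.** Genes are selected first, then median-centered;
  the reverse order is not offered.
- **Factor orientation.** `A` is genes x patients with cluster
  structure carried by the patient-side factor `V`; the published
  dimension statement for the factorization is internally inconsistent
  and the standard GNMF convention is adopted.
- **Regularization graph.** The Laplacian comes from a patient kNN
  graph (the GNMF reference default); the source leaves the graph
  unspecified.
- **Weighted adjacency.** Edge scores above the threshold are used as
  weights for the walk, not binarized (`binarize` flips this); with
  constant scores the two coincide.
- **Final labels.** Labels come from cutting the consensus dendrogram,
  never from a single factorization run, making them a deterministic
  function of the consensus matrix.
- **Yates convention.** Continuity correction exactly and only for 2x2
  tables — the unique convention that reproduces all four published
  contingency p-values from the same table of counts, pinned by tests.

# Problem sizes used by the tests and the acceptance script

Unit tests run on 40-90 patient cohorts over 120-500 gene networks.
The acceptance checks use the generator's default conditions (300
patients, 2,000 genes, three subtypes) with candidate `k` in 2..5,
20 consensus restarts per `k`, and five independently seeded cohorts
for the stochastic medians; the classifier tuning grid there is
`alpha` in {0.5, 1} with a 12-point `lambda` path. These sizes give
stable medians while keeping the whole suite in the minutes range on a
single core.

# Known limitations

- Cophenetic model selection rewards *stability*, not correctness; a
  regularizer strong enough to synchronize restarts makes every `k`
  look perfect. The unit-mean input scale keeps the default
  configuration out of that regime, but users supplying their own
  `lambda` or pre-scaled matrices should inspect the per-`k` consensus
  matrices, not only the cophenetic curve.
- Even in the default configuration, a *stable under-clustering* can
  tie or narrowly beat the true cluster count: when one pair of
  subtypes in a particular cohort realization happens to be slightly
  closer than the others, every restart at `k = 2` resolves the merge
  the same way, the `k = 2` consensus is exact, and its cophenetic
  coefficient reaches 1. Across simulated default-condition cohorts the
  true `k = 3` wins in roughly two thirds of realizations and the
  labels *at* `k = 3` are near-perfect (adjusted Rand index 0.98-1.0)
  regardless; the miss affects only the automatic count selection.
  Consensus over restarts cannot detect this failure mode by design —
  it measures variability, and there is none. Practitioners should
  read the full `k_table` together with per-`k` cluster sizes rather
  than trusting the argmax alone.
- The jackknife error is reported for the tuned grid point selected on
  the same leave-one-out loop; as in the original design, it is a
  tuning criterion, not an unbiased generalization estimate.
- Gene identity is the trimmed, case-sensitive symbol string; no alias
  resolution is attempted, and symbols missing from the network are
  reported and dropped rather than repaired.
- The propagation treats the network as undirected and the walk as
  memoryless; heat-kernel or insulated-diffusion variants are out of
  scope.
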