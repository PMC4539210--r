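# camsfdr

Molecular subtype discovery in heterogeneous expression cohorts, with a
false discovery rate estimator that corrects the conservative bias induced
by latent subgroup structure.

## The problem

Cohorts of a clinically defined disease (the motivating case: non-small
cell lung cancer with a relapse yes/no phenotype) usually hide unobserved
*molecular subtypes*.  Genes that predict relapse inside one subtype are
diluted in the whole cohort; worse, when each phenotype group mixes the
subtypes, the subtype expression differences inflate the pooled variance
of the per-gene two-sample t statistic without touching its numerator.
Under the latent-group model implemented here, the null statistic is
asymptotically

    z  ~  N(0, 1 / (1 + mu^2/16))

— *narrower* than the standard normal for any subtype effect `mu != 0`.
Small P values become depleted, `pi0` is overestimated, and the standard
estimator `FDR(P_(k)) = m * pi0 * P_(k) / k` overestimates the true false
discovery proportion, hiding real discoveries.

`camsfdr` provides:

* **CAMS**, an extensive two-way clustering search (shuffled disjoint gene
  subsets → hierarchical gene clustering at several cluster counts →
  size-thresholded patient clustering) that proposes candidate
  (gene-set, patient-set) subtypes;
* a **corrected FDR estimator**: histogram counts of the observed
  statistics are regressed (identity-scale Poisson) on the permutation-null
  average `phi0`, the smoothed first singular vector `phi1` of the
  permutation-null ensemble, and a smoothed-residual alternative
  component, giving `pi0`, a heterogeneity coefficient `b`, and a
  corrected null `f0 = phi0 + b*phi1` from which corrected P values and
  FDR curves follow;
* a **fast path** for scoring many candidates: a parametric fit whose `b`
  maps to the `N(0, (1-b/2)^2)` null when `|b| < 0.2`, otherwise the
  average of the 5 permutation curves closest to the observed histogram
  under a centre-weighted distance;
* **assessment and calibration** of every candidate: `N01` (genes with
  corrected FDR < 0.1 within the subtype), the depletion diagnostic
  `Ratio_0.2`, an `N01_0 <= 2` prefilter, and stacked-permutation P values
  for `N01`;
* a **latent-group simulator** so the whole pipeline is testable without
  any external download.

## Worked example

```r
library(camsfdr)

cohort <- simulate_latent_cohort(m = 2000, n = 60, frac_ms_genes = 0.99,
                                 mu = 2, mu0 = 3, seed = 7)
cohort
#> <latent_cohort> 2000 genes x 60 patients (99% MS-defining, mu=2, mu0=3, seed=7)
#>   phenotype: 30 RY / 30 RN; subtypes (latent): 30 + 30

tab <- fdr_table(cohort$expr, cohort$phenotype$group, method = "corrected",
                 K = 100, seed = 7)
glance(attr(tab, "fit"))
#> # A tibble: 1 x 7
#>   method            pi0 pi0_raw      b null_sd n_bins sv_ratio
#> 1 poisson-mixture 0.969   0.969 0.0835   0.958    120     3.53
```

The fitted `b > 0` says the permutation null is narrowed relative to its
baseline; `sv_ratio` is the dominance of the first singular value of the
permutation-ensemble variation.  The correction recovers discoveries the
standard estimator loses — with 20 truly relapse-related genes planted:

```r
std <- fdr_table(cohort$expr, cohort$phenotype$group, method = "standard")
c(standard = n01(std$fdr), corrected = n01(tab$fdr))
#> standard corrected
#>       17        19
```

The search-and-assess pipeline, ending in the summary table
(`Subtype_ID`, `Genes_in_clusters`, `Patients_in_subtype`, `N01`,
`P_value`, plus diagnostics):

```r
subtypes <- enumerate_subtypes(cohort$expr,
  cams_config(subsets = 4, clusters = 2:5, shuffles = 2,
              min_patients = 20, seed = 7))
assessed <- assess_subtypes(cohort$expr, cohort$phenotype$group, subtypes,
                            seed = 7)
assessed <- calibrate_n01(assessed, cohort$expr, cohort$phenotype$group,
                          subtypes, N_p = 50, seed = 7)
head(subtype_table(dplyr::arrange(assessed, p_value)), 3)
#> # A tibble: 3 x 7
#>   Subtype_ID Genes_in_clusters Patients_in_subtype   N01 P_value Ratio Skipped
#> 1 S001                     229                  30    17       0  1.09 FALSE
#> 2 S003                       3                  43    51       0  2.79 FALSE
#> 3 S004                       2                  52     9       0  1.26 FALSE
```

The top candidate `S001` is exactly the planted molecular subtype
(Jaccard overlap 1 with the latent MS1 labels) and carries a strong
within-subtype relapse signature (`N01 = 17`).  `run_pipeline()` wraps
these stages and writes the summary table, per-subtype membership files
and a manifest sufficient to rerun the result; outputs are byte-identical
for a given seed.

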