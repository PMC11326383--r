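# hemishift

Longitudinal brain asymmetry change analysis for two-visit imaging cohorts.

Most brain-imaging studies treat hemispheric asymmetry as a fixed trait.
hemishift is built for the opposite question: **how does structural
left–right asymmetry change within a person over years**, and what tracks
that change? It implements a complete, tested pipeline from bilateral
image-derived phenotypes (regional volumes, tract FA) to asymmetry-change
statistics and their demographic, behavioural and clinical correlates —
for neuroimaging epidemiologists working with two-visit cohort data, and
for methodologists who want a fully synthetic, ground-truthed testbed for
this family of analyses.

## The model in brief

For each homologous feature pair, the lateralization index is

    LI = (R − L) / (0.5 (R + L)),

bounded in [−2, 2]. LIs are deconfounded and z-scored with parameters
fitted at visit 1 and frozen, then projected onto an orthonormal SVD
pattern basis, P = A·V (K = 33 patterns over 85 pairs by default). Change
per pattern k is summarized two complementary ways:

    LBAC_k = (P_k2 − P_k1) / Δt_days × 365      (signed, pattern-units/yr)
    MBAC_k = |LBAC_k|                            (direction-agnostic)

LBAC signs are anchored to relative hemispheric cortical decline: the
reference ΔG_Δ = (ΔG_R − ΔG_L)/Δt × 365 (mm³/yr) is positive when the left
cortex declines faster, and each LBAC column is flipped if needed so its
correlation with ΔG_Δ is non-negative.

Downstream analyses: pooled-SD Cohen's d contrasts (sex, baseline-age
quartiles, three-group employment status), cross-pattern correlation
structure, L2-penalized phenome-wide regressions (20 domain groups, six
demographic covariates, adjusted R², permuted-label nulls with
largest-coefficient attribution), total-volume-change prediction against
age-sex baselines, and a medical-diagnosis-wide association scan
(ICD → phecode → per-class PCA with 5-permutation retention, plus CCA and
PLS-C composite disease clusters against a 100-PC connectivity block;
Bonferroni α/n_clusters and 5% BH-FDR per measure × pattern family).

A synthetic-cohort generator produces all five input tables with planted,
recoverable ground-truth effects; it is first-class, tested code, not a
fixture.

## Worked example

```r
library(hemishift)

bundle <- simulate_cohort(cohort_config(
  n_participants = 1425, seed = 7,
  planted_effects = planted_effect("lbac", 1, "sex", 0.5)))

res <- asymmetry_pipeline(bundle, k = 33)
glance(res$changes)
#> # A tibble: 1 × 6
#>   n_participants n_patterns mean_abs_lbac mean_mbac mean_interval_days
#>            <int>      <int>         <dbl>     <dbl>              <dbl>
#> 1           1425         33         0.121     0.121               834.
#> # i 1 more variable: n_sign_flips <int>
attr(res$homolog_correlations, "summary")
#> # A tibble: 1 × 4
#>   mean_r min_r max_r n_pairs
#>    <dbl> <dbl> <dbl>   <int>
#> 1  0.517 0.431 0.639      55

ct <- group_contrasts(res$changes, bundle$demographics)
mp <- match_patterns(res$basis, bundle$ground_truth$loadings)
f1 <- mp$fitted_pattern[mp$true_pattern == 1]
subset(ct, contrast == "sex" & measure == "lbac" & pattern == f1)[c("pattern", "n_a", "n_b", "d")]
#> # A tibble: 1 × 4
#>   pattern   n_a   n_b     d
#>     <int> <int> <int> <dbl>
#> 1       1   705   720 0.444
```

Reading this output: each of the 1,425 simulated participants changes
their 33 pattern expressions at |LBAC| ≈ 0.12 pattern-units/year on
average; left and right homolog volume changes track each other
imperfectly (mean r ≈ 0.52 across the 55 grey-matter pairs); and the
planted sex difference of d = 0.5 on pattern 1's lateralized change is
recovered at |d| = 0.44 (the sign of the fitted pattern, and hence of d,
is set by the grey-matter reference alignment, not by the plant). The
full pipeline — contrasts, phenome regressions, diagnosis scan, with
all tables and a run manifest written to disk — is one call:

```r
run <- run_pipeline(run_config(output_dir = "results/run1", simulate = TRUE,
                               cohort = cohort_config(n_participants = 1425),
                               seed = 7))
autoplot(run$mediwas$scan)   # Manhattan plot of the diagnosis-wide scan
```

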