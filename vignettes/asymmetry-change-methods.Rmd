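---
title: "Quantifying longitudinal brain asymmetry change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying longitudinal brain asymmetry change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemishift)
library(dplyr)
```

## The measurement model

hemishift studies how structural brain asymmetry changes between two imaging
visits. The raw inputs are bilateral image-derived phenotypes: for each of 85
homologous feature pairs (48 cortical grey-matter regions, 7 subcortical
regions, 21 white-matter tracts measured as fractional anisotropy, 9
cerebellar parcels) we observe a left and a right value per participant per
visit.

Each pair is condensed to a **lateralization index**

$$\mathrm{LI} = \frac{R - L}{0.5\,(R + L)},$$

a unitless, size-normalized left–right imbalance bounded in $[-2, 2]$.
Positive LI means a larger right homolog. The index is undefined when both
homologs are zero (emitted as missing) and inputs must be non-negative —
volumes and FA cannot be negative, so a negative value is treated as a data
error rather than silently tolerated.

Raw LIs are residualized per feature on a technical-confound table (head and
body size, head motion, head position, scan-site terms; any numeric or
one-hot encoding is accepted) by ordinary least squares, then z-scored using
the residual mean and SD. Both operations are **fitted on visit-1 data only
and frozen**: visit-2 LIs are pushed through the identical parameters, so a
genuine shift between visits survives (visit-2 columns are deliberately not
re-centered). A zero residual SD aborts the fit — it signals a degenerate
feature, not something to paper over.

## Asymmetry patterns and change scores

Whole-brain **asymmetry patterns** are an orthonormal loading matrix
$V \in \mathbb{R}^{85 \times K}$ over the standardized LIs; per-participant
pattern expression is the projection $P = A V$. The basis is obtained from
the singular value decomposition of the visit-1 standardized LI matrix
(top-$K$ right singular vectors, $K = 33$ by default), which makes the
visit-1 expression columns exactly uncorrelated on the fit sample. Because
singular vectors are sign-indeterminate, columns follow a deterministic
convention (largest-absolute loading positive) before any alignment flip.

Between-visit change is summarized per pattern $k$ as

- **LBAC** (lateralized brain asymmetry change):
  $(P_{k2} - P_{k1}) / \Delta t_\text{days} \times 365$, a signed rate in
  pattern-units/year; and
- **MBAC** (magnitude of brain asymmetry change): $|\mathrm{LBAC}_k|$,
  direction-agnostic.

A year is 365 days exactly. The two views are complementary: a population in
which half the individuals drift leftward and half rightward shows ~zero
LBAC but a large MBAC.

To give LBAC signs a physical anchor, we compute a **grey-matter change
reference**: per hemisphere, the sum of the 48 cortical volumes per visit,
its yearly change $\Delta G_H$, and the difference
$\Delta G_\Delta = (\Delta G_R - \Delta G_L)/\Delta t \times 365$ in
mm³/year. $\Delta G_\Delta > 0$ means the left cortex declines faster. Each
LBAC column whose Pearson correlation with $\Delta G_\Delta$ is negative is
flipped (the flip is recorded on the basis), so positive LBACs always
correspond to relatively faster left-cortical decline. A zero-variance or
exactly tied column keeps $+1$ — a deterministic tie-break that is stable
under resampling.

## Group contrasts

Effect sizes use pooled-SD Cohen's d with no small-sample correction —
the canonical definition. Three contrast families are built per pattern and
measure: sex (male − female), baseline-age quartiles (oldest 25% −
youngest 25%, with values equal to the empirical quartile cut included in
the extreme group, matching an inclusive "age ≥ cut" reading), and
employment status. Employment uses a three-group design derived from
per-visit status: employed at both visits, retired at both, or transitioning
in between ("retiring"); all other trajectories are excluded. Contrasts are
descriptive — no p-values are attached, deliberately.

## Phenome-wide regressions

Behavioural phenotypes are typed (continuous, binary, ordered-categorical,
unordered-categorical) and grouped into 11 baseline domains, 9 of which also
have a between-visit **change** version — 20 regression groups per
asymmetry-change target. Change encoding follows fixed rules: binary and
categorical changes live in $\{-1, 0, +1\}$ (lost / unchanged / gained, with
multi-level ordered moves collapsed to their sign), unordered variables are
expanded to per-level indicators before differencing, and continuous
differences are z-scored. Per-visit values are never re-standardized before
differencing, which would mask genuine change. Phenotypes with below 10%
response at either visit are dropped and logged.

All models are ridge (L2-penalized) linear regressions on standardized
features with an unpenalized intercept, solved in closed form
($(X^\top X + \lambda I)\beta = X^\top y$), so $\lambda = 0$ reproduces OLS
exactly. The penalty default is $\lambda = 1$ on standardized features; the
planted-effect recoveries are insensitive to this choice over several orders
of magnitude, and it exists mostly to stabilize wide blocks. Every model
includes six demographic covariates: age, sex, age², age×sex, age²×sex, and
days between visits.

Model fit is reported as adjusted $R^2$. Two variants are available:
the standard form $1 - (1 - R_0^2)(n-1)/(n-d-1)$ (default) and a
multiplicative variant $R_0^2\,(n-1)/(n-d-1)$ (`as_printed = TRUE`). The
multiplicative variant can exceed 1 and is best understood as a degraded
transcription of the standard formula; it is kept available for exact
comparability, but the package defaults to the standard form. Both agree at
$d = 0$. $d$ counts all non-intercept regressors, also under penalization.

For the reverse direction — predicting a behavioural change from all $K$
LBACs plus $K$ MBACs plus demographics — the interesting quantity is the
**gain** over a permuted-label null: the brain-change block is row-shuffled
(demographics intact), the model refit, and the mean null adjusted $R^2$
(default 100 permutations, seeded) subtracted from the true one.
Attribution reports the category (LBAC / MBAC / demographic) of the
largest-|β| standardized feature. Total-volume-change prediction compares
asymmetry-feature models against an age-sex baseline by k-fold
cross-validated out-of-sample $R^2$; a constant target scores 0 for every
model by convention. A coefficient-matrix PCA (centered, with the same
sign convention) summarizes recurring phenotype motifs across the per-
pattern, per-domain fits; an all-identical coefficient matrix yields zero
components with a warning rather than a spurious axis.

## Diagnosis-wide association scan

ICD-9/ICD-10 records are aggregated through a phecode map (each phecode in
exactly one of 17 disease classes) into a binary ever-diagnosed matrix.
Composite disease clusters are built per class three ways:

1. **PCA** on the centered (not variance-scaled — components stay
   prevalence-weighted; a scale option exists) class block, with
   permutation-calibrated retention;
2. **CCA** against a connectivity block reduced to its top 100 centered
   principal components, with a small ridge (1e-3) on both block
   covariances for numerical stability;
3. **PLS-C**, the SVD of the cross-covariance between the same blocks.

CCA/PLS-C keep as many disease-side variates as the class' retained PCA
count, so the total is always 3 × Σ retained. Disease-side scores are
standardized with the deterministic sign convention.

Retention compares the true explained-variance profile against the mean
over 5 permutations in which **each phecode column is shuffled
independently** — prevalences preserved, inter-phecode links broken — and
keeps ranks whose true explained variance exceeds the null mean,
rank-by-rank with no contiguity requirement (a stop-at-first-failure switch
exists). Zero retained components is a valid outcome.

One property of this rule deserves emphasis. Under a true null (mutually
independent phecodes), the observed block and its column-shuffled versions
are exchangeable, so each rank's comparison is close to a fair coin flip:
the rule retains about half the ranks on pure-noise blocks (and about half
the time at least one component even with the stop-at-first option). This is
an inherent trait of mean-reference parallel analysis, not an
implementation artifact; we implement the rule as specified rather than
silently substituting a conservative variant (such as a max-over-
permutations reference) with different behavior. In practice the rule's
value is on *correlated* blocks, where leading factors absorb variance and
push later ranks below the null profile — there, retention is small,
contiguous and finds exactly a planted one-factor rank in 100/100
calibration runs at n = 4000.

The scan itself is plain Pearson correlation (two-sided) between every
cluster score and every asymmetry-change column, with two gates: Bonferroni
at $\alpha / n_\text{clusters}$ (0.05/174 = 2.87e-4 under the reference
cluster budget), and Benjamini–Hochberg FDR at 5% applied within each
(measure × pattern) family. The BH-passing set always contains the
Bonferroni-passing set at equal α. Under fully null simulations the scan's
p-values are uniform (KS p ≈ 0.8 pooled over 200 replicates) and the
family-wise error under Bonferroni is ≈ 0.047.

## The synthetic cohort: what it emulates, and what it does not

The generator produces all five input tables under the study conditions the
analysis targets: 1,425 participants by default (49% male; age 62.5 ± 7.2
years at first visit; 27.4 ± 1.4 months between visits; employment split
870/121/308 employed/retiring/retired), 85 feature pairs, 33 latent
patterns.

Its model, stage by stage:

- **Latent structure.** Visit-1 LIs are $Z\,S\,V^\top + \Gamma$-confounds
  $+\ \varepsilon$ with $Z$ standard normal, $V$ drawn orthonormal, and a
  $1/\sqrt{k}$ loading spectrum $S$. The spectrum matters: per-feature
  standardization in the pipeline perturbs near-degenerate singular
  vectors, so a flat or slowly decaying spectrum would let the fitted basis
  rotate away from the planted one and dilute planted effects. The
  power-law spectrum gives the leading patterns large eigengaps (fitted-
  to-planted loading correlations ≈ 0.9–0.98 for patterns 1–6 at
  n = 4000); ground-truth effects should therefore target leading patterns,
  and recovery tests match fitted to planted patterns by maximum loading
  correlation rather than by index.
- **Drift.** Visit-2 latent scores are visit-1 scores plus
  $\text{rate} \times \Delta t$, with rates mean ≈ 0 (a small decaying
  leftward trend), residual spread `drift_sd` = 0.03 pattern-units/year, and
  planted effects injected into the rate. Group drivers (sex, age,
  employment) shift rate means so the implied Cohen's d equals the planted
  value: age effects divide by the normal quartile-separation constant
  $2\varphi(z_{0.75})/0.25 \approx 2.54$, and MBAC effects act on the drift
  spread through the half-normal relation $d \approx 1.32\,\delta$ for a
  relative SD shift $\delta$. Correlation drivers (phenotype, disease
  latent) use a variance-preserving mixture so the planted value is a true
  correlation. These calibrations ignore measurement-noise attenuation
  (small by construction: projection noise per year is ≈ 0.009
  pattern-units against a drift spread of 0.03) and basis-alignment leakage
  (fitted-to-planted loading correlation 0.88-0.99 on leading patterns);
  the preregistered ±0.1 recovery tolerance at n = 4000 absorbs both.
- **Bilateral reconstruction.** A lognormal pair total $T$ (class-specific
  location: ~9,000 mm³ cortical, ~2,500 mm³ subcortical, ~1,800 mm³
  cerebellar, ~1 for FA pairs) is split as $R = T(2+\mathrm{LI})/4$,
  $L = T(2-\mathrm{LI})/4$, which inverts the LI formula exactly — the LI
  round trip is exact to 1e-12. Totals shrink by 0.5% ± 1.9%/year
  (mean ± between-participant SD) by default. The shared atrophy component
  is what makes left and right homolog volume changes positively but
  imperfectly correlated (mean r ≈ 0.5, range ≈ 0.4-0.7 at the default
  cohort size) and sets per-hemisphere cortical declines of roughly
  -1,000 mm³/year - the qualitative regime of an ageing two-visit cohort,
  with the LI drift contributing the hemisphere-differential part.
- **Phenotypes** are generated per type from Gaussian latents (eleven
  domains, four variables each by default); change couplings rebuild a
  phenotype's change latent as a noisy copy of a pattern's drift.
- **Diagnoses** arise from one latent factor per disease class (loading
  0.6, prevalence 8%) thresholded into per-phecode indicators — exactly
  the one-factor structure the retention step is calibrated to find. The
  default per-class phecode counts are the reference class sizes scaled
  down ~25×. Each phecode maps to two ICD-10 codes and one ICD-9 code in a
  synthetic map with the real map's schema.
- **Connectivity features** load on the disease-class latents plus
  independent extras, so CCA/PLS-C have genuine cross-block structure.
- **Reproducibility.** One global seed feeds a hierarchy of named
  substreams (one per table), so regenerating a single table never
  perturbs the others, and the caller's RNG state is restored.

What the generator does **not** emulate: spatial covariance between
neighbouring brain regions (features are exchangeable given the latent
patterns), realistic phenotype distributions or missingness mechanisms
(missingness is uniform at a configurable rate, 0 by default — no
published rates exist to copy), ICD coding noise, genotypes, or raw images.
Passing recovery tests therefore demonstrates that the *estimation
machinery* is faithful under the assumed data-generating structure — not
that the structure matches any real cohort.

## Numerical choices and degenerate inputs

- SVD/PCA sign indeterminacy is resolved everywhere by the
  largest-|loading|-positive rule (first index wins ties).
- Ridge solves use `solve(crossprod + λI)`; features with zero variance are
  given SD 1 (their centered column is zero, so they get zero weight).
- CCA whitening uses symmetric inverse square roots with eigenvalues
  floored at machine epsilon; the 1e-3 covariance ridge keeps
  near-collinear binary blocks well-posed.
- Both-homologs-zero LI → missing with a warning; a missing homolog makes
  that LI missing, and participants with incomplete features are excluded
  from basis fitting (complete-case SVD).
- Quartile ties are included in the extreme group; the grey-reference
  alignment keeps +1 on exact ties; `Δt ≤ 0` is a validation error.

## Problem sizes

The bundled tests exercise unit properties on cohorts of 100–150
participants with 3–8 patterns, Monte-Carlo calibrations on 100–200
replicates (retention at n = 4000, association scans at n = 150), and one
study-scale recovery run (n = 4000, K = 33, 100 permutations). The full
end-to-end pipeline at that scale completes in one to two minutes on a
single CPU.

## Known limitations

- The deconfounding and basis parameters are fitted on the analysis cohort
  itself; the original design transfers them from a much larger external
  baseline sample, which is not reproducible here. The fit-once,
  apply-to-both-visits contract is preserved.
- Tail patterns (small eigengaps) are not individually identifiable from a
  fitted basis; only subspace-level statements are meaningful there.
- White-matter "volume" totals for the volume-change prediction use summed
  FA in this atlas — a structural-integrity total rather than mm³; the
  comparison between asymmetry-feature and age-sex models is unaffected.
- The mean-reference retention rule retains ~k/2 components on truly
  independent blocks (see above); use `stop_at_first_failure = TRUE` or
  treat retained counts on weakly correlated classes with caution.
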