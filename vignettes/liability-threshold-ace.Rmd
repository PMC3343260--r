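---
title: "Decomposing disease-endophenotype associations with bivariate liability-threshold ACE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing disease-endophenotype associations with bivariate liability-threshold ACE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The question the model answers

A dichotomous disorder (the motivating case is schizophrenia) is repeatedly
found to co-occur with quantitative brain measures — smaller cerebral volume,
smaller white-matter volume, larger third ventricle. Twin data can say *why*:
is the association driven by genes that influence both the disorder and the
measure, by environment shared within families, or by individual-specific
exposures (including correlated measurement error)?

The classical design compares monozygotic (MZ) twins, who share all
segregating genetic variation, with dizygotic (DZ) twins, who share on
average half of additive genetic effects. Trait variance decomposes into
additive genetic (A), common/shared environmental (C) and unique
environmental (E) components; cross-twin cross-trait correlations carry the
information about *shared* aetiology: a 2:1 MZ:DZ ratio of those correlations
points to additive genetic overlap, a 1:1 ratio to shared environment.

## Model

### Liability threshold

The disorder is modelled as a standard-normal latent liability dichotomised
at a threshold \(t = \Phi^{-1}(1 - K)\) where \(K\) is the population
prevalence (default 1%, \(t = 2.326\)). The continuous endophenotype is
residualised on covariates (one site indicator, sex, age, intracranial
volume), ordinalised into \(k = 5\) classes of roughly equal size, and
likewise treated as a discretised latent normal. All inference is
full-information maximum likelihood on the ordinal pair table: a twin pair
with observed categories defines a rectangle in the 4-variate liability space
\((Sz_1, BV_1, Sz_2, BV_2)\) and contributes the log of its rectangle
probability under the model-implied correlation matrix. A pair with one
unobserved member (a singleton) contributes the bivariate rectangle of the
observed member, i.e. the missing member is marginalised out — this is how
the asymmetric patient/co-twin cell counts of the bundled sampling frame are
handled.

### Correlation structure (`twin_polychoric`)

The saturated-but-constrained stage estimates five polychoric correlations:

* `r_within` — within-person cross-trait, constrained equal for every
  individual (one disorder-endophenotype correlation for the whole sample);
* `r_bv_mz`, `r_bv_dz` — cross-twin endophenotype correlations;
* `r_cross_mz`, `r_cross_dz` — cross-twin cross-trait correlations,
  constrained member-symmetric (`Sz1-BV2 = Sz2-BV1`).

Endophenotype thresholds are shared across members, zygosities and affection
groups.

### Cholesky decomposition (`twin_ace`)

The structural stage is a bivariate Cholesky factorisation: disorder-side
factors \(A_1, C_1, E_1\) load on the disorder (paths \(a_c, c_c, e_c\)) and
on the endophenotype (paths \(a'_c, c'_c, e'_c\)); endophenotype-specific
factors \(A_2, C_2, E_2\) load only on it (\(a_s, c_s, e_s\)). Standardising
gives the correlated-factors solution: variance proportions
\(h^2, c^2, e^2\) per trait, factor correlations \(r_g, r_c, r_e\), and the
decomposition of the phenotypic correlation

\[
r_{ph} = \sqrt{h^2_{Sz}}\, r_g \sqrt{h^2_{BV}}
       + \sqrt{c^2_{Sz}}\, r_c \sqrt{c^2_{BV}}
       + \sqrt{e^2_{Sz}}\, r_e \sqrt{e^2_{BV}} .
\]

These identities are enforced to numerical precision and tested; a factor
correlation whose variance component is zero is reported as undefined (`NA`)
with a zero contribution.

### Ascertainment correction

Cohorts recruited through affected probands oversample high-liability pairs,
which biases unconstrained variance-component estimates. The correction used
here fixes every disorder-side parameter to external population values:
variance components \(h^2 = .81, c^2 = .11, e^2 = .08\) (meta-analytic
estimates for schizophrenia), hence cross-twin disorder correlations
\(h^2 + c^2 = .92\) (MZ) and \(.5 h^2 + c^2 = .515\) (DZ), and the threshold
fixed by the 1% lifetime risk. Only the endophenotype side and its
relationship to the disorder are estimated. No explicit
\(\Pr(\text{ascertainment})\) denominator enters the likelihood; the
correction is entirely through the fixed disorder-side parameters, and the
fixed constants are propagated bit-exactly to the output.

## Numerical choices

* **Rectangle probabilities.** The bivariate normal CDF uses Genz's hybrid
  algorithm (absolute error below 5e-16). Three- and four-dimensional
  rectangles are integrated by panelled tensor Gauss-Legendre quadrature over
  the narrowest one or two dimensions with the remaining pair handled by the
  analytic conditional bivariate CDF. The rule is fixed and deterministic;
  against a brute-force tensor-grid oracle the default rules agree to better
  than 1e-8 (optimisation rule) and 1e-10 (reporting rule), comfortably
  inside the 1e-7 contract of `mvn_rect()`.
* **Parameterisation.** Correlations are optimised on the atanh scale;
  thresholds as first threshold plus log-increments, which enforces strict
  ordering. In the Cholesky model the constraint that the endophenotype has
  unit variance eliminates \(e_s\) (computed as the positive root), with a
  penalty when the root would be imaginary.
* **Optimisation.** Nelder-Mead followed by BFGS polish, from two
  deterministic starts (all correlations zero, and normal-score moment
  estimates; for the Cholesky model a Falconer-style transform of those
  moments). The best of the starts is kept. Likelihood evaluations during
  optimisation use the coarser quadrature rule; the reported log-likelihood
  is recomputed with the fine rule.
* **Confidence intervals.** Profile likelihood at the \(\chi^2_1\) 95%
  cutoff (\(-2\Delta \ln L = 3.84\)), located by outward bracketing and root
  refinement with warm-started inner re-optimisation. For derived quantities
  of the Cholesky fit (e.g. \(h^2_{BV}\), \(r_g\), \(r_{ph}\)) the profile is
  computed under a quadratic constraint penalty holding the quantity at the
  candidate value. Components at a variance boundary (e.g. \(c^2 = 0\))
  get one-sided intervals, and likelihood-ratio tests for dropping them use
  the naive \(\chi^2\) reference, which is conservative at the boundary (the
  50:50 mixture issue); the `anova` method prints that caveat.
* **Degenerate inputs.** Cells with non-positive probability flag a boundary
  (`-Inf` log-likelihood) rather than erroring; ties at ordinalisation
  cutpoints all drop to the lower class (deterministic, left-continuous
  type-1 quantiles); a mass point spanning two cutpoints is a degeneracy
  error rather than silently fewer classes.

## The synthetic cohort generator

`simulate_twins()` realises exactly the generative model the likelihood
assumes: explicit A/C/E factor draws with MZ/DZ additive-genetic correlation
1 and 0.5, common environment shared, liabilities standard normal, disorder
dichotomised at the prevalence threshold. Defaults mirror the motivating
study's conditions: 1% prevalence, five endophenotype classes, and a
cerebrum-like generating truth (\(h^2_{BV} = .76\), \(c^2_{BV} = 0\),
\(e^2_{BV} = .24\), within-person correlation \(-.22\)) used throughout the
recovery tests. Covariates are drawn independently of liability (sites with
probabilities proportional to the bundled frame, sex shared in MZ pairs, age
shared within pairs, intracranial volume with a shared component); optional
linear confounding coefficients let residualisation be tested both as a
no-op and as a real correction. The generator does **not** emulate scanner
or segmentation artefacts beyond the E component, age/sex effects on
liability itself, or any control-pair frequency matching — passing recovery
tests therefore validates the statistical machinery under the model's own
assumptions, not robustness to violations of them.

`ascertain()` implements three schemes: none, proband-plus-controls (default
control:case pair ratio taken from the bundled frame), and exact replication
of the bundled multi-site frame (684 individuals: 410 MZ, 274 DZ, 142
affected) by sampling pairs without replacement, with singletons drawn as one
member of an extra pair of the required concordance type. Cell counts are
invariant across seeds by construction; an unsatisfiable cell raises an
error naming it.

## Worked example

```{r example, eval = FALSE}
gen <- twin_paths_from_components(0.76, 0, 0.24, r_g = -0.21, r_e = -0.40)
d <- simulate_twins(gen, n_mz = 5000, n_dz = 5000, seed = 1)
d <- prep_bv(d, k = 5)

pc <- twin_polychoric(d)     # correlation stage
ace <- twin_ace(d)           # Cholesky stage
summary(ace)
decompose_rph(ace)
anova(ace, fit_submodel(ace, drop = c("C_common", "C_specific"))$fit)
```

## Problem sizes and replication counts

Recovery tests use 5,000 pairs per zygosity — larger than the motivating
cohort (342 pairs plus singletons), chosen so that recovery failures indicate
implementation error rather than sampling noise; because the likelihood
aggregates pairs into at most \(2 \times 5 \times 2 \times 5\) cells per
zygosity, fit cost is essentially independent of sample size. Stochastic
properties (interval coverage of null parameters, likelihood-ratio behaviour
under the null, sign recovery) are asserted over small numbers of seeded
replicates with correspondingly lenient pass counts; they are
regression-style guards, not power studies.

## Known limitations

* Estimating cross-trait correlations at 1% prevalence is intrinsically
  noisy: with 10,000 pairs only about 200 individuals are affected, and the
  within-person correlation estimate has a standard error near 0.04.
* The profile for a variance proportion at its boundary returns the boundary
  as the interval endpoint; no mixture-distribution adjustment is applied.
* Only two traits are modelled; no sex limitation, no gene-environment
  interaction or correlation (assumed zero, as in the classical twin model),
  and no per-zygosity endophenotype thresholds (constrained equal by design).
* The correlation-stage and Cholesky-stage models are fitted independently;
  no standard errors are propagated from one to the other (the Cholesky fit
  uses the correlation fit only for starting values).
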