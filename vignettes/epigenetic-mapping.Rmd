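---
title: "Mapping dietary exposures to triglyceride through methylation mediators"
author: "epimediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dietary exposures to triglyceride through methylation mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimediate)
```

# The problem

Plasma triglyceride (TG) is a causal, modifiable risk factor for
cardiovascular disease, and dozens of blood DNA-methylation sites (CpG
probes, "DMSs") associate with it. What those associations mean is
ambiguous: a TG-associated CpG may be a downstream readout of lipid
levels, a marker of blood cell composition, or a molecular intermediate
through which habitual exposures — alcohol, carbohydrate, smoking —
actually move TG. `epimediate` implements a three-step *epigenetic
mapping* procedure that tries to separate these readings in family-based
cohort data:

1. **EWAS for TG.** Each CpG beta value is tested against log10 TG in a
   linear mixed model with a kinship random effect, adjusting for sex,
   age, cell-type heterogeneity (methylation principal components) and
   medication use. Bonferroni control at the epigenome-wide level flags
   significant DMSs, and correlated DMSs are reduced to representative
   loci.
2. **Exposure mapping.** Each representative DMS is tested against every
   variable of a longitudinal dietary/lifestyle panel at each of four
   exams. Because panel variables are heavily correlated, the per-DMS
   Bonferroni divisor is the *effective number of independent tests*
   (eigenvalue method), not the raw variable count.
3. **Mediation.** For the exposures with the strongest, most consistent
   signal (alcohol and carbohydrate as % of energy), a counterfactual
   mediation model decomposes the exposure effect on TG into a natural
   direct effect (NDE) and a natural indirect effect through the CpG
   (NIE), with family-clustered bootstrap intervals.

Because the motivating cohort data are controlled-access, the package
ships a synthetic family-cohort generator whose planted effects make
every stage testable by parameter recovery.

# Models

## Kinship mixed model

All association steps use one engine: for response $y$ (log10 TG, a beta
value, or expression),

$$y = X\beta + g + \varepsilon,\qquad
  \mathrm{cov}(g) = 2\Phi\,\sigma_g^2,\quad
  \mathrm{cov}(\varepsilon) = I\,\sigma_e^2,$$

where $\Phi$ is the pedigree kinship matrix (0.5 self, 0.25
parent–offspring and full sibs). Variance components are estimated by
REML after a single eigendecomposition of $2\Phi$, profiled over the
ratio $\delta = \sigma_e^2/\sigma_g^2$; because family cohorts give a
block-diagonal $\Phi$, the decomposition is done per family block. For
probe scans, the components are estimated once on the covariate-only null
model and reused for every predictor (the standard approximation for
large scans), so a scan costs one decomposition plus one generalized
least-squares solve per probe. Wald tests use the t distribution with
residual degrees of freedom, which makes the model collapse *exactly* to
OLS when the kinship matrix is identity-proportional.

Per-predictor variance explained is reported as
$100\,\hat\beta^2\,\mathrm{var}(x) / \mathrm{var}(y_{adj})$ with
$y_{adj}$ the response residualized on the other fixed effects — a
partial-$R^2$ convention, stated here because output tables depend on it.
The joint contribution of several loci ("multi-locus" variance) is the
$R^2$ of the covariate-adjusted response on all loci simultaneously under
the null-model GLS weights, with rank reduction for collinear sets.

## Effective number of tests

For an $M$-variable panel with correlation matrix eigenvalues
$\lambda_i$, the effective number of tests is
$M_{\mathrm{eff}} = \sum_i \big[\mathbf 1(\lambda_i \ge 1) +
(\lambda_i - \lfloor\lambda_i\rfloor)\big]$ (Li & Ji 2005). Correlations
are pairwise-complete; eigenvalues slightly negative from pairwise
completion are clipped at zero, and eigenvalues are rounded at 1e-9
before the floor so that exact multiplicities are not split by float
fuzz. The simpler Cheverud–Nyholt variant is available via
`method = "cheverud"` for sensitivity analysis. With the default
synthetic panel (300 variables in correlated blocks), $M_{\mathrm{eff}}$
comes out near 155 per exam.

## Representative loci

Significant EWAS probes are clustered by single linkage on
$1 - |r|$ and cut so that probes connected by any path of pairwise
$|r| \ge 0.8$ share a cluster; the smallest-p probe represents each
cluster, with ties broken by probe id. Both the threshold and the
algorithm are package choices (exposed as `r_threshold`), since
clustering conventions differ between studies.

## Counterfactual mediation

For exposure $A$, mediator $M$ (one CpG), outcome $Y$ (log10 TG), and
covariates $C$, two linear models are fitted on the medication-free
subset:

$$M = \alpha_0 + \alpha_1 A + \alpha_2^\top C + \varepsilon_M,\qquad
  Y = \theta_0 + \theta_1 A + \theta_2 M + \theta_3 AM\,[\text{opt}] +
      \theta_4^\top C + \varepsilon_Y.$$

For a contrast $a^*\!\to a$ (default: subset mean to mean + 1 SD),

$$\mathrm{NDE} = \big(\theta_1 + \theta_3(\alpha_0 + \alpha_1 a^* +
  \alpha_2^\top c_{\mathrm{ref}})\big)(a - a^*),\qquad
  \mathrm{NIE} = (\theta_2\alpha_1 + \theta_3\alpha_1 a)(a - a^*),$$

and $\mathrm{TE} = \mathrm{NDE} + \mathrm{NIE}$ identically. With the
interaction off this reduces to the product-of-coefficients rule, which
the tests exploit as an independent oracle. Intervals are percentile
bootstrap over *families resampled whole* (clusters respect the same
structure the mixed models model as a random effect); the regressions
themselves are fixed-effects-only, which is the standard practice this
estimator emulates. The interaction is excluded from headline runs but
always separately tested (Wald). Proportion mediated (NIE/TE) is
reported only when NIE and TE agree in sign.

**Mutual adjustment matters here.** In the generative model both alcohol
and carbohydrate act on shared mediators. In a single-mediator outcome
model, the *other* exposure then induces correlation between the modeled
mediator and the omitted ones, biasing $\theta_2$ (we measured up to
two-fold inflation for shared carbohydrate mediators). Conditioning on
the other exposure (`extra_adjustment`) restores conditional
independence across probes, so recovery and coverage checks run with
mutual adjustment on; this mirrors the robustness analysis usual in this
design.

# The synthetic cohort

`sim_config()` defaults define the study conditions:

* **Pedigrees:** 500 nuclear families, 2 founders + 1–3 children
  (~2,000 samples). Family effects are drawn with covariance
  $2\Phi\sigma_g^2$ per family block.
* **Cell types:** 6, Dirichlet weights with concentration
  (30, 7.5, 4, 4, 2.5, 2.5) — granulocyte-dominated like whole blood.
  Per-probe cell-type baselines are spread with SD 0.15 beta units,
  matching the large cell-type differentials seen on methylation arrays;
  this is what makes unadjusted EWAS scans inflate (median genomic
  inflation ≈ 10 in our null runs) and 5 PCs repair them.
* **Cell-composition confounding:** log10 TG includes a term in the
  mixture weights (coefficients 0.7 … −0.2). Blood counts do correlate
  with metabolic phenotypes, and without this term cell-type adjustment
  would be untestable.
* **Exposure panel:** 300 variables at 4 exams, AR(1) persistence 0.8
  across exams. Named variables have fixed blocks (alcohol + 4 drink
  types; carbohydrate + sugar), the rest sit in 29 equicorrelated blocks
  of 10 at latent $\rho = 0.6$. Alcohol is zero-inflated gamma (30% at
  zero), carbohydrate ~50% of energy, total energy lognormal around
  2,000 kcal. The observed variables are deterministic transforms of the
  latent scores, so persistence carries through.
* **Planted effects:** 12 mediator CpGs carry literature-scale
  coefficients — alcohol effects from −0.0018 to +0.0003 beta units per
  g/day (negative at most sites), carbohydrate effects of the opposite
  sign at shared sites, and mediator-to-TG effects from −2.9 to +1.1
  log10 units per beta unit. Direct exposure effects on TG are small and
  positive. The truth table records, per (exposure, probe), the implied
  NDE/NIE/TE for the default 1-SD contrast, with TE = NDE + NIE exact.
* **Covariates and medications:** sex from the pedigree; age uniform
  40–90 (children are *not* aged relative to parents — irrelevant to the
  statistics tested); BMI normal(28, 4.5); lipid-lowering medication is
  an independent Bernoulli(0.45) flag. Independence from TG keeps the
  medication-free subset unbiased; modeling treatment-by-indication is
  out of scope.

What the generator does **not** emulate: array chemistry and batch
effects, detection p-values, probe cross-reactivity, genotype effects
(beyond the family covariance), or realistic nutrient co-consumption
networks. Passing recovery tests therefore shows the estimators are
correct under the stated model, not that real FFQ data are this tame.

Beta values are truncated to [0,1] after all effects are added; the
truncated fraction is reported (typically < 1%) so planted effects stay
in the linear regime.

# Numerical choices

* REML is profiled on a 21-point log-ratio grid then refined by Brent
  search (tolerance 1e-11); ratios at the upper grid edge are reported
  as $\sigma_g^2 = 0$.
* Covariates are standardized internally in scans, which makes results
  numerically invariant under affine covariate rescaling (p-values agree
  to 1e-10). Under sample *reordering*, agreement is ~1e-7: reordering
  changes floating-point summation order inside per-family
  eigendecompositions, and full-sib blocks have repeated eigenvalues.
* PC sign convention: the largest-magnitude loading of each component is
  made positive.
* Bootstrap p-values are the smallest $\alpha$ at which the
  $(1-\alpha)$ percentile interval excludes zero; seeds are mandatory
  and recorded in every result.
* Bonferroni thresholds carry a `display` attribute rounded to 4
  decimals (0.05/170 → 0.0003, 0.05/11 → 0.0045), matching the usual
  reporting convention.
* Constant predictors are flagged `untestable` rather than dropped;
  constant mediators make the interaction test return NA with an
  `untestable` note.

# Problem sizes used in tests

The test suite exercises the same machinery at desk scale: recovery and
coverage run 50 cohorts of ~2,000 samples with 1,000 probes and 200
bootstrap replicates; null calibration uses ≥ 2,000 probe tests;
inflation checks use 10 cohorts of ~1,400 samples with 4,000 probes.
These sizes were chosen so Monte-Carlo error is small relative to the
properties asserted (e.g. the median-based inflation factor has SE
≈ 0.02 at 4,000 probes). The acceptance script reports the same
quantities at slightly reduced replication.

# Known limitations

* Single-mediator decomposition only; joint multi-mediator effects are
  out of scope, and the mutual-adjustment caveat above is the visible
  consequence.
* One genetic variance component (kinship); no GxE variance terms or
  score tests. A family-block exchangeable covariance can be emulated by
  supplying a block-constant matrix as the kinship argument.
* The scan approximation (variance components fixed at the null-model
  estimate) is standard but slightly anticonservative for predictors
  with large effects; the type-I calibration test covers the null case
  only.
* Exposure measurement error and reverse causation (TG shaping
  methylation) are not modeled; nothing in the pipeline can distinguish
  the latter from forward mediation.
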