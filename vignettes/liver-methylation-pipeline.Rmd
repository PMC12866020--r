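---
title: "Methods: blood DNA methylation and liver steatosis, from EWAS to mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood DNA methylation and liver steatosis, from EWAS to mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverEWAS)
```

## The analysis problem

Hepatic steatosis and its serum correlates (gamma-glutamyltransferase GGT,
the aminotransferases ALT/AST, and the composite fatty liver index FLI) leave
traces in whole-blood DNA methylation. The analytical chain this package
implements asks, in order:

1. which CpG sites' methylation beta-values associate with a liver phenotype
   after adjusting for the obvious confounders (EWAS);
2. which of those associations replicate across independent cohorts and pool
   convincingly in a fixed-effect meta-analysis;
3. whether the associations strengthen with cohort age across three
   generations of related participants;
4. whether cis-acting genetic variants (meQTLs) that shift methylation
   explain away the phenotype association when conditioned on;
5. whether the expression of nearby genes (eQTM) mediates the
   methylation-FLI association, quantified by a product-of-coefficients
   decomposition with Delta-method inference.

Restricted-access cohort data cannot ship with a package, so every stage is
exercised against a synthetic multi-cohort generator whose planted ground
truth makes parameter recovery testable end to end.

## Phenotype derivation

The fatty liver index is the logistic score
$$L = 0.953\,\ln TG + 0.139\,BMI + 0.718\,\ln GGT + 0.053\,WC - 15.745,
\qquad FLI = 100\,\frac{e^L}{1+e^L},$$
with triglycerides in mg/dl (a `tg_unit` flag converts from mmol/l by the
factor 88.57; the original index was derived on mg/dl and we default to it),
BMI in kg/m², GGT in U/l and waist circumference in cm. The score is bounded
in (0, 100) and strictly increasing in each component.

Liver enzymes and FLI are right-skewed, so association models use the
rank-based inverse-normal transformation
$\Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with the Blom offset $c = 3/8$
(configurable to $c = 1/2$ or $c = 0$ for sensitivity; the choice moves the
scores by a near-affine amount and does not change ranks). Ties receive
average ranks; missing values propagate; the transform is idempotent up to
rank.

Alcohol enters twice, with different codings: as a continuous g/day covariate
in the EWAS models, and as the three-level drinks-per-day factor
(none / up to one / more than one, one drink = 12 g ethanol, boundary
inclusive) in the mediation models. Weekly consumption classes
(none / moderate / excess) use sex-specific limits of 350 g/week for females
and 420 g/week for males, boundaries inclusive. BMI strata split at
25 kg/m².

## The EWAS model and its calibration

For each CpG $j$, the model is ordinary least squares,
$$y_i = \alpha + \beta_j\, m_{ij} + \boldsymbol{\theta}' \mathbf{c}_i + \varepsilon_i,$$
with $y$ the inverse-normal transformed phenotype, $m_{ij}$ the beta-value
and $\mathbf{c}$ the covariates: age, sex, BMI, smoking, alcohol (g/day),
cell-type proportions (one of the six dropped — they sum to one and would be
collinear with the intercept) and the technical principal components.
Two-sided p-values come from the t distribution; the matrix fast path
(Frisch–Waugh–Lovell residualisation of the outcome and all CpGs on the
shared covariates) reproduces the per-CpG fits exactly, including the
degrees of freedom, and is used whenever there are no missing values.

Binary steatosis uses the same linear contract on the 0/1 indicator (a
linear probability model) by default, so the coefficient lives on the same
methylation-difference scale as the crude group difference
$\Delta\beta = \overline{m}_{\text{cases}} - \overline{m}_{\text{controls}}$
that is reported alongside; logistic scoring is available by the `link`
argument. $\Delta\beta$ is deliberately covariate-free.

Calibration is summarised by the genomic inflation factor
$\lambda = \mathrm{median}(z^2)/\mathrm{median}(\chi^2_1)$. When $\lambda$
exceeds the trigger (default 1.1, configurable), the z-scores are passed
through an empirical-null correction: a three-component Gaussian mixture
(central null plus two tail components for true associations) is fitted by a
deterministic EM algorithm; the null component's mean is the bias, its SD the
inflation, and corrected statistics are $(z - \text{bias})/\text{inflation}$
with normal p-values. Two numerical choices matter:

* **Identifiability.** Unconstrained three-component EM can collapse into a
  solution where a "tail" component invades the central bulk. We constrain
  the tail means to lie at least 2.5 null-SDs from the null mean — playing
  the role that informative priors play in the Bayesian version of this
  estimator — which makes the fit stable across pure-null and
  contaminated inputs alike.
* **Determinism.** EM starts from (mean 0, SD 1, weight 0.9) with tails at
  ±3; three seeded random restarts are run and the best-likelihood solution
  kept, so results are reproducible without a sampler. Non-convergence
  returns the raw statistics with a warning and a flag rather than
  half-corrected output.

FDR control is Benjamini–Hochberg throughout (delegated to
`stats::p.adjust`; an independent brute-force implementation backs it in the
test suite). Extreme statistics can underflow p to exactly zero in floating
point; those are floored at the smallest positive double before adjustment.

## Meta-analysis and replication

Per-CpG cohort results are pooled by inverse-variance weighting:
$w_i = 1/SE_i^2$, pooled effect $\sum w_i\hat\beta_i / \sum w_i$, pooled SE
$(\sum w_i)^{-1/2}$, $Z$ = effect/SE with a normal p-value, adjusted by BH
over all CpGs tested in at least two cohorts. The direction string carries
one sign per cohort in a fixed, documented order (`?` for missing cohorts).
The replication rule is count-based: a CpG passes when it is cohort-level
FDR-significant (q < 0.05) in at least two cohorts. Direction consistency is
*not* required by default — discordant but individually significant patterns
are informative — and is available as a flag. Cochran's Q and I² are computed
as diagnostics; the pooling itself is fixed-effect only.

The cross-generation summary juxtaposes effects for the same CpGs across
cohorts ordered young to old and flags CpGs whose |effect| increases
monotonically with cohort mean age.

## meQTL conditioning

Variant QC keeps variants with MAF ≥ 0.02, exact Hardy–Weinberg p ≥ 1e−6 and
missingness strictly below 5%. The HWE test is the standard exact conditional
test (no mid-p), computed with a log-scale ratio recurrence over the
heterozygote support so it is overflow-safe at any sample size; monomorphic
variants return p = 1 by convention.

The cis scan regresses methylation on additive dosage for every QC-passed
variant within ±1 Mb of the CpG (closed interval), without covariates by
default — mirroring common standalone-scanner practice; the covariate set is
configurable. Samples with missing dosage are dropped per variant. Variants
with p < 5e−8 are significant; the top variant is the one with the lowest p,
ties broken by smaller distance, then lexicographic id.

The conditional models fit `outcome ~ CpG + covariates` and
`outcome ~ CpG + variant + covariates` on the identical complete-case rows.
When the phenotype loads on methylation itself (genetics acting only through
the CpG), the CpG coefficient is insensitive to conditioning and the variant
shows no independent association — the qualitative pattern the planted
synthetic architecture reproduces. Near-collinearity between CpG and variant
(|r| > 0.999) is flagged but both models are still attempted.

## eQTM and mediation

The eQTM scan fits `expression ~ methylation + age + sex + BMI + smoking +
alcohol` for every transcript whose start lies within ±100 kb of the CpG,
and flags nominal p < 0.05 pairs as mediation candidates.

Mediation uses three OLS fits on identical rows,
$$\begin{aligned}
FLI &= \eta_0 + \eta_1\,DNAm + \boldsymbol{\eta}_2'\mathbf{C} \\
FLI &= \gamma_0 + \gamma_1\,DNAm + \gamma_2\,GE + \boldsymbol{\gamma}_3'\mathbf{C} \\
GE  &= \beta_0 + \beta_1\,DNAm + \boldsymbol{\beta}_2'\mathbf{C},
\end{aligned}$$
with $\eta_1$ the total effect, $\gamma_1$ the direct effect and
$\beta_1\gamma_2$ the indirect (expression-mediated) effect. For nested OLS
sharing rows and covariates the identity
$\eta_1 = \gamma_1 + \beta_1\gamma_2$ holds exactly in sample, and the code
treats any row mismatch as a hard error rather than risking a silent break.
The Delta-method SE of the product is
$\sqrt{\gamma_2^2\,\widehat{Var}(\beta_1) + \beta_1^2\,\widehat{Var}(\gamma_2)}$
with the cross-model covariance set to zero (the coefficients come from
separate regressions; this is the classical product-of-coefficients /
Sobel form). A nonparametric bootstrap utility provides an empirical
cross-check of both this SE and the proportion-mediated SE. The proportion
mediated is indirect/total with the ratio-gradient Delta SE; when the total
effect is indistinguishable from zero the ratio is reported as undefined
with a reason, not as an unstable number.

The mediation covariate set is age, sex, smoking and the three-level alcohol
category — BMI is deliberately absent because the analysis is stratified at
25 kg/m² instead, and stratification replaces adjustment; the EWAS covariate
set can be substituted by configuration. FLI is inverse-normal transformed
within each analysis stratum. Mediation is inferred when the 95% CI of the
indirect effect excludes zero; opposite signs of direct and indirect effects
raise an inconsistent-sign flag, since such patterns suggest a mechanism
other than straightforward expression regulation. The causal reading rests
on the four exchangeability (no-unmeasured-confounding) conditions; they are
stated assumptions, and nothing in the code can or does test them.

## What the synthetic generator emulates

`simulate_cohort()` draws, per cohort under a shared architecture:

* **Methylation**: per-CpG logit-normal beta-values around CpG-specific
  baselines, with cell-type composition loadings, technical-PC loadings and
  residual logit noise (SD 0.35). Planted effects act on the logit scale, so
  beta-values stay strictly inside (0, 1).
* **Genetics**: additive dosages from per-SNP allele frequencies; each
  planted CpG carries one causal cis-SNP (per-allele beta-value shift 0.05,
  the scale at which a shift is comfortably detectable at genome-wide
  stringency around n = 1500). Dosages go missing completely at random at a
  configured 2% rate. In the three-generation set, offspring receive one
  transmitted allele per parent, so Mendelian consistency is exact by
  construction.
* **Expression**: unit-variance residual noise plus mild covariate structure;
  mediation-triplet genes additionally load on their CpG with slope
  `mediation_a`.
* **Phenotypes**: log-normal GGT/ALT/AST with age/sex/BMI/smoking/alcohol
  structure; planted CpG effects enter log-GGT as standardized slopes
  (default 0.25 SD, residual SD 0.5) — FLI inherits the signal through GGT,
  which mirrors the overlap between GGT-associated and FLI-associated CpGs
  one expects when FLI is partly built from GGT; ALT and AST carry no planted
  signal. Steatosis is Bernoulli with a logistic risk driven by the same
  metabolic and methylation signal. Planted slopes scale multiplicatively
  with $(\text{cohort mean age}/45)^{k}$ (default $k = 1$), producing the
  old > middle > young effect gradient without asserting a specific
  biological model of epigenetic drift.

Cohort sizes default to 1500 (the order of the discovery cohorts such a
study uses), 5000 CpGs, 20 planted CpGs, 3 mediation triplets with
$a = 0.5$, $b = 0.4$, $c' = 0.3$.

The generator deliberately does **not** emulate: probe chemistry or
normalisation artefacts (beta-values are born clean), linkage disequilibrium
beyond a single causal variant per meQTL, pedigrees beyond parent–offspring
trios, genuine cell-type deconvolution (proportions are known inputs), or
any form of unmeasured confounding of the mediation chain. Passing tests
therefore demonstrate statistical correctness of the machinery under the
stated generative model — not robustness to the artefacts of real arrays.

## QC conventions and edge cases

* Detection-p threshold: 1e−15 by default, a literal reading of the
  conventional "10e−16" filter, overridable to 1e−16.
* The sample rule removes samples with call rate *below* 95% (the standard
  direction); the probe rule removes probes failing in more than a 1%
  fraction of samples (a per-fraction convention chosen because per-sample
  vs any-sample behaviour differs across published pipelines; the fraction
  is a parameter and the removal report states counts per rule).
* All-constant CpGs are reported with missing statistics, never a crash;
  a fully-filtered matrix warns and returns an empty result.
* Coordinates are 1-based inclusive internally; BED interchange converts to
  0-based half-open at the boundary, and VCF output is GT-only v4.2.

## Problem sizes used by the tests

The test-suite simulations are sized to make every property measurable at
conventional tolerances while the suite stays quick: null-calibration runs
use 5000 CpGs at n = 1000 over ten seeds; empirical-null recovery uses 10⁴
statistics with 5% alternatives whose effects are drawn from a zero-centred
Gaussian (SD 3) — the classical two-groups design, under which a correct
correction also restores $\lambda$ to ≈ 1, whereas a point-mass alternative
would shift the median of $z^2$ by construction no matter how good the
correction; mediation recovery uses 200 replicates at n = 1500 and a
1000-replicate bootstrap cross-check; the end-to-end trace runs three
cohorts of n = 1500 with 2000 CpGs. `scripts/acceptance.R` re-runs the same
computations from scratch and writes the resulting rates and estimates as
JSON.

## Known limitations

* The empirical-null EM estimates a *global* null; it cannot separate
  polygenic-like widespread weak signal from technical inflation, and with
  heavy contamination (≫10% alternatives) the inflation estimate drifts
  upward by design.
* The fixed-effect meta-analysis assumes a common true effect per CpG;
  heterogeneity is reported (Q, I²) but never modelled.
* The linear probability model for steatosis is a convention choice for
  effect-scale interpretability; its p-values are approximate under strong
  risk gradients (the logistic switch exists for that case).
* Delta-method CIs for the indirect effect are symmetric and first-order;
  at very small samples or near-zero paths the bootstrap utility is the
  more trustworthy reference.
* The replication rule counts FDR-significant cohorts and is sensitive to
  per-cohort power differences; it is a selection device, not an estimator.
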