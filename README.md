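# liverEWAS

Epigenome-wide association analysis of liver-steatosis indicators — a tested,
reusable R implementation of the complete statistical chain linking
whole-blood DNA methylation to liver phenotypes, for epidemiologists and
epigeneticists who want each stage of such an analysis as an auditable,
reproducible function rather than a one-off script.

## What it computes

For a liver phenotype *y* (GGT, ALT, AST, the fatty liver index FLI — each
inverse-normal transformed — or binary steatosis) and methylation beta-values
*m<sub>j</sub>* per CpG *j*:

* **Phenotype derivation** — FLI = 100·e<sup>L</sup>/(1+e<sup>L</sup>) with
  L = 0.953·ln TG + 0.139·BMI + 0.718·ln GGT + 0.053·WC − 15.745; rank-based
  inverse-normal transformation (Blom offset 3/8); alcohol dose categories;
  BMI strata at 25 kg/m².
* **EWAS** — per-CpG OLS *y* ~ *m<sub>j</sub>* + age + sex + BMI + smoking +
  alcohol + cell-type proportions + technical PCs, with genomic inflation
  λ = median(z²)/median(χ²₁), empirical-null correction of bias and inflation
  (three-component Gaussian mixture fitted by constrained EM) when λ exceeds
  a trigger, and Benjamini–Hochberg FDR. Binary outcomes report the crude
  Δβ = mean(cases) − mean(controls) alongside the regression coefficient.
* **Meta-analysis & replication** — inverse-variance fixed-effect pooling
  (w<sub>i</sub> = 1/SE<sub>i</sub>², Z = pooled effect / pooled SE), per-cohort
  direction strings, and the ≥2-cohort FDR-replication rule.
* **Genetics** — variant QC (MAF ≥ 0.02, exact Hardy–Weinberg p ≥ 1e−6,
  missingness < 5%), cis-meQTL scan within ±1 Mb (p < 5e−8), top-variant
  selection, and conditional models testing whether the meQTL explains the
  CpG–phenotype association.
* **eQTM & mediation** — transcripts within ±100 kb screened at nominal
  p < 0.05, then the product-of-coefficients decomposition
  η₁ = γ₁ + β₁γ₂ (total = direct + indirect) from three OLS fits, with
  multivariate Delta-method SEs, proportion mediated, 95% CIs, a CI-based
  mediation decision, and BMI-stratified reporting.
* **Synthetic cohorts** — a generator with planted CpG effects that grow with
  cohort age across three generations (Mendelian genotype transmission
  included), planted cis-meQTLs and mediation triplets, giving ground truth
  for parameter-recovery tests of every stage.

## Worked example

Three synthetic discovery cohorts, an adjusted EWAS of inverse-normal GGT in
each, meta-analysis, and the replication filter:

```r
library(liverEWAS)

cfg <- cohort_config(n_samples_per_cohort = 800, n_cpgs = 1000,
                     n_true_cpgs = 10, n_snps = 60, n_genes = 30,
                     n_mediation = 3, seed = 42)
cohorts <- lapply(simulate_discovery_cohorts(cfg), derive_phenotypes)

res <- lapply(cohorts, function(ch)
  run_ewas(ch$methylation, ch$phenotypes$ggt_int,
           ch$covariates[, c("age", "sex", "bmi", "smoking", "alcohol_gday",
                             "cd4t", "cd8t", "bcell", "nk", "mono",
                             paste0("pc_", 1:5))],
           outcome_name = "ggt"))
res$cohort_A
#> EWAS of 'ggt' (continuous): 1000 CpGs, n = 800
#>   lambda 1.104 -> 1.109 after empirical-null correction (bias -0.033, inflation 1.008)
#>   FDR-significant CpGs (q < 0.05): 13

meta <- meta_analysis(res)
meta
#> Inverse-variance fixed-effect meta-analysis over cohorts: cohort_A, cohort_B, cohort_C
#>   1000 CpGs pooled; 10 replicated (FDR-significant in >= 2 cohorts)
#>     cpg_id    effect        se          z             p            q direction ...
#>  cg0000128  4.221404 0.1963533  21.499023 1.589989e-102 1.589989e-99       +++
#>  cg0000066  2.790767 0.1782806  15.653786  3.130284e-55 1.565142e-52       +++
#>  ...

hits <- replication_filter(res)
sum(hits %in% cohorts$cohort_A$truth$planted$cpg_id)
#> [1] 10   # all ten planted CpGs replicate; nothing spurious
```

The `effect` column is the pooled change in the transformed outcome per unit
beta-value; `direction` holds one sign per cohort; `replicated` marks CpGs
FDR-significant in at least two cohorts.

Mediation of a methylation effect through nearby-gene expression, at the
generator's configured paths (a = 0.5, b = 0.4, direct c′ = 0.3, so the true
indirect effect is a·b = 0.20):

```r
dat <- simulate_mediation_data(n = 1500, a = 0.5, b = 0.4, c_direct = 0.3,
                               seed = 1)
fit_mediation(dat$y, dat$x, dat$m,
              dat[, c("age", "sex", "smoking", "alcohol_drinks_cat")])
#> Mediation decomposition (product of coefficients, Delta-method SEs)
#>   n = 1500
#>   total    effect: +0.5163 (SE 0.0275, p = 7.61e-71)
#>   direct   effect: +0.3383 (SE 0.0292, p = 8.37e-30)
#>   indirect effect: +0.1780 (SE 0.0161, 95% CI [0.1465, 0.2094])
#>   proportion mediated: 0.345 (34%; SE 0.036)
#>   decision: mediated
```

The full chain — cohorts, EWAS, meta, generations, meQTL conditioning, eQTM,
stratified mediation — runs as one call:

```r
res <- run_full_pipeline(pipeline_config(generator = cfg), out_dir = "out")
```

## Documentation

The methods vignette (`vignettes/liver-methylation-pipeline.Rmd`) documents
the models, the empirical-null EM and its constraints, the mediation
decomposition and its assumptions, what the synthetic generator does and
does not emulate, and known limitations.
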