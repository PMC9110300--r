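# sibgwas

Within-sibship GWAS estimation and the summary-statistic inference built on
top of it, for statistical geneticists who need direct-effect estimates
free of the confounding that contaminates population GWAS: population
stratification, assortative mating, and indirect genetic effects of
relatives.

## The estimator

For individual *j* in sibship *i*, the population model regresses the
phenotype on the raw allele count with covariates,

```
y_ij ~ G_ij + Sex_ij + Age_ij + PC1_ij + ... + PCK_ij
```

while the within-sibship model centers each genotype on the sibship mean
and includes that mean as a covariate:

```
y_ij ~ G^C_ij + G^F_i + Sex_ij + Age_ij + PC1_ij + ... + PCK_ij
G^F_i = sum_j G_ij / n_i ,   G^C_ij = G_ij - G^F_i
```

Which allele a sibling inherits is randomized at meiosis conditional on the
parents, so the `G^C` coefficient estimates the direct genetic effect:
everything transmitted through the parents — stratification, assortment,
parental indirect effects — is absorbed by `G^F`. Standard errors are
cluster-robust over sibships in both models.

Downstream, the package implements the full comparison chain between the
two designs:

* **shrinkage** `δ = 1 − S_W/S_P` of discovery-weighted variant scores,
  with leave-one-out jackknife SEs and calibrated heterogeneity tests
  across variants and across studies;
* a compact **LD score regression** (`χ² ≈ N h² l_j/M + N a + 1`) for SNP
  heritability, the confounding ratio `(intercept − 1)/(mean χ² − 1)`,
  cross-trait genetic correlations, and block-jackknife difference tests
  between designs (with effective sample sizes
  `N_eff = sd_Resid² / (se² · 2·MAF·(1−MAF))` absorbing the power gap);
* **IVW Mendelian randomization**
  `β_MR = Σ β_E β_O/σ_O² / Σ β_E²/σ_O²` run on both designs with a
  jackknife difference test;
* **polygenic adaptation** testing via the Spearman correlation of
  trait-aligned singleton density scores (tSDS) with |Z|, after region
  exclusion, 1%-frequency-bin normalization and effective-N filtering;
* a **family-cohort simulator** that generates exactly the confounding
  structures the estimator removes (assortative mating by phenotype
  rank-matching, two-subpopulation stratification, parental/sibling
  indirect effects, shared environment, cryptic relatedness), with truth
  tables for parameter-recovery testing.

The methods vignette (`vignettes/within-sibship-methods.Rmd`) documents the
models, the numerical choices, and what the simulator does and does not
emulate.

## Worked example

The end-to-end scenario simulates an independent discovery sample and two
sibship studies with an education-like effect structure (direct effects
0.08, parental indirect effects 0.04, cross-mate phenotype correlation
0.2), fits both GWAS models per study, meta-analyzes, and runs every
downstream stage:

```r
library(sibgwas)
report <- run_scenario(scenario_config(seed = 3))
make_report(report)
#> == scenario: education-like (seed 3) ==
#> shrinkage: 36.0% (se 3.7%), 95% CI [28.7, 43.3], M = 41, variant-Q p = 0.945, study-het p = 0.184
#> h2: population 0.289 (se 0.011), within-sibship 0.123 (se 0.004), expected WS 0.118, diff p = 1.69e-63
#> rg: population -0.306, within-sibship -0.051, diff p = 3.17e-56
#> MR: population 0.191 (se 0.022), within-sibship 0.155 (se 0.037), diff p = 0.283
#> adaptation: rho population 0.1458 (p 0.0116), within-sibship 0.1046 (p 0.0156)
```

Reading the output: the weighted-score association shrinks by 36% from the
population to the within-sibship model (the generative truth is
η/(β+η) = 33% plus a contribution from assortment), with no evidence that
shrinkage varies across variants (Q p = 0.95) or across the two studies
(p = 0.18). The within-sibship SNP heritability (0.123) sits on the
uniform-shrinkage expectation `(1 − k)² h²_pop` (0.118). The planted
genetic correlation attenuates from −0.31 to −0.05 across designs, the MR
estimate of the simulated 0.2 causal effect is recovered by both designs
(difference p = 0.28, as no indirect path links exposure to outcome here),
and the simulated selection signal yields positive tSDS correlations in
both models.

The building blocks are exported individually — `simulate_cohort()`,
`fit_population_model()`, `fit_within_sibship_model()`,
`fixed_effects_meta()`, `shrinkage_analysis()`, `ldsc_fit()`,
`cross_trait_rg()`, `mr_ivw()`, `tsds_correlation()` — and every estimate
carries its SE and the seed that produced it.

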