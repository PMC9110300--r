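---
title: "Within-sibship GWAS and downstream inference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-sibship GWAS and downstream inference: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibgwas)
```

## The problem

A genome-wide association estimate from unrelated individuals mixes three
things: the direct effect of the inherited allele on the carrier's
phenotype, demographic structure (population stratification and assortative
mating), and indirect genetic effects of relatives whose genotypes correlate
with the carrier's. Sibships let us separate them. Conditional on the
parents, which allele a sibling inherits is randomized at meiosis, so the
deviation of a sibling's genotype from the sibship mean is independent of
everything transmitted through the parents.

## The two association models

For individual $j$ in sibship $i$ with genotype $G_{ij}$ (allele count 0, 1,
2), the package fits per variant:

* **population model**: $y_{ij} \sim G_{ij} + \text{sex} + \text{age} +
  \text{PC}_1 \ldots \text{PC}_K$ — the conventional covariate-adjusted
  regression;
* **within-sibship model**: $y_{ij} \sim G^C_{ij} + G^F_i + \text{sex} +
  \text{age} + \text{PC}_1 \ldots \text{PC}_K$, where $G^F_i = \sum_j
  G_{ij}/n_i$ is the sibship mean over the study-present siblings and
  $G^C_{ij} = G_{ij} - G^F_i$ the centered genotype.

The reported within-sibship coefficient is the $G^C$ term; $G^F$ absorbs
everything that travels through the parents (stratification, assortment,
parental indirect effects) and is retained as an auxiliary column. Both
models are fitted to identical samples; sibships in which only one member
has a phenotype are blanked first (`apply_missingness_rule()`), and variants
are screened at MAF > 0.01 and INFO ≥ 0.3 (`qc_filter_variants()`).

**Standard errors.** Siblings share environment, so residuals cluster
within sibships. Both models use a CR0 cluster-robust sandwich over
sibships with a $G/(G-1)$ small-sample factor; with thousands of clusters
the choice of CR variant is immaterial, and CR0 keeps the genome-wide scan
a closed-form matrix computation (the models are fitted by
Frisch–Waugh partialling of the shared covariates, so a scan over thousands
of variants is a handful of matrix products). P-values use the normal
approximation, consistent with downstream Z-score machinery. Degenerate
variants (zero variance, or genotype-concordant within every sibship) are
emitted as flagged missing records rather than dropped, keeping tables
alignable across models.

The within-sibship model does *not* remove sibling-on-sibling indirect
effects: those act within the sibship and are a recognized limitation of
the design, reproducible in the simulator via `eta_sibling`.

## Meta-analysis and effective sample size

Study estimates are divided by the cohort phenotype SD
(`standardize_units()`), harmonized to a common effect allele (sign flips
and allele swaps; unresolvable variants dropped with a log message), and
pooled by fixed-effects inverse-variance weighting (`fixed_effects_meta()`).
The per-variant effective sample size

$$N_{\text{eff}} = \frac{1}{\text{se}^2}
  \frac{\text{sd}_\text{Resid}^2}{2\,\text{MAF}(1-\text{MAF})}$$

converts a standard error into the number of independent observations it
implies; the within-sibship design is statistically less efficient, so its
effective N is smaller at the same raw N, and it is the N that LD score
regression must be given. The study-level summary is the median over
variants with MAF in [0.1, 0.4] — the per-variant formula is noisy at low
frequency, and the median is robust to the tails.

## Shrinkage of population relative to within-sibship estimates

For an instrument set chosen in an *independent* discovery sample (greedy
p-value clumping at $r^2 < 0.001$ within 10 Mb; liberal threshold
$10^{-5}$ primary, $5\times10^{-8}$ as sensitivity), the weighted score

$$S = \frac{\sum_k w_k \beta_k / \sigma_k^2}{\sum_k w_k^2/\sigma_k^2},
  \qquad \sigma_S = \Big(\sum_k w_k^2/\sigma_k^2\Big)^{-1/2}$$

summarizes a target GWAS with discovery betas $w_k$ as weights (it is the
no-intercept WLS slope of $\beta$ on $w$). Shrinkage is
$\delta = 1 - S_W/S_P$, reported in percent. Using an independent discovery
sample for selection and weights is the winner's-curse guard: selecting in
the target sample would bias both scores.

Because the two scores come from separate regressions on the same people,
their covariance is unknown; $\sigma_\delta$ therefore comes from a
leave-one-variant-out jackknife, $\sqrt{\frac{M-1}{M}\sum_k
(\delta_{(k)}-\bar\delta)^2}$. A delta-method SE that accepts an external
covariance estimate is exposed alongside; a positive covariance reduces it,
consistent with seemingly-unrelated-regression analyses.

Ratio caveats: $\delta$ explodes when $S_P$ is weak, so the package flags a
population score with $|Z| < 2$, and the ratio carries an
$O(\sigma_{S_P}^2/S_P^2)$ small-sample bias; precise denominators (strong
instruments) keep it negligible.

**Heterogeneity across variants.** Per-variant Wald ratios
$s_k = \beta_{P,k}/\beta_{W,k}$ are compared to the combined ratio
$S = S_P/S_W$ with

$$Q = \sum_k w_k^2 (s_k - S)^2, \qquad
  w_k = \big(\sigma_{s_k}^2 + \sigma_S^2\big)^{-1/2},$$

$\sigma_{s_k}^2 = (\sigma_{P,k}^2 + S^2\sigma_{W,k}^2)/\beta_{W,k}^2$ the
delta-method variance of the per-variant ratio and $\sigma_S$ the
delta-method SE of the combined ratio, referred to $\chi^2_{M-1}$. The
design here was genuinely open: writing the weight with raw per-variant
SEs instead of ratio-scale SEs is dimensionally inconsistent and produced
astronomically inflated Q under exactly homogeneous shrinkage, so the
calibrated ratio-scale reading was adopted (verified type-I error ≈ 0.046
at $\alpha = 0.05$ over 500 homogeneous replicates; the two forms coincide
when the within-sibship effects are standardized to unit size). Weak
denominators ($|Z_W| \le 2$) are filtered before forming ratios, logged.
Across-study heterogeneity of per-study $\delta$ uses standard
inverse-variance Cochran Q.

## Compact LD score regression

Under $\chi^2_j \approx N h^2 l_j / M + N a + 1$, the slope of a weighted
regression of $\chi^2$ on the LD score $l_j$ estimates $N h^2/M$ and the
intercept $1 + Na$; the confounding ratio is
$(\text{intercept}-1)/(\overline{\chi^2}-1)$, clipped to [0, 1] with a flag
(sampling noise makes small excursions routine) and undefined when the mean
chi-square does not exceed 1. Weights are $1/\max(l_j, 1)$ with one
reweighting iteration on *relative* fitted values — normalizing the fitted
values by their mean makes the weight profile invariant to rescaling all
chi-squares, so uniform shrinkage by $(1-k)$ scales the fitted $h^2$ by
exactly $(1-k)^2$, matching the expectation algebra that links a shrinkage
coefficient $k$ to $h^2_{WS} = (1-k)^2 h^2_{Pop}$
(`effective_n_adjustment_check()`). Full LDSC weighting (heteroscedasticity
plus overcounting with per-variant N) is out of scope; the difference is
absorbed into the jackknife SEs.

Standard errors come from a delete-one-block jackknife over 100 contiguous
blocks of equal variant counts in (chromosome, position) order; blocks
shrink automatically (with a warning) on small panels, and with one variant
per block the block jackknife equals the leave-one-out jackknife exactly
(tested). Weights are computed once on the full data and held fixed across
resamples.

Cross-trait genetic correlation regresses $z_1 z_2$ on $l_j$:
$r_g = \text{gencov}/\sqrt{h^2_1 h^2_2}$, with the cross-trait intercept
capturing sample overlap. One fixed weight vector $1/\max(l_j,1)$ is shared
by all three regressions inside `cross_trait_rg()`, which makes a trait's
correlation with itself exactly 1 — a property worth more here than the
marginal efficiency of per-regression reweighting. $|r_g|$ up to 1.25 is
tolerated numerically and flagged beyond.

**Difference tests.** $h^2_{\text{Diff}} = h^2_{Pop} - h^2_{WS}$ with
$\text{se} = \sqrt{\text{se}_P^2 + \text{se}_W^2 - 2\,\text{Cor}\cdot
\text{se}_P \text{se}_W}$, where Cor is estimated by the cross-GWAS LDSC
intercept. This correction is calibrated in the sampling regime it is meant
for — one trait analyzed by two designs on overlapping samples, where the
true per-variant effects are a single shared realization and only noise is
resampled. The simulator exposes exactly that regime
(`simulate_ldsc_pair(..., shared_effects = TRUE)`); re-drawing effects
jointly instead makes the intercept understate the estimator covariance and
inflates the test, a property of the regime rather than the test.
$r_{g,\text{Diff}}$ uses a 100-block jackknife of the whole difference.
In the degenerate limit of identical inputs every leave-block difference is
exactly zero, so the jackknife SE is zero and the test reports p = 1 (no
evidence of difference).

## Mendelian randomization

`mr_ivw()` implements fixed-effect IVW with first-order weights:
$\beta_{MR} = \sum \beta_E \beta_O / \sigma_O^2 \big/ \sum \beta_E^2 /
\sigma_O^2$, the no-intercept WLS slope of outcome on exposure betas; with
one instrument it is the Wald ratio. Whether random-effects SEs were
intended is not determinable from the printed formula, so the fixed-effect
form is used and an over-dispersion note is attached when Cochran's Q
across the Wald ratios clearly exceeds its degrees of freedom.
`mr_difference_jackknife()` compares the two designs with a
leave-one-instrument-out jackknife; instruments come from the independent
discovery sample at $5\times10^{-8}$.

## Polygenic adaptation

Singleton density scores are processed in the field's standard order:
exclude regions under strong recent selection (MHC
chr6:25,892,529–33,436,144 and lactase chr2:134,608,646–138,608,646,
1-based inclusive), normalize within 1% derived-allele-frequency bins
(half-open $[k/100, (k+1)/100)$, last bin closed; bins with fewer than two
variants pass through flagged), drop variants below 50% of the maximum
effective N (the exact boundary is retained), and sign the score to the
trait-increasing allele (tSDS; beta exactly 0 is flagged, not dropped, to
preserve alignment). The test statistic is the Spearman correlation
(average ranks on ties) between tSDS and $|Z|$, with a 100-block jackknife
SE and a two-sided p from the jackknife Z — the jackknife Z rather than the
classical Spearman test, matching the SE machinery used everywhere else.
A secondary statistic, the mean tSDS among top associated loci
(`mean_tsds_top_loci()`), is positive under directional selection.

## What the simulator emulates — and what it does not

`simulate_parent_pool()` → `simulate_sibships()` → `simulate_phenotype()`
generate two subpopulations with per-variant allele-frequency divergence
±Δp and a phenotype mean offset; phenotype-based assortative mating by
rank-matching mothers to a noisy latent copy of the father's phenotype
(calibrated so the cross-mate phenotypic correlation hits `am_corr`; one
generation of assortment only — under single-generation assortment the
sibling genotype correlation is $(1+r)/(2+r)$, not the equilibrium
$(1+r)/2$); Mendelian transmission with each child allele drawn uniformly
from the parent's two; parental and sibling indirect effects per allele;
sibship-shared environment; and cryptic relatedness as pairs of sibships
whose fathers are full siblings, plus an environment term shared across the
pair — enough to make naive and sibship-clustered population SEs
anti-conservative while leaving the within-sibship estimator calibrated.
Principal components are simulated as the standardized subpopulation
indicator plus noise with controllable leakage (`pc_noise_sd`), so tests
can probe incomplete stratification control; true genotype PCs can be
substituted by the user.

Noise is scaled so each phenotype has unit variance, and a truth table
records every component's realized variance, enabling exact decomposition
tests. All randomness flows from one seed with fixed per-stage offsets
(parents +1, transmission +2, phenotype +3, variant map +9), so cohorts are
reproducible and stages can be re-run in isolation.

Deliberately absent: LD haplotype structure from reference panels
(variants are exchangeable and independent — `select_instruments()`
therefore accepts an explicit $r^2$ matrix and treats absent LD as
independence), imputation uncertainty (INFO defaults to 1), the X
chromosome, multi-generation assortment equilibria, and real SDS
(synthetic scores are standard normal within frequency strata, shifted by
the standardized rank of the trait effect under selection). Passing tests
therefore demonstrate the estimators' behavior under the modeled
confounding structures, not robustness to LD misspecification or real
genotyping artifacts; the LD-mismatch phenomenon (inflated confounding
ratios under mis-scaled LD scores) is reproducible qualitatively by fitting
with rescaled scores, but no exact magnitudes are claimed.

## Problem sizes and numerical choices

Stochastic checks in the test suite use 20,000 sibling pairs for the
estimator-separation experiment, 5,500 independent null variants for
type-I calibration, 300 replicates for each jackknife-fidelity comparison,
and 100 seeds for LD score regression coverage — sizes at which the
Monte-Carlo error of each assertion is several times smaller than its
tolerance band, while keeping the default suite in the low minutes.
Zero-variance thresholds are $10^{-8}$ on residualized sums of squares;
LD scores are floored at 1; frequency clamps keep simulated subpopulation
frequencies inside (0.005, 0.995). The end-to-end scenario
(`run_scenario()`) defaults to two studies of 1,200 and 800 sibships, a
discovery sample of 8,000, and 600 variants with an education-like effect
structure (direct 0.08, parental 0.04, assortment 0.2), so meta-analysis,
cohort-heterogeneity and every downstream stage are exercised in seconds.

```{r example, eval = FALSE}
report <- run_scenario(scenario_config(seed = 3))
make_report(report)
```
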