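---
title: "Methods: one-sample MR of dietary intake with a Cox second stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample MR of dietary intake with a Cox second stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Observational associations between dietary habits and colorectal cancer are
vulnerable to confounding by everything that travels with diet — income,
smoking, body mass, health consciousness. Mendelian randomisation (MR) uses
genetic variants as instruments: because alleles are assigned at conception,
a variant that shifts, say, fruit intake is (under the instrumental-variable
assumptions) unconfounded by lifestyle, and its association with cancer
incidence isolates the causal pathway through the exposure.

`dietmr` implements the complete one-sample analysis chain for a
biobank-style cohort, together with a synthetic-cohort generator that
provides ground truth for every stage. Nothing in the package requires
restricted data: every estimator is exercised, and validated, on simulated
cohorts whose generating parameters are known.

# The estimator

For each dietary trait the chain is:

1. **Trait derivation.** Categorical food-frequency questionnaire (FFQ)
   responses are converted to quantitative frequencies (`convert_frequency`,
   `estimate_milk`) and combined into food groups (`compose_groups`):
   red meat = pork + beef + lamb; total fish = oily + non-oily; total
   fruits = fresh + ½·dried; total vegetables = cooked + raw; milk volume
   (mL/day) = 100·cereal bowls + 25·coffee cups + 35·tea cups, zero for
   never/rarely consumers.
2. **GWAS.** The variant panel is QC-filtered in a fixed order — imputation
   INFO < 0.3, missingness > 0.05, MAF < 2·10⁻⁴, Hardy–Weinberg p < 10⁻⁶ —
   each removed variant counted once under the first filter it fails, so
   removal reports are reproducible. The trait is scanned per variant by
   covariate-adjusted least squares (age, sex, top principal components);
   with a kinship structure, a family random intercept is absorbed first
   and the conditional residuals are scanned (a GRAMMAR-style two-step
   approximation of the per-variant linear mixed model, which is
   unnecessary at desk scale).
3. **Loci.** Genomic risk loci are selected greedily at p < 5·10⁻⁸ with a
   250 kb distance window. Distance clumping deliberately replaces
   LD-based clumping: the synthetic panel has no reference LD panel, and
   the greedy-by-smallest-p rule with position tie-breaks makes the output
   invariant to row order.
4. **Instruments.** Lead variants form an internally weighted allele score
   (weights = trait-GWAS betas; missing dosages mean-imputed per variant).
   Sensitivity exclusions drop leads associated with ≥ 2 dietary traits
   (configurable to > 2: the two published wordings of this rule differ,
   so both are available) and leads associated with the outcome at
   p < 0.05. Instrument strength is F = (β̂/SE)², the squared first-stage
   t-statistic; scores with F < 10 are refused unless overridden.
5. **Two-stage estimation.** Stage 1 regresses the trait on its allele
   score (plus covariates); stage 2 fits an age-scale Cox
   proportional-hazards model — delayed entry at recruitment age, Efron
   ties — on the stage-1 fitted values. The hazard ratio is reported per
   unit of exposure with CI `exp(logHR ± 1.96·SE)`.
6. **Pleiotropy diagnostics.** MR-Egger (WLS of per-instrument outcome
   effects on exposure effects, weights 1/SE²_out, alleles oriented so all
   exposure effects are ≥ 0; the intercept tests directional pleiotropy on
   k−2 df) and MR-PRESSO (simulation-based global heterogeneity test,
   per-instrument outlier test with Bonferroni correction, and a
   distortion test against random-removal nulls). Multivariable MR groups
   traits whose allele scores correlate at |r| > 0.10 or whose genetic
   correlation exceeds 0.30, fits each trait on all of the group's scores
   jointly, and enters all fitted exposures into one Cox model.
7. **Observational arm.** Univariate and multivariable age-scale Cox models
   of the outcome on the raw trait, with the adjustment set screened by
   univariate outcome association (p < 0.05, configurable) and alcohol
   dropped from its own adjustment set.

# Heritability and genetic correlation

The paper-scale trait summaries (SNP heritability, genetic correlation)
use Haseman–Elston regression: products of covariate-residualized,
standardized trait values over sample pairs are regressed on the genomic
relatedness entries; the slope estimates h², and the bivariate form
normalized by the two h² slopes gives r_g. Two implementation choices
matter:

* **The n×n relatedness matrix is never formed.** All pair sums reduce to
  identities in Z′Z and Z′y (Z the standardized dosage matrix), e.g.
  Σ_{i≠j} G_ij y_i y_j = ‖Z′y‖²/M − Σ_i G_ii y_i², and
  ‖G‖²_F = ‖Z′Z‖²_F/M². This keeps n = 10⁴–2·10⁴ estimation in seconds.
* **Standard errors** come from a delete-a-block jackknife over samples
  (20 contiguous blocks by default), with the block-deleted sums computed
  from the same identities.

Estimates are clipped to their parameter space ([0,1] for h², [−1,1] for
r_g) with a flag; a pair with a non-positive h² slope is reported as
undefined rather than silently rescaled. Identical traits give r_g = 1
exactly, which the tests assert to 10⁻⁶.

# The synthetic cohort

`simulate_genotypes` draws biallelic dosages binomial(2, p) in
Hardy–Weinberg proportions with configurable MAF range, with per-variant
INFO and missingness metadata drawn from mixtures so roughly 8% of
variants fail each of those filters; `hwe = FALSE` draws with inbreeding
coefficient 0.3 so the HWE filter also has work to do. An optional
two-subpopulation allele-frequency shift exists solely to exercise the
principal-component operation.

`make_architecture`/`simulate_traits` build each trait as genetic value +
family random effect + latent confounder + Gaussian noise, with
components scaled so realized variance shares match the targets; shared
causal variants keep one effect draw across traits, so two traits sharing
a fraction s of equally weighted causal variants have r_g ≈ s.
`simulate_outcome` draws event ages from an exponential baseline hazard
on the age scale (rate 0.0055/year by default, ≈ 10% cumulative events
under administrative censoring at age 75) with delayed entry at the
recruitment age, and assigns colon:rectal subsite labels 2:1 — the
approximate case mix of a large prospective cohort. Baseline covariates
emulate such a cohort: age ~ N(56.6, 8²) truncated to 37–73, 53% women,
and plausible family-history/income/smoking/BMI/activity margins.

Each generator stage seeds its RNG from a distinct stream derived from the
user seed. This matters: seeding two stages with the same raw integer
would replay the same underlying uniforms, and event times drawn from the
same stream as causal dosages acquire a spurious correlation with the
genetic value that visibly attenuates downstream causal estimates.

What the generator does **not** emulate: linkage disequilibrium (variants
are independent given allele frequency), within-family genotype
correlation (families share an environmental random effect only, so the
kinship adjustment is exercised as a variance-absorbing step, not as a
confounding correction), selection effects, time-varying diet, and
non-proportional hazards. Passing tests therefore demonstrate internal
statistical validity of the estimators under the stated model, not
robustness to those real-data features.

# Numerical and design choices

* The per-variant OLS scan uses Frisch–Waugh residualisation against the
  covariate block, which is algebraically identical to the full
  normal-equations solve per variant (asserted to 10⁻⁸) and vectorises
  over the panel.
* Shapiro–Wilk normality checks run on a random subsample capped at 5000
  (the test is undefined above that and over-powered long before), with
  the subsample seed recorded.
* FFQ category matching is case-insensitive after whitespace and dash
  normalisation; "do not know"/"prefer not to answer" map to missing.
  Cheese uses the meat/fish label set — the source table lists identical
  categories. The inverse mapping bins a frequency to the nearest
  category value with ties to the lower category, making
  convert∘simulate the identity on category values.
* Composites are missing iff any constituent is missing (complete-case
  analysis downstream; no imputation).
* MR-PRESSO defaults: n_sim = 1000, outlier significance 0.05/k, 1000
  distortion resamples; runs are bit-reproducible given a seed. n_sim
  below 100 is rejected as an unstable null. Note that the Bonferroni
  outlier threshold is only attainable when n_sim · α/k ≥ 1 — with the
  default α and 50 instruments that requires n_sim ≥ 1000.
* The 2SLS-Cox SE is the model-based Cox SE by default; an optional
  nonparametric bootstrap over individuals (re-running both stages)
  propagates first-stage uncertainty. Both are reported when the
  bootstrap is on. With strong allele-score instruments (F in the
  hundreds) the two are close.
* Subsite analyses censor the competing subsite's events at their event
  age; sex subgroups are sample subsets.
* Positions are 1-based and clump windows inclusive on both ends.

# Problem sizes

The validation suite runs the recovery and calibration studies at sizes
chosen to make the assertions sharp while keeping the whole suite quick on
a single CPU: causal-effect recovery at n = 20 000 with a 2000-variant
panel, 60 causal variants, h² = 0.08 and true HR 0.8/serving over 20
seeds; null calibration and the confounding contrast at n = 10 000 over
100 replicates each; Egger calibration on 500 simulated 50-instrument
summary sets; Haseman–Elston recovery at n = 10 000, M = 1000 over 10
seeds. The analysis scripts under `analysis/` run a full narrative
pipeline at n = 12 000, M = 1200.

# Limitations

Internal weighting (weights and effects estimated in the same sample)
carries winner's-curse bias, surfaced as a warning attribute rather than
corrected. Distance clumping yields loci counts that depend on variant
density, so no specific locus count is targeted. The Cox second stage
assumes a linear exposure–log-hazard relationship, and the hazard-ratio
scale is non-collapsible: with a ~10% event fraction, estimates on a
coarse instrument attenuate by a few percent relative to the generating
conditional HR, which the recovery tolerances accommodate.
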