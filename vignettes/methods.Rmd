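---
title: "Models and methods behind sumstatmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sumstatmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumstatmr)
```

# Scope and data model

`sumstatmr` works entirely from GWAS *summary statistics*: per-variant
records of a per-allele effect $\beta$, its standard error, the signed
statistic $z = \beta/\mathrm{se}$, a two-sided p-value, the effect-allele
frequency (EAF), the contributing sample size, and optionally an
imputation INFO score and a Hardy–Weinberg p-value. A `sumstats` object is
such a table plus study metadata. Where joint multi-variant modelling is
needed, an external LD reference (`ld_ref`: a correlation matrix with a
variant sidecar, optionally a D′ matrix) stands in for individual-level
genotypes.

Redundant fields are reconstructed when absent (missing $z$ from
$\beta/\mathrm{se}$, missing p from the two-sided normal tail of $z$,
missing se from $|\beta/z|$). All tail probabilities use the normal, not
the t, distribution: the cohorts this workflow targets have thousands to
hundreds of thousands of participants, where the two are
indistinguishable, and summary records rarely carry residual degrees of
freedom anyway. The one exception is MR-Egger, whose k − 2 residual
degrees of freedom (k = number of instruments, often ≪ 30) genuinely
matter; it uses t-based inference.

Extreme statistics are a practical concern: a strong metabolite locus can
have $|z| > 38$, where the two-sided normal p underflows double
precision. Every p-value in the package is therefore computed in log
space (`p_from_z`), and significance decisions compare log p-values with
log thresholds, so a hard zero never enters a comparison.

# Quality control and harmonization

The per-variant QC filter excludes records with se > 10 or se ≤ 0,
$|\beta| > 5$, Hardy–Weinberg p < 1e-6 or INFO below a configurable
threshold (default 0.4; genotyping platforms differ, so it is per-study
configuration). The rules are evaluated independently — a record failing
two rules is counted under both and removed once — and a rule is skipped,
with the skip counted, when its field is missing. The se ≤ 0 clause is
interpreted to include zero, since a zero SE breaks every downstream
inverse-variance weight; such rows are already rejected when *reading*
files, because they violate the type invariants.

Harmonization aligns two records for the same variant to a common effect
allele. Swapped alleles flip the signs of $\beta$ and $z$ and map EAF to
1 − EAF; complement-strand reports are relabelled, possibly combined with
a flip. Palindromic variants (A/T, C/G) whose minor-allele frequency
exceeds 0.40 in either record are tagged and dropped rather than guessed
— with both alleles near 50% frequency, strand cannot be inferred from
frequency. The 0.40 cutoff is the common two-sample MR convention; it is
a tunable argument. Harmonization is idempotent: re-harmonizing an
aligned pair is the identity.

Multi-allelic records (comma-separated alleles) are rejected at read time
with a logged warning; with summary data alone there is no reliable way
to decompose them.

# Meta-analysis

Two fixed-effect schemes are provided, mirroring how heterogeneous study
panels are actually combined:

* **Sample-size-weighted Z** (`stouffer_meta`):
  $z_{meta} = \sum_i \sqrt{n_i}\,z_i / \sqrt{\sum_i n_i}$, using only
  p-values, directions and sample sizes. This is the right tool when the
  phenotype scale differs across studies (different metabolomics
  platforms, different transformations). The $\sqrt{n}$ weight is the
  documented default of the standard meta-analysis software for this
  scheme. A study missing a variant contributes nothing and appears as
  `?` in the direction string.
* **Inverse-variance effect pooling** (`ivw_effect_meta`) where effect
  sizes are commensurable, with Cochran's
  $Q = \sum_i (\beta_i - \beta_{pool})^2/\mathrm{se}_i^2$ on k − 1 df as
  the heterogeneity diagnostic.

Because studies differ in imputation strategy, pooled results are
restricted (`coverage_filter`) to variants seen in at least two studies,
covering more than half of the grand total sample size, with MAF at least
0.1%. The MAF used is the sample-size-weighted mean EAF across
contributing studies, folded. No genomic-control correction is applied
before meta-analysis; none is implemented.

# Locus discovery

`clump` applies greedy distance-based clumping: the most significant
remaining variant below 5e-8 founds a locus and absorbs everything within
its window. "1 Mb windows" is read as ±0.5 Mb around the lead; an
exceptionally strong, broad signal can be given a wider window (e.g.
±3 Mb) through `special_windows`. Both readings of the window convention
are reachable through configuration. Ties on p break by position then
variant id, so results are deterministic.

`cojo_joint` reconstructs the multiple-regression normal equations from
marginal statistics plus the LD reference: with
$v_j = 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)$ the Hardy–Weinberg dosage
variance, $S_{jk} = \sqrt{v_j v_k}R_{jk}$,
$(X'X)_{jk} \approx \sqrt{n_j n_k}\,S_{jk}$ and
$(X'y)_j \approx n_j v_j \beta_j$. Per-variant sample sizes are taken
from the summary rows (coverage differs across variants); for uniform n
this reduces to the textbook $n S$. The phenotypic variance is estimated
robustly as the median over members of $v_j\beta_j^2 + v_j n_j
\mathrm{se}_j^2$; the residual variance follows from the fitted model
with the median n as the effective denominator. This median-based
convention is one of several used by approximate-conditional software;
the accuracy claim here is agreement with brute-force multiple least
squares on generating genotypes (the test suite asserts max relative
error < 5% at n = 5000 over 20 seeds), not bit-compatibility with any
external tool. A condition number above 1e8 on $S$ raises a collinearity
error naming the worst pair.

`cojo_stepwise` performs forward selection seeded with the lead: the
candidate with the smallest conditional p joins if its joint p clears
5e-8 and its r² with every selected variant stays below the collinearity
guard 0.9 (the guard value is the convention of the standard software;
nothing in the underlying theory pins it). After each addition the model
is re-fitted and any member whose joint p has drifted above the threshold
is dropped. Candidates with MAF < 1% are excluded up front — their
marginal statistics are too unstable for the approximation.

`prune_selected` then keeps, in joint-p order, only variants with
pairwise r² ≤ 0.05 (strict: exactly 0.05 survives), and finally removes
low-frequency variants (MAF < 1%) in near-complete haplotype sharing with
the common sentinel. Published descriptions of this second filter pair
"high LD" with a printed D′ *below* 0.05, which is internally
contradictory (D′ near 1, not near 0, indicates haplotype sharing); the
rule here drops a low-frequency variant when |D′| with the sentinel
*exceeds* a threshold, default 0.95, with the threshold configurable so
either reading can be reproduced. This is flagged rather than silently
corrected.

Per-variant variance explained on a standardized trait is
$2p(1-p)\beta^2$; the cumulative version over independent variants is the
running sum, which is non-decreasing by construction.

# Genetic scores and trait scans

`build_score` orients every weight to the exposure-raising allele
(flipping alleles where the meta-analytic $\beta$ is negative), which
makes nested tiers unambiguous: a sub-score is literally a subset of its
parent's rows. Weights come from the effect-size meta-analysis, not from
any single cohort. `score_values` is the weighted allele count;
`score_r2` the squared Pearson correlation with a (standardized)
phenotype. `trait_scan` fits per-trait least squares of trait on score
(plus covariates such as sex and measurement batch), flags significance
at the exact Bonferroni level α/m, and reports the display-rounded
threshold separately. Display rounding follows the reporting convention
of thresholds below 1e-3 to two significant figures and larger ones to
three decimals (0.05/894 → 5.6e-5, 0.05/27 → 0.002); decisions never use
the rounded value. Scan traits are standardized but not winsorized by
default; winsorization is part of the exposure-GWAS preparation
(`prep_phenotype`), not of the scan contract.

# Sex-stratified comparison

Phenotypes are standardized within sex (`standardize_by_sex`, sample-SD
convention), per cohort, before estimation; the per-sex raw SDs are
returned because downstream MR needs them to express per-SD effects on
the raw scale. The sex contrast is
$z_{sex} = (\beta_f - \beta_m)/\sqrt{se_f^2 + se_m^2}$ with a two-sided
normal p in log space — the dominant metabolite locus produces
$|z_{sex}| \approx 40$, far past double-precision underflow, and the
log-space path keeps such results finite and comparable. The normal
rather than t reference is deliberate: the residual degrees of freedom
are unknown from summary data and irrelevant at these sample sizes.
Cross-cohort pooling is fixed-effect per sex, then the contrast on the
pooled pair. The same contrast applies unchanged to sex-specific MR
estimates (pairs of (θ, se)). The Bonferroni family for the contrast
defaults to the number of lead variants tested, not counting secondary
signals.

# The MR engine

Given harmonized instruments $(\gamma_j, \sigma_{x,j};
\Gamma_j, \sigma_{y,j})$ from non-overlapping samples:

* **Wald ratio**: $\hat\theta = \Gamma/\gamma$, se $|\sigma_y/\gamma|$
  (first-order delta method).
* **IVW**: weighted regression of $\Gamma$ on $\gamma$ through the
  origin, weights $1/\sigma_y^2$; the fixed-effect se
  $(\sum \gamma_j^2/\sigma_{y,j}^2)^{-1/2}$ is the default, with
  heterogeneity reported separately as Cochran's Q over the
  per-instrument ratios rather than folded into the se. A multiplicative
  random-effects option (`random_effects = TRUE`) inflates the se by the
  residual scale when it exceeds 1, but is off by default.
* **MR-Egger**: the same weighted regression with a free intercept,
  after orienting all instruments to $\gamma \ge 0$ (without a fixed
  orientation the intercept is meaningless). The intercept estimates the
  average directional pleiotropy under the InSIDE assumption; inference
  is t-based on k − 2 df.
* **Weighted median**: per-instrument ratios sorted with normalized
  weights $w_j = \gamma_j^2/\sigma_{y,j}^2$ (the leading-order inverse
  variance of a ratio — the originating publication's choice; the
  workflow description this package follows does not specify one);
  cumulative midpoints $s_j = \sum_{i\le j} w_i - w_j/2$; linear
  interpolation at $s = 1/2$. Consistent while at least half the weight
  comes from valid instruments.
* **Penalized weighted median**: each instrument's heterogeneity
  contribution $Q_j = w_j(\hat\theta_j - \hat\theta_{wm})^2$ (with raw
  inverse-variance weights) is converted to a one-df chi-square tail
  probability $q_j$ and the weight multiplied by $\min(1, 20\,q_j)$
  before re-applying the median rule. The penalty constant 20 and the
  5000-draw parametric bootstrap follow the originating publication;
  both are arguments. Penalty → ∞ recovers the plain weighted median,
  as does any homogeneous instrument set.
* **Multivariable MR**: weighted least squares of $\Gamma$ on several
  exposures' effect columns, no intercept, weights $1/\sigma_y^2$; the
  metabolite coefficient with blood-pressure columns present is the
  blood-pressure-adjusted direct effect. Published wording for this
  model swaps "explanatory" and "independent" variables; it is
  implemented with the outcome effects as the response, which is what
  the stated weighting requires. An all-zero exposure column is dropped
  with an `NA` coefficient (reducing to the univariable model) rather
  than erroring; true collinearity (condition number > 1e8) errors.

Median-method standard errors come from a *parametric* bootstrap —
instrument effects redrawn from normal distributions centred on the
observed values with the reported SEs — because with 24 instruments a
nonparametric resample of instruments is too coarse; whether the original
analyses used parametric or nonparametric draws is not stated anywhere we
could follow. Bootstraps are seeded and bit-reproducible, and restore the
caller's RNG state.

`scale_and_transform` converts a fit to per-raw-SD units (multiplying θ
and its interval by the exposure SD — equivalent to dividing γ by the SD
before fitting, and tested to commute) and optionally exponentiates to an
odds-ratio view for binary outcomes.

# The synthetic-cohort generator

The generator exists so that every claim the package makes is testable
against known truth. It emulates the statistical structure of the
metabolite-GWAS setting, not any particular cohort:

* **Genotypes**: diploid dosages as sums of two haplotypes; within an LD
  block, haplotype alleles share an equicorrelated latent Gaussian
  thresholded at the MAF quantile; blocks are independent. Thresholding
  *attenuates* the latent ρ: a latent 0.9 at MAF 0.3 yields a dosage
  correlation near 0.7. This attenuation is characterized exactly by the
  bivariate-normal orthant probability, and the test suite checks the
  generator against that oracle rather than assuming a value. The model
  was chosen over coalescent simulation because it gives direct analytic
  control of block correlation and is fast at desk scale.
* **Metabolite**: per-variant true effects are expressed in within-sex SD
  units; the latent trait is their dosage sum plus normal noise with
  variance 1 − h² within each sex. Raw values are
  $\exp(\sigma_{sex}\,\mathrm{latent})$ with log-scale SDs defaulting to
  0.321 (women) and 0.195 (men) — the reported sex-specific SDs of the
  motivating metabolite — so the analysis pipeline's log transform,
  5-SD winsorization and standardization are genuinely exercised.
  Defaults place one dominant locus carrying 25% of the male h² (default
  0.10) with a three-fold stronger female effect, matching the reported
  near-three-fold dimorphism; the implied female h² is then ≈ 0.29 and
  the sex-combined instrument strength ≈ 0.19, consistent with the
  reported 15.6% score-explained variance. The derived
  `beta_combined` vector — the per-allele effect on the pooled-
  standardized log metabolite, $(\sigma_f\beta_f + \sigma_m\beta_m)/2$
  over the pooled SD — is what a sex-combined GWAS estimates, and is the
  truth used by the summary-level generator.
* **Outcome**: liability = θ · (standardized exposure) + direct variant
  effects α + standard normal noise; binary outcomes threshold the
  liability at the configured case fraction (default 0.15), and
  per-variant logistic fits then put instrument-outcome effects on the
  log-odds scale, matching the case-control consortia such analyses draw
  on. α is zero (`none`), mean-zero normal (`balanced`, variance τ²) or
  mean-μ normal (`directional`). θ defaults to −0.05, a modest protective
  effect of the size such metabolite analyses report; calibration
  experiments override it explicitly. θ acts on the measured (log-scale)
  exposure — the same quantity the exposure GWAS standardizes — so the
  estimand of the simulated MR equals the configured θ exactly.
* **Two-sample structure** is enforced: exposure and outcome GWAS never
  share individuals.
* `cohort_gwas` is per-variant least squares (or logistic score fits),
  with covariates handled by prior residualization; it deliberately does
  *not* implement mixed models — relatedness and population structure are
  out of the generator's scope, so there is nothing for a mixed model to
  absorb.

What passing tests on these cohorts does **not** show: robustness to
population stratification, cryptic relatedness, imputation error,
selection bias, or winner's-curse effects from instrument selection —
none of which the generator produces.

# Numerical choices and problem sizes

* All calibration experiments fix seeds; bootstraps are seeded
  separately from data generation.
* The estimator-calibration experiments run at the reference conditions
  of 24 instruments and n = 20,000 per sample, 500 replicates, at the
  summary level (observed effects drawn from their exact sampling
  distributions) — orders of magnitude faster than individual-level
  simulation with the same first-two-moment structure. Bootstrap SEs in
  these experiments use 1000 draws; the package default stays at 5000.
* Individual-level chain checks (simulate → GWAS → harmonize → MR) run
  at n = 8000 with 16 equal-share, sex-homogeneous variants: equal
  shares and sex-homogeneity isolate estimator calibration from
  architecture effects. With the default sex-dimorphic dominant locus,
  sex-pooled marginal GWAS standard errors are mildly heteroskedastic
  (the residual contains (β_sex − β̄) × dosage), which depresses
  nominal-SE coverage a few points — a real property of pooled-sex GWAS
  on dimorphic traits and one reason the workflow reports sex-specific
  analyses with sex-specific SDs.
* The directional-pleiotropy robustness experiment gives 40% of
  instruments a direct effect μ = 0.04, chosen from the analytic bias
  formula (predicted IVW bias ≈ Σw γ α / Σw γ² ≈ 0.06–0.1, comfortably
  above the detection bound, while the invalid ratios sit ≈ +0.3 away
  from the valid cluster). The dominant instrument is kept valid so the
  weighted median's majority-weight condition holds — the experiment
  probes robustness inside the estimator's stated validity region, not
  its breakdown.
* Degenerate inputs: monomorphic variants yield NA rows (logged);
  zero-variance scores, phenotypes or strata raise errors; collinearity
  guards use condition-number 1e8 throughout.

# Known limitations

* Approximate conditional estimates inherit the accuracy of the LD
  reference; the implementation is validated against in-sample LD, and
  reference-mismatch error grows as panels diverge.
* Fixed-effect IVW standard errors ignore exposure-side sampling error;
  with strong instruments (the intended regime) the omission is a
  few-percent effect, visible in the calibration experiments as coverage
  near the lower edge of the nominal band.
* The liability-threshold/logistic route approximates log-odds effects
  well at modest case fractions; it is not an exact logistic model.
* No correlated-instrument MR: instruments are assumed LD-pruned
  upstream, and no outlier-removal (MR-PRESSO-style) variants are
  provided.
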