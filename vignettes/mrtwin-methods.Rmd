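---
title: "Models and methods in mrtwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mrtwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mrtwin` implements two complementary routes to a causal effect of one trait
on another from genetic data: two-sample Mendelian randomization (MR) on
GWAS summary statistics, and MR-DoC structural equation modeling of MZ/DZ
twin pairs with a polygenic score (PRS) as the instrument. This vignette
documents the models, the assumptions each identification strategy leans
on, the tunable parameters and their defaults, the synthetic-data
generators, and the numerical choices — including the places where the
design was genuinely open and what was decided.

## Arm 1: two-sample Mendelian randomization

### Instrument validity workflow

A SNP enters the candidate instrument set when it is genome-wide
significantly associated with the exposure (`p_exp_max = 5e-8`), present in
the outcome summary statistics, and *not* genome-wide significant for the
outcome (`p_out_min = 5e-8`) — a SNP whose strongest association is with
the outcome is more plausibly an outcome instrument. Both thresholds are
arguments with these conventional defaults.

Harmonization aligns the outcome effect to the exposure's effect allele:
identical orientation passes through, swapped alleles negate the outcome
beta and reflect its allele frequency (`1 - eaf`), and any other
configuration is an error naming the SNP. Strand flips are deliberately
**not** inferred: palindromic (A/T, C/G) SNPs, for which orientation cannot
be resolved from alleles at all, are flagged and excluded, and attempting
frequency-based strand inference for the rest would import exactly the
ambiguity the palindrome exclusion is meant to avoid.

Steiger filtering keeps an instrument only if it explains strictly more
variance in the exposure than in the outcome. Variance explained uses the
t-statistic identity `r^2 = t^2 / (t^2 + n - 2)` rather than an
allele-frequency formula because effect-allele frequency is an optional
input column; the two agree asymptotically for standardized traits. Ties
fail the filter (a tie provides no directional support), and instruments
with missing sample sizes are skipped with a warning rather than silently
passed. The reported `steiger_p` is the two-sided Fisher-z comparison of
the two correlations; the keep decision itself is by direction only, since
no significance threshold is imposed on the comparison.

The confounder exclusion list is a user-supplied file of SNP ids known to
associate with potential confounders (socioeconomic traits, substance use,
education, psychiatric disorders, ...). Two parallel tracks result: the
*conservative* track drops the listed SNPs before estimation; the *full*
track keeps them and lets constrained-ML MR select invalid instruments
data-drivenly. Agreement between tracks is itself evidence the exclusion
list captured the real problem instruments.

### The estimator battery

With harmonized effects $(\hat\beta_{Xj}, \hat\beta_{Yj})$ and outcome
standard errors $\sigma_{Yj}$, inverse-variance weights are
$w_j = 1/\sigma_{Yj}^2$ throughout.

**IVW (random effects).** $\hat\theta = \sum w_j \hat\beta_{Xj}
\hat\beta_{Yj} / \sum w_j \hat\beta_{Xj}^2$, the weighted regression
through the origin. Heterogeneity is Cochran's
$Q = \sum w_j (\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$, and the
random-effects standard error multiplies the fixed-effect one by
$\max(1, \sqrt{Q/(J-1)})$. The multiplicative (overdispersion) form with a
floor at 1 is the common implementation of a random-effects IVW; the floor
makes the estimator mildly conservative under the null (measured type-I
error ≈ 0.04 at the 5% level in the suite's calibration check).

**Weighted median.** The weighted quantile of the Wald ratios at cumulative
weight 0.5 with weights $(\hat\beta_{Xj}/\sigma_{Yj})^2$. The quantile is
*mass-based*: the smallest ratio whose normalized cumulative weight reaches
0.5, interpolating midway only when the boundary is hit exactly. This
convention was chosen over cumulative-midpoint interpolation because it
preserves two properties a median-type estimator should have: an
instrument carrying more than half the total weight returns its own ratio,
and splitting any instrument's weight across duplicates changes nothing.
The SE comes from a parametric bootstrap (default `n_boot = 10000`,
seeded) that redraws both exposure and outcome effects from their reported
standard errors.

**MR-Egger.** Weighted regression *with* intercept after orienting every
instrument so its exposure effect is positive (flipping both betas
together); without that orientation the intercept is not interpretable as
average directional pleiotropy. SEs use the same residual-based
multiplicative overdispersion floored at 1. A design in which all exposure
effects are equal is singular (slope and intercept collinear) and is
rejected rather than regularized.

**PRESSO-style global and outlier tests.** The observed statistic is the
weighted residual sum of squares against leave-one-out IVW predictions;
its null distribution is simulated parametrically (default
`n_sim = 1000`, seeded) by redrawing outcome effects around the
leave-one-out fitted values and exposure effects around their estimates.
Outlier p-values compare each observed weighted residual to its simulated
distribution, with significance Bonferroni-divided by J. The corrected
estimate is IVW on the non-outliers and is *identical* to raw IVW when no
outlier is found. The distortion test is not implemented: no downstream
decision in this package consumes it.

**MR-cML with model averaging.** The constrained Gaussian likelihood treats
the latent per-SNP exposure effects $b_j$ as free, the outcome means as
$\theta b_j + r_j$, and allows exactly $K$ instruments a nonzero direct
effect $r_j$. For fixed $K$ the likelihood profiles to a smooth 1-D
function of $\theta$ (each $b_j$ has a closed form given $\theta$), which
is minimized exactly inside the invalid-set re-selection loop. A plain
coordinate fixed-point iteration was tried first and discarded: it
converges only linearly and stalls under misspecification, and its greedy
selection falls into local optima at small J. Multistarts at the IVW
slope, zero, the ratio median, and each Wald ratio (each ratio being the
slope consistent with one instrument's validity) cover the selection
modes; the implementation matches exhaustive subset search on every tested
5-instrument instance. Model averaging uses weights
$\propto \exp(-\Delta/2)$ with $\Delta$ the AIC ($2K$ penalty) or BIC
($K\log n$ penalty) increment, the averaged variance adding between-model
spread; $n$ defaults to the smallest sample size on the instrument table.
The BIC penalty being heavier, its selected invalid set is empirically a
subset of the AIC one — the conservative/powerful pairing.

Estimator minima (1 instrument for Wald, 2 for IVW/median, 3 for
Egger/cML, 4 for PRESSO) are enforced with explicit
insufficient-instrument errors; confidence intervals are normal-based at
95% everywhere.

## Arm 2: MR-DoC twin modeling

### Model and identification

Per twin, with all observed variables residualized and standardized,

$$X = b_1\,\mathrm{PRS} + A_x + C_x + E_x, \qquad
  Y = g_1 X + b_2\,\mathrm{PRS} + A_y + C_y + E_y,$$

where A/C/E are additive-genetic, shared- and unique-environment
components with cross-twin correlations 1/0.5 (A, by zygosity), 1 (C) and
0 (E), and the PRS has unit variance and cross-twin correlation 1 (MZ) /
0.5 (DZ). The causal path $g_1$ and the horizontal-pleiotropy path $b_2$
are *simultaneously* identified because the within-person
unique-environment covariance between X and Y (covE) is fixed rather than
estimated — the model's key assumption. The default `covE = 0` asserts no
unique-environmental confounding; `cov_e_sensitivity()` refits over a
user grid of fixed values (the grid must be strictly increasing and
contain 0, whose entry reproduces the primary fit) to show how $\hat g_1$
would move if that assumption fails. On data generated with positive
E-confounding the curve falls monotonically in covE, and the fit fixing
covE at the generating value lands nearest the true causal path.

Because MZ co-twins share a genome, the model-implied MZ covariance with
two PRS variables is exactly singular; the MZ likelihood therefore uses a
single PRS per pair (a 5-variate density), implemented through the same
missingness machinery that handles incomplete data. MZ pairs with
materially different PRS values trigger a warning, since the model cannot
represent them.

A/C cross-trait correlation paths (`ra_xy`, `rc_xy`) are fixed at 0 in the
default MR-DoC configuration (the identified variant) and exposed by a
switch. In the **hybrid DoC** model — no PRS, reciprocal paths $g_1, g_2$
identified by the differing MZ/DZ cross-twin cross-trait covariance
signatures — freeing both causal paths *and* both cross-correlations would
mean 10 free parameters against 9 distinct informative moments, a
structurally flat likelihood. The default hybrid therefore estimates
$g_1, g_2$ with cross-correlations fixed at 0; `estimate_rarc = TRUE` with
`free_g2 = FALSE` gives the alternative identified configuration, and the
unidentified combination warns. When the observed information matrix is
not positive definite the fit is returned with an identification warning
and flagged SEs rather than dropped. In the weak-instrument limit
($b_1 \to 0$) the PRS block decouples and MR-DoC collapses onto the hybrid
fit; the suite verifies estimate and SE agreement at $b_1 = 0$ to within
optimizer resolution (observed difference ~1e-4 at 4000 pairs).

### Likelihood, ordinal outcomes, optimization

Families are independent, so within a zygosity group all pairs share one
model-implied covariance. Complete continuous patterns reduce to
sufficient statistics (one crossproduct matrix per missingness pattern),
making each likelihood evaluation O(1) in the number of families; rows
with missing variables contribute their marginal density pattern-wise
(FIML). Model means are fixed at zero — inputs are centered and scaled to
unit variance during fitting (pooled over twins and zygosity), and
estimates are reported on that standardized scale.

A 3-level ordinal outcome is a latent liability cut at thresholds fixed in
advance at the inverse-normal cumulative category proportions,
$\tau_1 = \Phi^{-1}(n_0/N)$, $\tau_2 = \Phi^{-1}((n_0+n_1)/N)$ (pooled
MZ+DZ counts by default; an empty top category is an error instructing
collapse). Identification of the threshold scale requires unit liability
variance, imposed exactly by solving the unit-variance constraint for the
outcome's unique-environment path (the constraint is linear in $e_y^2$).
Each pair's likelihood multiplies the continuous margin by the conditional
bivariate-normal rectangle probability between thresholds. Rectangle
probabilities use a vectorized 20-node Gauss–Legendre evaluation of the
classical single-integral reduction of the bivariate normal CDF for
$|\rho| \le 0.925$ (absolute error ~1e-14, cross-checked against
`mvtnorm::pmvnorm` in the tests) and delegate rarer extreme correlations
to `mvtnorm` — a vectorized path matters because one likelihood evaluation
needs thousands of rectangles.

Optimization is quasi-Newton (`nlminb`) on the free path coefficients with
multistart (default `starts = 10`: defaults plus seeded jitters, SD 0.15),
relative tolerance 1e-10, and a large finite penalty for non-positive-
definite implied covariances or an infeasible liability constraint.
Standard errors come from the numerically differenced observed information
at the optimum; a non-positive-definite information matrix flags the fit
(`se_ok = FALSE`) instead of discarding it. Path coefficients are
sign-indeterminate (only their squares enter variances); causal,
instrument and pleiotropy paths are sign-identified.

## Preprocessing

`residualize()` regresses a measure on fixed covariates (genetic PCs, sex,
age) plus a site random intercept fitted by REML through `lme4`, returning
the response minus fixed predictions and predicted (BLUP) site effects.
With fewer than three sites the random effect is statistically
meaningless and the function degrades to fixed-effects-only least squares
with a warning — that path is exactly idempotent and orthogonal to the
covariates. Zero-inflated checklist scores use `log10(x + 1)`, keeping
zeros at zero. `bh_fdr()` validates inputs and applies the
Benjamini–Hochberg step-up rule via `stats::p.adjust`; the adjustment
family is all causal tests within one analysis direction of a pipeline
battery, which is also how `run_mrdoc_pipeline()` applies it.

## Synthetic-data generators

The generators are first-class, tested code and double as cross-module
oracles: the twin generator draws from the same path equations whose
implied moments the model assembles, so the empirical covariance of a
large simulation must match `mrdoc_implied_moments()` at every parameter
point — the central consistency check of the twin arm.

**Summary statistics** (`sumstats_scenario()`): J = 18 SNPs, true effect
θ = −0.15, 7 invalid instruments — the instrument landscape of the
motivating analysis. Exposure GWAS size 32,488; outcome size 167,500, the
*effective* sample size $4/(1/n_\text{case} + 1/n_\text{control})$ of a
case-control GWAS with ~44k cases and ~915k controls, so outcome standard
errors sit on a realistic scale. Per-SNP exposure variance explained
defaults to 0.002 — a selected instrument is genome-wide significant by
construction, so the generator should not routinely produce candidates
that fail their own selection gate. Effect alleles are oriented as
exposure-increasing (the top-hits convention), which makes mean-nonzero
pleiotropy *directional*: with random orientations a constant direct
effect cancels in ratio space and confounded instruments would barely
bias IVW. Pleiotropic effects default to N(0.02, 0.005), sized to bias
IVW visibly while keeping invalid instruments below the outcome
genome-wide threshold (instruments that crossed it would never have
entered the candidate set). Optional estimation-error correlation
`overlap_rho` emulates participant overlap between the two GWAS samples;
`noise_scale = 0` gives noiseless effects for exactness tests; a fraction
of outcome records is emitted with swapped alleles so harmonization has
real work.

**Twin pairs** (`twin_scenario()`): 199 MZ / 257 DZ pairs by default (the
European twin-sample size), causal path 0.3, instrument path 0.3, ACE
residual shares 0.5/0.2/0.3 (exposure; brain-structure measures are
strongly heritable) and 0.4/0.2/0.4 (outcome; behavioral measures carry
more unique environment). Both traits are standardized to unit population
variance: the exposure's shares apply to $1 - b_1^2$ and the outcome's
residual paths are rescaled so the total (liability) variance is exactly
1, which also makes generated thresholds and fitted thresholds directly
comparable. Default ordinal prevalences are 470/34/7 out of 511 (≈ 92%,
6.7%, 1.4%) — no suicidal thoughts or behaviors, ideation only,
behaviors.

What the generators deliberately do **not** emulate: linkage
disequilibrium between instruments (inputs are assumed pre-clumped),
winner's curse in instrument selection, individual-level genotypes behind
the PRS, assortative mating, sex-limitation or G×E structure, and
non-normal liability. Passing tests therefore certify the estimators
under the stated generating model, not robustness to those violations.

## Problem sizes and numerical tolerances in the test suite

The suite's simulation sizes are chosen to give tight Monte-Carlo
resolution while keeping a full run around five minutes on one CPU:
closed-form oracle equivalences at 1e-10 on 20 randomized instances;
exhaustive-subset cML verification at J = 5; IVW type-I error over 2000
seeded null replicates (band [0.03, 0.07]); estimator recovery over 500
replicates; the moment oracle at 10⁶ simulated pairs per parameter point
(bounded at 4 Monte-Carlo SEs per covariance entry); MR-DoC recovery and
95%-CI coverage over 200 replicates at 2000+2000 pairs and unbiasedness
at the 199+257 study scale over 100 replicates; ordinal recovery at
1500+1500 pairs. All replication seeds are fixed in the tests.

## Known limitations

- Two-sample MR here is univariable; multivariable MR, LD-aware
  (correlated-instrument) methods, and mode-based/RAPS/CAUSE estimators
  are out of scope.
- The twin models assume bivariate normal liability, no dominance (ADE),
  no sex limitation, and no moderation; thresholds are fixed, not jointly
  estimated.
- MR-cML is implemented without the data-perturbation variant; the
  reported SEs are asymptotic model-averaged ones.
- PRESSO's distortion test is omitted.
- Residualization fits the covariate model on the pooled sample (not per
  zygosity group), matching standard practice when group differences in
  covariate effects are not of interest.
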