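---
title: "Modelling left ventricular mass against skeletal muscle measures with skew-t regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling left ventricular mass against skeletal muscle measures with skew-t regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Sarcopenia — the age-related loss of skeletal muscle mass — appears to be
linked to cardiac structure. Cohort studies relate DXA-derived muscle
measures (total skeletal muscle mass SMM, appendicular lean mass ALM, the
skeletal muscle index SMI = ALM/height², BMI) to echocardiographic left
ventricular mass (LVM). Two statistical problems dominate such analyses:

1. **Severe multicollinearity.** SMI, SMM, ALM and BMI all proxy body size;
   variance inflation factors (VIF) above 10 are typical, so ordinary least
   squares coefficients are unstable.
2. **A right-skewed, heavy-tailed outcome.** LVM from the cube formula is a
   third power of summed linear dimensions; its distribution is visibly
   right-skewed (sample skewness near 0.9), so Gaussian-error regression is
   suspect.

`lvmskew` implements the corresponding analysis pipeline: derived clinical
measures, the descriptive two-group comparison machinery, VIF screening plus
ridge regression, a Bayesian linear regression with skew-t residuals
sampled by MCMC, Gelman-Rubin diagnostics, and LOWESS trend curves — all
exercised on a synthetic-cohort generator, because subject-level data of this
kind are typically not deposited.

## Derived measures

* BMI = weight (kg) / height (m)²; SMI = ALM (kg) / height (m)².
* LVM uses the linear-method (Devereux-convention) cube formula
  \(0.8 \times 1.04\,[(\mathrm{LVDd}+\mathrm{IVSTd}+\mathrm{LVPWTd})^3 -
  \mathrm{LVDd}^3] + 0.6\) **with lengths in cm**. Echo dimensions are
  tabulated in mm, so the package converts mm → cm before cubing: the
  0.8·1.04 constant belongs to the cm convention, under which adult values
  land in the familiar 100–200 g range (the mm scale would produce values
  three orders of magnitude larger).
* Low muscle mass follows the AWGS-2019 cutoffs, *strictly* below
  7.0 kg/m² (male) / 5.4 kg/m² (female).

## The synthetic cohort: what it emulates and what it does not

The generator (`generate_cohort()`) is first-class, tested code. Its defaults
are the study conditions the rest of the package assumes:

* 278 subjects, ages uniform on 18–91, 159 females (the female count is fixed
  by rounding, not Bernoulli, so the cohort composition is reproducible);
* heights and the muscle/body-size measures lognormal around sex-specific
  centres chosen to match published group medians (male/female height 170/158
  cm, SMI 7.6/5.9 kg/m², SMM 45/34 kg, BMI 24.3 kg/m² both sexes);
* one latent body-size factor drives SMI, SMM and BMI at
  `collinearity_rho = 0.95` (ALM is SMI × height² by definition), which puts
  the VIF of all four measures above 10 — the multicollinearity regime the
  ridge stage exists for;
* the SMI distribution is calibrated by a single multiplicative shift so that
  *exactly* `target_low_smm_count = 80` subjects fall below their sex cutoff.
  This is a location calibration of the distribution, not post-hoc
  relabelling; a target that would need more than a ~2-fold rescaling errors
  out as infeasible;
* LVM is generated as `intercept + (standardized covariates) %*% beta_true +
  skew-t noise`, and the echo dimensions are then *back-solved*: LVDd has a
  fixed N(45.8, 3.0 mm) distribution, the wall-thickness sum comes from
  inverting the cube formula (the asymmetry between IVSTd and LVPWTd is
  noise that leaves their sum — hence LVM — unchanged), so recomputing LVM
  from the echo columns reproduces the generative target to machine
  precision. The generative model is therefore exactly the model the
  inference stages assume.
* Comorbidity flags are independent Bernoulli draws at the published pooled
  prevalences.

**Noise calibration.** The skew-t noise defaults (`alpha_true = 6`,
`nu_true = 8`, `sigma_true = 40` g, intercept 96 g) were chosen once, via the
closed-form skew-t moments (`skew_t_moments()`), so that generated LVM has
mean ≈ 131 g, sd ≈ 35 g and mean sample skewness ≈ 0.9 across seeds — the
regime the outcome is reported to occupy. Sample skewness of a heavy-tailed
variable at n = 278 is volatile (sd ≈ 0.3 across seeds), so calibration
targets the *mean over 20 seeds*, not each seed.

What the generator does **not** emulate: age–muscle coupling (SMI does not
decline with age in the default cohort; tests of the age-stratified LOWESS
direction construct their own age-coupled data), longitudinal change,
within-subject correlation of the unused echo measures, measurement error in
DXA, or the screening process behind the cohort's composition. Passing tests
therefore validate the *statistical machinery* under the generative
assumptions, not epidemiological claims about real populations.

## Ridge regression and VIF

VIF_j = 1/(1 − R²_j) is computed as the diagonal of the inverse correlation
matrix. Ridge standardizes predictors internally (0/1 flags like continuous
ones, so coefficients are commensurate, in grams per SD) and centres the
response; the intercept is unpenalized and equals the response mean.
Standard errors use the standard ridge sandwich
σ̂²(XᵀX+kI)⁻¹XᵀX(XᵀX+kI)⁻¹ with σ̂² at `n − p − 1` df (263 at the default
cohort size), and CIs use the t quantile at those df — the rule that
reproduces published bounds from published (β, SE) pairs. The penalty is
chosen by generalized cross-validation over a log-spaced grid (ties to the
smallest k) because no penalty value is typically reported; a fixed penalty
can be supplied instead.

## The Bayesian skew-t regression

Residuals follow the Azzalini–Capitanio skew-t with scale σ, slant α and ν
degrees of freedom:
\[
f(e) = \frac{2}{\sigma}\, t_\nu(e/\sigma)\,
T_{\nu+1}\!\Big(\alpha \tfrac{e}{\sigma}\sqrt{\tfrac{\nu+1}{\nu+e^2/\sigma^2}}\Big).
\]
The sampler uses the stochastic representation
\(e = \sigma\lambda^{-1/2}(\delta z_0 + \sqrt{1-\delta^2}\,z_1)\),
δ = α/√(1+α²), λ ~ Gamma(ν/2, ν/2), giving per-observation latents: a mixing
scale λᵢ (the heavy tails) and a half-normal zᵢ (the skewness). Full
conditionals are conjugate for β (Gaussian), λᵢ (Gamma) and zᵢ (truncated
normal, sampled by inverse CDF with an exponential-rejection branch deep in
the tail); (log σ, α) move by joint random-walk Metropolis whose step sizes
adapt toward ~0.3 acceptance during burn-in only, preserving detailed balance
afterwards. When ν is grid-sampled, (ν, λ) are drawn as one block — ν from
its λ-marginalized conditional (a closed-form Gamma integral), then λ given
ν — because ν conditioned on λ barely moves.

Design choices, made where the problem is genuinely open:

* **Univariate response.** The multivariate transformation matrix of the
  general skew formulation collapses to the identity for a single outcome;
  only the univariate case is implemented.
* **One skew family.** The Azzalini–Capitanio skew-t is the single residual
  family; variant "skew-I" formulations are not distinguished.
* **ν defaults to fixed 4** (clearly heavy-tailed but with finite variance),
  with optional grid sampling over 3–30. ν is weakly identified at n ≈ 278
  and rarely reported, so fixing it is the transparent default.
* **Priors.** Flat on coefficients by default, with a Gaussian(0, τ²)
  "ridge" prior available for sensitivity analysis; inverse-gamma(0.001,
  0.001) on σ²; N(0, 100²) on α. Posterior means shift by < 0.5 posterior SD
  across τ ∈ {1, 10, 100} on simulated data (tested).
* **Burn-in** is the first half of each chain. Desk scale is 4 chains ×
  2,000 iterations — enough for the coefficient posteriors the tests check,
  chosen so the whole suite runs in minutes; a full-scale switch (32 ×
  20,000) exists for full runs.
* **Intercept vs skewness mean.** A location-0 skew-t has positive mean
  (σδb_ν), so an intercept and the slant are weakly separated in small
  samples; when data are generated without an intercept, fitting without one
  (`intercept = FALSE`) is the correctly specified model and is what the
  recovery and coverage experiments use. RMSE/MAE at the posterior-mean
  coefficients deliberately exclude the noise mean, which is why RMSE can sit
  well above MAE for skewed residuals.

Reported "standard errors" of posterior summaries are posterior standard
deviations, and intervals are equal-tailed 2.5–97.5% quantiles pooled across
chains.

## Convergence diagnostics

`gelman_rubin()` implements the classic (non-split, non-rank-normalized)
potential scale reduction factor
\(\hat R = \sqrt{((n-1)/n\,W + B/n)/W}\). Two facts worth stating plainly:
on *identical* chains it returns √((n−1)/n) < 1 (e.g. √(2/3) for length-3
chains), and on short or unconverged chains it can sit near 2 — the package
logs the conventional warning above 1.1 rather than treating large values as
acceptable. A split-chain variant is available (`split = TRUE`), and
`shrink_trajectory()` evaluates R̂ over growing prefixes for the usual
shrink-factor plots.

## LOWESS

`lowess_fit()` is Cleveland's classic scheme, implemented directly because
the package pins down the exact definition its tests verify: at every
observed x, a weighted local *linear* fit over the ⌊frac·n⌋ nearest
neighbours (stable index tie-break) with tricube weights scaled by the
farthest neighbour, then `robust_iters` bisquare reweighting passes with
scale 6·median|residual|. Defaults frac = 2/3, robust_iters = 3. Local
linear fits reproduce straight lines exactly (to 1e-10 in tests) and each
point matches an independent per-point weighted-least-squares oracle; the
base-R smoother (`stats::lowess`, which takes small numerical shortcuts)
agrees to well within the noise level and serves as an independent
cross-check in the tests. Degenerate local designs fall back to the weighted
mean; constant x errors out.

Age stratification splits at 60 years (< 60 vs ≥ 60) and fits each stratum
independently; a stratum smaller than 5 points fails naming the stratum.

## Numerical choices and degenerate inputs

* Chi-square on 2×2 tables is Pearson *without* continuity correction —
  the convention that reproduces published statistics from their counts —
  and fails on zero margins.
* Mann-Whitney uses the tie-corrected normal approximation without
  continuity correction (z is what comparison tables print); for groups of
  ≤ 10 without ties the exact two-sided p replaces the approximation.
* Welch's t is the default t-test variant (pooled is an option); which
  variant published tables used is generally not determinable.
* Normality routing: a variable goes non-parametric if either group's
  Shapiro-Wilk p < 0.05.
* The cube formula accepts zero wall thicknesses (returning the 0.6 g
  offset) but requires a positive LVDd; classification requires known sex
  labels; imputation fails if all values are missing.
* All problem sizes in the test-suite experiments (n = 120–500 for sampler
  checks, 100 replicates for coverage, 20 seeds for skewness calibration)
  are the package's chosen desk-scale study conditions and are stated in the
  tests themselves.

## Known limitations

* The sampler is plain R; at 32 × 20,000 on n ≈ 278 expect minutes, not
  seconds. No HMC/NUTS, no WAIC/LOO model comparison.
* ν on the grid is a coarse treatment of tail weight; fixed-ν misspecification
  mainly inflates σ's posterior rather than biasing coefficients (observed on
  simulated data).
* The generator's marginals are stylised (lognormal anthropometrics,
  independent flags); it reproduces the *statistical structure* a cohort of
  this kind exhibits, not any particular population.
* Coefficient estimates from real cohort data are not reproducible here
  because such data are not deposited; the pipeline's correctness is instead
  established against analytic oracles, enumeration, quadrature and
  simulation truth.
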