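# lvmskew

Statistical machinery for studying the association between skeletal-muscle
mass measures and echocardiographic left ventricular mass (LVM) in cohorts
screened for low muscle mass (sarcopenia workups).

Analyses of this kind face two problems at once. The DXA-derived muscle and
body-size measures — total skeletal muscle mass (SMM), appendicular lean mass
(ALM), the skeletal muscle index (SMI = ALM/height², the quantity the
AWGS-2019 low-muscle cutoffs are defined on) and BMI — are severely
collinear (VIF > 10), destabilising ordinary least squares. And the outcome,
LVM from the linear-method cube formula

    LVM = 0.8 · 1.04 · [(LVDd + IVSTd + LVPWTd)³ − LVDd³] + 0.6   (lengths in cm, grams)

is right-skewed and heavy-tailed, so Gaussian-error regression is suspect.
`lvmskew` addresses both: **ridge regression** (with GCV penalty selection,
sandwich standard errors and t-based CIs) for the collinearity, and a
**Bayesian linear regression with Azzalini–Capitanio skew-t residuals**,

    y_i = x_i' β + e_i,   e_i ~ SkewT(σ, α, ν),
    f(e) = (2/σ) t_ν(e/σ) T_{ν+1}( α (e/σ) √((ν+1)/(ν+e²/σ²)) ),

sampled by Metropolis-within-Gibbs under the classic scale-mixture
augmentation (Gamma mixing scales λᵢ for the tails, half-normal latents zᵢ
for the skewness; conjugate β, λ, z updates; joint random-walk Metropolis on
(log σ, α) with burn-in-only adaptation). Around these sit the supporting
stages such cohort papers report: derived clinical measures (BMI, SMI,
Devereux-type LVM, AWGS classification), a two-group comparison table
(Shapiro-Wilk routing to Welch t or Mann-Whitney U; Pearson chi-square
without continuity correction for flags; median imputation), Gelman-Rubin
convergence diagnostics with shrink-factor trajectories, and LOWESS trend
curves with age stratification (< 60 vs ≥ 60 years).

Because subject-level data of this kind are typically not deposited, the
package ships a **synthetic-cohort generator** that reproduces the
statistical structure the analyses assume — 278 subjects aged 18–91, exactly
80 below the sex-specific AWGS cutoffs (7.0 / 5.4 kg/m²), a shared
body-size factor putting the VIF of SMI/SMM/ALM/BMI above 10, and LVM built
from skew-t regression noise calibrated to sample skewness ≈ 0.9 — with echo
dimensions back-solved so the cube formula recovers the generative LVM
exactly. Every inference stage is tested against independent oracles
(enumeration, closed forms, quadrature, simulation truth) on that generator.

## Worked example

```r
library(lvmskew)

co <- generate_cohort(generator_config())
nrow(co)                                  # 278
sum(co$low_smm_flag)                      # 80
round(sample_skewness(co$lvm), 2)         # 1.1 (right-skewed outcome)

X <- cbind(age = co$age, gender = as.numeric(co$sex == "female"),
           as.matrix(co[, covariate_roster()[-(1:2)]]))
round(compute_vif(X)[c("smi", "smm", "alm", "bmi")], 1)
#>  smi  smm  alm  bmi
#> 28.5 22.4 11.2 10.4                     # severe collinearity

fit <- fit_ridge(X, co$lvm, penalty_k = select_penalty(X, co$lvm))
subset(ridge_table(fit), variable %in% c("const", "age", "smi", "alm"))
#>  variable    beta    se      t     p  ci_low ci_high
#>     const 127.837 1.766 72.376 0.000 124.359 131.315
#>       age   2.200 1.302  1.689 0.092  -0.365   4.764
#>       smi   4.699 0.770  6.104 0.000   3.183   6.215
#>       alm   4.802 1.029  4.666 0.000   2.775   6.828

ch <- run_sampler(scale(X), co$lvm, skew_t_model_spec(),
                  n_chains = 4, n_iter = 2000, seed = 1)
post <- summarize_posterior(ch)
post[post$variable %in% c("age", "smi", "alm", "sigma", "alpha"), ]
#>  variable  mean   sd ci_low ci_high
#>       age  4.19 1.24   1.76    6.58
#>       smi 17.65 6.86   4.38   31.03   # SMI's interval excludes 0
#>       alm 11.69 4.26   3.06   19.62
#>     sigma 31.78 2.57  26.92   36.86   # residual scale, grams
#>     alpha  4.05 1.25   2.09    7.05   # right skew recovered

posterior_fit_error(ch, scale(X), co$lvm)  # RMSE 41.6 g, MAE 31.0 g
gelman_rubin(ch, "smi")                    # 1.014
```

Coefficients are in grams of LVM per standard deviation of each predictor
(predictors are standardized, 0/1 flags included, so effects are
commensurate). `sigma`/`alpha` are the residual scale and slant of the
skew-t law; RMSE exceeds MAE here because predictions at the posterior-mean
coefficients exclude the positive mean of the skewed residual law.

The same pipeline runs as a scripted workflow:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + data dictionary
Rscript analysis/02_descriptives.R      # two-group comparison table
Rscript analysis/03_ridge.R             # VIF screening + ridge fit
Rscript analysis/04_bayes_skewt.R       # posterior, RMSE/MAE, Gelman-Rubin
Rscript analysis/05_lowess.R            # trend curves, age-stratified
```

with outputs under `results/`, or programmatically via
`run_pipeline(run_config(...))`, which writes every table plus a manifest
with seeds and checksums (reruns are bit-identical). `run_config(full_scale
= TRUE)` switches the sampler to 32 chains × 20,000 iterations.

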