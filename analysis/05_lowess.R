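#!/usr/bin/env Rscript
# Stage 5: LOWESS trends of LVM against age and the muscle measures, plus
# age-stratified (< 60 vs >= 60 years) curves of SMI and LVM against age.

library(lvmskew)

cohort <- validate_cohort_csv("results/cohort.csv")
dir.create("results/lowess", showWarnings = FALSE)

for (v in c("age", "smi", "smm", "alm")) {
  cu <- lowess_fit(cohort[[v]], cohort$lvm)
  write.csv(lowess_curve_df(cu),
            sprintf("results/lowess/lvm_vs_%s.csv", v), row.names = FALSE)
  cat(sprintf("LVM vs %-4s: Spearman(fitted, %s) = %+.2f\n", v, v,
              cor(cu$fitted, cu$x_grid, method = "spearman")))
}

for (resp in c("smi", "lvm")) {
  st <- stratified_trends(cohort, "age", resp, split_age = 60)
  write.csv(lowess_curve_df(st$younger),
            sprintf("results/lowess/%s_vs_age_under60.csv", resp),
            row.names = FALSE)
  write.csv(lowess_curve_df(st$older),
            sprintf("results/lowess/%s_vs_age_over60.csv", resp),
            row.names = FALSE)
  cat(sprintf("%s vs age: %d subjects < 60, %d >= 60\n",
              resp, st$n_younger, st$n_older))
}
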