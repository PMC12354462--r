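#!/usr/bin/env Rscript
# Stage 3: multicollinearity screening and ridge regression of LVM.
#
# VIF confirms the SMI/SMM/ALM/BMI block is severely collinear (VIF > 10),
# which is the motivation for the L2 penalty. The penalty is selected by
# generalized cross-validation; coefficients are per SD of each predictor,
# with sandwich standard errors and t-based 95% CIs at n - p - 1 df.

library(lvmskew)

cohort <- validate_cohort_csv("results/cohort.csv")
X <- cbind(age = cohort$age, gender = as.numeric(cohort$sex == "female"),
           as.matrix(cohort[, covariate_roster()[-(1:2)]]))
y <- cohort$lvm

vif <- compute_vif(X)
write.csv(data.frame(variable = names(vif), vif = round(unname(vif), 2)),
          "results/vif.csv", row.names = FALSE)
cat("VIF of the muscle/body-size block:\n")
print(round(vif[c("smi", "smm", "alm", "bmi")], 1))

k <- select_penalty(X, y)
fit <- fit_ridge(X, y, penalty_k = k)
tab <- ridge_table(fit)
tab[, -1] <- round(tab[, -1], 4)
write.csv(tab, "results/ridge.csv", row.names = FALSE)

cat(sprintf("\nGCV-selected penalty k = %.4g; residual df = %d; RMSE = %.2f g\n",
            k, fit$residual_df, fit$rmse))
cat("coefficients significant at P < 0.05:\n")
print(tab[tab$p < 0.05, ], row.names = FALSE)
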