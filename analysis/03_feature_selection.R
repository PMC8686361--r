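#!/usr/bin/env Rscript
# Feature selection on the measured PD-cohort features: univariable
# logistic screen (p < 0.05), variance-inflation filter (VIF > 2.5),
# stepwise binary logistic regression adjusting for age, sex, height and
# BMI, and ROC/Youden cutoffs for the selected features. Produces the
# selection report shaped like a clinical turning study's selection table.

library(turn360)

feats <- read.csv("results/features_pd.csv")
subs <- read_metadata("results/cohort_pd_subjects.tsv")
labels <- as.integer(feats$group != "control")

fcols <- setdiff(names(feats), c("subject_id", "group"))
usable <- fcols[vapply(feats[fcols], function(v)
  all(is.finite(v)) && sd(v) > 0, logical(1))]
tab <- cbind(feats[usable],
             age = subs$age, sex = as.integer(subs$sex == "M"),
             height = subs$height, bmi = subs$bmi)

res <- select_features(tab, labels,
                       covariates = c("age", "sex", "height", "bmi"))

cat(sprintf("screen kept %d of %d features; VIF dropped %d; stepwise kept: %s\n",
            sum(res$screen$kept), length(usable),
            length(res$vif$dropped),
            paste(res$selection$selected, collapse = ", ")))
print(res$selection)

sel_tab <- res$selection$coefficients
sel_tab$cutoff <- vapply(sel_tab$feature, function(f)
  res$roc[[f]]$cutoff, numeric(1))
sel_tab$auc <- vapply(sel_tab$feature, function(f) res$roc[[f]]$auc,
                      numeric(1))
sel_tab$sensitivity <- vapply(sel_tab$feature, function(f)
  res$roc[[f]]$sensitivity, numeric(1))
sel_tab$specificity <- vapply(sel_tab$feature, function(f)
  res$roc[[f]]$specificity, numeric(1))
sel_tab$nagelkerke_r2 <- res$selection$nagelkerke_r2
write.csv(sel_tab, "results/selection_pd.csv", row.names = FALSE)
cat("\nWrote results/selection_pd.csv.\n")
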