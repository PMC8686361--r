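#!/usr/bin/env Rscript
# Associations between clinical scores and turning features in the
# synthetic PD cohort: blockwise stepwise linear regression (block 1 =
# age, sex, height, BMI forced; block 2 = turning features, stepwise on
# partial-F p-values) for each clinical dependent, plus rank/linear
# correlations among the clinical scores. The cohort generator plants the
# links (UPDRS scores and PIGD on the outer contralateral coordination
# parameter, NFOGQ negatively on outer step length), so recovered signs
# are checkable against results/cohort_pd_truth.csv.

library(turn360)

feats <- read.csv("results/features_pd.csv")
subs <- read_metadata("results/cohort_pd_subjects.tsv")

tab <- cbind(feats[setdiff(names(feats), c("subject_id", "group"))],
             age = subs$age, sex = as.integer(subs$sex == "M"),
             height = subs$height, bmi = subs$bmi,
             subs[c("updrs_total", "updrs_iii", "pigd", "nfogq")])
cand <- c("step_length_outer", "dt_contra_outer", "max_anti_phase",
          "step_width", "incline_angle")

reports <- list()
for (dep in c("updrs_total", "updrs_iii", "pigd", "nfogq")) {
  rep <- stepwise_linear_blocks(tab, dep, candidates = cand)
  print(rep)
  reports[[dep]] <- cbind(dependent = dep, rep$coefficients,
                          r_squared = rep$r_squared)
}
write.csv(do.call(rbind, reports), "results/association_models.csv",
          row.names = FALSE)

cat("\ncorrelations with UPDRS total:\n")
for (v in c("dt_contra_outer", "step_length_outer")) {
  sp <- correlate(tab[[v]], tab$updrs_total, "spearman")
  pe <- correlate(tab[[v]], tab$updrs_total, "pearson")
  cat(sprintf("  %-18s spearman rho = %6.3f (p = %.3g); pearson r = %6.3f\n",
              v, sp$estimate, sp$p, pe$estimate))
}
cat("\nWrote results/association_models.csv.\n")
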