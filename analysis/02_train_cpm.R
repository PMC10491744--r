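#!/usr/bin/env Rscript
# Step 2 — leave-one-out cross-validated CPM for both mood targets.
#
# For each left-out subject, edges are selected at p < 0.001 on the
# remaining subjects, positive/negative network strengths are summed, and
# linear models (including the bivariate combined model) predict the
# held-out score. Consensus masks (edges selected in every fold) feed the
# interpretation step; the full-sample frozen model feeds external
# validation.

library(moodcpm)
dir.create("results", showWarnings = FALSE)

g <- generate_cohort(sim_config(n_subjects = 81, n_nodes = 368,
                                n_outliers = 1, seed = 11))
qc <- flag_outlier_subjects(g$cohort$edges)
cohort <- subset_cohort(g$cohort, qc$subject_id[!qc$flag])
cat("Analyzing", n_subjects(cohort), "subjects after QC exclusion\n\n")

for (target in c("hdrs5", "ymrs")) {
  cv <- run_loocv(cohort, target)
  print(cv)
  tab <- data.frame(subject_id = cohort$subject_id,
                    observed = cv$observed,
                    predicted_pos = cv$predictions[, "positive"],
                    predicted_neg = cv$predictions[, "negative"],
                    predicted_combined = cv$predictions[, "combined"])
  out <- sprintf("results/loocv_%s.tsv", target)
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  predictions ->", out, "\n")
  jsonlite::write_json(
    list(target = target, consensus = cv$consensus,
         r = as.list(cv$r), rmse = as.list(cv$rmse)),
    sprintf("results/consensus_%s.json", target), auto_unbox = TRUE,
    digits = NA)

  model <- train_cpm(cohort, target)
  write_network_model(model, sprintf("results/model_%s.json", target))
  cat("  frozen model ->", sprintf("results/model_%s.json", target), "\n\n")
}
cat("Note: only the depressed-mood (hdrs5) target has a planted network in\n")
cat("this simulated cohort; the ymrs run shows the pipeline's behavior on a\n")
cat("target with no embedded signal.\n")
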