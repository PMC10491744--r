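#!/usr/bin/env Rscript
# Step 5 — out-of-sample validation of the frozen model.
#
# The full-sample model trained in step 2 (frozen masks + coefficients) is
# applied, without any re-selection or re-fitting, to an independent
# 43-subject cohort drawn from the same generative process with
# heterogeneous per-subject noise scales (emulating mixed scanners and run
# counts) and two subjects missing the elevated-mood score.

library(moodcpm)
dir.create("results", showWarnings = FALSE)

g <- generate_cohort(sim_config(n_subjects = 81, n_nodes = 368,
                                n_outliers = 1, seed = 11))
qc <- flag_outlier_subjects(g$cohort$edges)
cohort <- subset_cohort(g$cohort, qc$subject_id[!qc$flag])
model <- if (file.exists("results/model_hdrs5.json")) {
  read_network_model("results/model_hdrs5.json")
} else {
  train_cpm(cohort, "hdrs5")
}

gv <- generate_cohort(sim_config(n_subjects = 43, n_nodes = 368,
                                 noise_scale_range = c(0.8, 1.3),
                                 n_missing_ymrs = 2, id_prefix = "V",
                                 seed = 12),
                      truth = g$truth)
cat("Validation cohort:", n_subjects(gv$cohort), "subjects (independent ids)\n")

pred <- apply_trained_model(model, gv$cohort)
ev <- evaluate_transfer(pred[, "combined"], gv$cohort$scores$hdrs5,
                        gv$cohort$covariates[, c("age", "gender")])
cat(sprintf("HDRS-5 transfer: r = %.3f (df = %d, p = %.4g); partial r = %.3f (p = %.4g); RMSE = %.2f; n = %d\n",
            ev$r, ev$df, ev$p, ev$r_partial, ev$p_partial, ev$rmse, ev$n))

# the elevated-mood roster loses its two missing-score subjects
ph_val <- data.frame(subject_id = gv$cohort$subject_id,
                     gv$cohort$covariates, gv$cohort$scores)
co_ymrs <- assemble_cohort(gv$cohort$edges, ph_val, "ymrs")
cat("YMRS analyzable subjects after missing-score exclusion:",
    n_subjects(co_ymrs), "of", n_subjects(gv$cohort), "\n")

jsonlite::write_json(
  list(n = ev$n, n_excluded_ymrs = n_subjects(gv$cohort) - n_subjects(co_ymrs),
       r = ev$r, p = ev$p, df = ev$df,
       r_partial = ev$r_partial, p_partial = ev$p_partial,
       df_partial = ev$df_partial, rmse = ev$rmse,
       model_target = model$target, model_alpha = model$alpha,
       model_n_train = model$n_train),
  "results/validation.json", auto_unbox = TRUE, digits = NA)
cat("Validation report -> results/validation.json\n")
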