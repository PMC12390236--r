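#!/usr/bin/env Rscript
# Step 4 — the experiment grids.
#
# Three experiment families on the simulated cohort, after correlation
# pruning:
#   (a) model comparison: random forest vs gradient boosting vs RBF-SVR,
#       10-fold CV, all data, for each symptom and the patient-reported
#       state;
#   (b) validation-scheme comparison: 10-fold vs leave-one-patient-out for
#       the best family;
#   (c) device-scope comparison: all data vs phone-only vs armband-only.
# Flags the best model per target by R2 (ties by lower class-balanced MAE).
#
# Writes: results/metrics_models.csv, results/metrics_scopes.csv,
#         results/predictions_best.csv

library(pdsense)

coh <- read_cohort("results/cohort")
ft <- assemble_feature_table(coh)
pruned <- prune_correlated(ft$features)$retained
cat("correlation pruning: ", ncol(ft$features), " -> ", length(pruned),
    " columns\n", sep = "")
ft$features <- ft$features[, pruned]
ft$feature_info <- ft$feature_info[match(pruned, ft$feature_info$name), ]

targets <- c("tremor", "bradykinesia", "stiffness", "dyskinesia",
             "trs_patient")
grid_models <- run_grid(ft, targets = targets,
                        models = c("rf", "xgb", "svm"),
                        schemes = list(`10F` = cv_scheme("kfold", k = 10,
                                                         seed = 3)),
                        seed = 3, keep_predictions = TRUE)
write.csv(grid_models, "results/metrics_models.csv", row.names = FALSE)
best <- grid_models[grid_models$best,
                    c("target", "model", "r2", "r", "mae", "bmae", "bmse")]
cat("best family per target (10-fold, all data):\n")
print(best, row.names = FALSE, digits = 3)

grid_scheme <- run_grid(ft, targets = "tremor", models = "svm",
                        schemes = list(`10F` = cv_scheme("kfold", k = 10,
                                                         seed = 3),
                                       LOO = cv_scheme("loo_patient")),
                        seed = 3)
cat(sprintf("tremor SVM: 10F R2 = %.3f, LOO R2 = %.3f (gap %.3f)\n",
            grid_scheme$r2[1], grid_scheme$r2[2],
            abs(diff(grid_scheme$r2))))

grid_scopes <- run_grid(ft, targets = c("tremor", "trs_patient"),
                        scopes = list(all_data = list(),
                                      phone = list(device = "phone"),
                                      myo = list(device = "myo")),
                        models = "svm",
                        schemes = list(`10F` = cv_scheme("kfold", k = 10,
                                                         seed = 3)),
                        seed = 3)
write.csv(grid_scopes, "results/metrics_scopes.csv", row.names = FALSE)
cat("device scopes (SVM, 10F):\n")
print(grid_scopes[, c("scope", "target", "r2", "bmae")],
      row.names = FALSE, digits = 3)

preds <- attr(grid_models, "predictions")
key <- paste("all_data", "tremor",
             best$model[best$target == "tremor"], "10F", sep = ".")
write.csv(preds[[key]], "results/predictions_best.csv", row.names = FALSE)

svm_r2 <- grid_models$r2[grid_models$model == "svm"]
rf_r2 <- grid_models$r2[grid_models$model == "rf"]
ht <- compare_scores(svm_r2, rf_r2)
cat(sprintf("SVM vs RF paired signed-rank p = %.3g\n", ht$p.value))
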