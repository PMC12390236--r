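#!/usr/bin/env Rscript
# Step 5 — figures.
#
# Violin plots of predicted vs true severity per class (with class-specific
# MAE) for each symptom's best all-data model, and the predicted-vs-true
# scatter for the treatment-response state, axes spanning -4..4.
#
# Writes: results/violin_<symptom>.png, results/scatter_trs.png

library(pdsense)

coh <- read_cohort("results/cohort")
ft <- assemble_feature_table(coh)

for (tg in c("tremor", "bradykinesia", "stiffness", "dyskinesia")) {
  pr <- cross_validate(ft$features, ft$labels[[tg]], ft$patient_id,
                       model_spec("svm"), cv_scheme("kfold", k = 10, seed = 3))
  pr <- clip_predictions(pr, c(0, 4))
  out <- severity_violin_report(pr, sprintf("results/violin_%s.png", tg),
                                target = tg)
  cat(tg, "per-class MAE:",
      paste(sprintf("%d:%.2f", out$per_class$class, out$per_class$mae),
            collapse = "  "), "\n")
}

pr <- cross_validate(ft$features, ft$labels$trs_patient, ft$patient_id,
                     model_spec("svm"), cv_scheme("kfold", k = 10, seed = 3))
pr <- clip_predictions(pr, c(-4, 4))
out <- trs_scatter_report(pr, "results/scatter_trs.png",
                          target = "patient-reported state")
cat("state scatter:", out$n, "examinations ->", out$path, "\n")
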