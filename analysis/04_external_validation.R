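#!/usr/bin/env Rscript
# External validation: apply the frozen full-model bundle (thresholds and all
# parameters from training) to the PLCO-like cohort, evaluate 5-year cancer
# prediction, and calibrate the BRCAness score against binned relative risk.
#
# Usage: Rscript analysis/04_external_validation.R   (after 02_train_cv.R)

library(brcaness)

model <- load_model("results/full_model/model")
ext <- read_cohort("results/cohorts/external/manifest.yml")
res <- run_external(model, ext)

cat(sprintf("external AUC (5-year cancer outcome): %.3f (95%% CI %.3f-%.3f)\n",
            res$roc$auc, res$roc$ci[1], res$roc$ci[2]))
m <- res$metrics
cat(sprintf("at the training threshold: accuracy %.0f%%, specificity %.0f%%, sensitivity %.0f%%\n",
            100 * m$accuracy, 100 * m$specificity, 100 * m$sensitivity))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
if (!is.null(res$risk_curve)) {
  write.csv(res$risk_curve$bins, "results/tables/external_risk_curve.csv",
            row.names = FALSE)
  f <- res$risk_fit
  jsonlite::write_json(list(slope = f$slope, intercept = f$intercept,
                            pearson_r = f$r, r_ci = f$r_ci, p = f$p,
                            n_bins = f$n_bins),
                       "results/tables/external_risk_fit.json",
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("log relative risk vs BRCAness score: slope %.2f, R = %.2f (95%% CI %.2f-%.2f), p = %.2g\n",
              f$slope, f$r, f$r_ci[1], f$r_ci[2], f$p))
  cat(sprintf("implied relative risk at score 0.6: %.1f-fold; at 0.9: %.1f-fold\n",
              risk_at_score(f, 0.6), risk_at_score(f, 0.9)))
}
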