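#!/usr/bin/env Rscript
# Deployment composite risk score: refit the class-weighted L1 logistic
# model on the full cohort restricted to the two stable predictors, report
# the raw-scale coefficients (per mmol/L and per mmol/mol), and tabulate
# the operating points at the five predetermined sensitivities.

suppressMessages(library(ppgdm))

cohort <- label_cohort(read_cohort("results/cohort.csv"), "NICE")
final <- fit_final_model(cohort, model_spec("sparse_logistic"),
                         cv_config(seed = 2),
                         features = c("a_fg", "a_hba1c"))
write_risk_model(final, "results/model.json")

cat("deployment model (raw scale):\n")
cat(sprintf("  intercept  %8.4f\n", final$intercept))
for (nm in names(final$coefficients)) {
  cat(sprintf("  %-9s %8.4f\n", nm, final$coefficients[[nm]]))
}
cat(sprintf("risk at cohort-mean inputs (a_fg 4.95, a_hba1c 35.52): %.3f\n",
            composite_risk(final, c(a_fg = 4.95, a_hba1c = 35.52))))

preds <- aggregated_predictions(
  utils::read.csv("results/predictions.csv", colClasses = c(id = "character")))
ops <- operating_points(preds, c(60, 70, 75, 80, 90))
utils::write.csv(ops, "results/operating_points.csv", row.names = FALSE)
cat("\noperating points at predetermined sensitivities:\n")
print(ops[, c("target_sensitivity", "c", "g1", "g2", "ppv", "npv", "f1",
              "accuracy")], row.names = FALSE, digits = 3)
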