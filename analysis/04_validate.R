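#!/usr/bin/env Rscript
# Step 2 of the study, part two: diagnostic-accuracy validation. One-vs-rest
# confusion counts per disease (plus a malignancy row), sensitivity and
# specificity with exact 95% Clopper-Pearson intervals, PPV, NPV, accuracy
# and balanced accuracy.

suppressMessages(library(fibrostep))

cohort <- read_cohort("results/cohort_step2.csv")
preds <- read.csv("results/predictions_step2.csv",
                  colClasses = "character")

report <- validation_report(cohort$true_label, preds$predicted_label,
                            labels = disease_labels(),
                            true_malignancy = cohort$true_malignancy,
                            predicted_malignancy =
                              preds$predicted_malignancy)
txt <- format_validation_report(report)
write.csv(txt, "results/validation_report.csv",
          row.names = FALSE, quote = FALSE)
print(txt, row.names = FALSE)
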