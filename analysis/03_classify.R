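#!/usr/bin/env Rscript
# Step 2 of the study, part one: apply the stepwise rule engine to the
# 100-patient validation cohort and tabulate agreement with the
# pathologically proven diagnoses.

suppressMessages(library(fibrostep))

cohort <- read_cohort("results/cohort_step2.csv")
preds <- classify_cohort(cohort)
write.csv(preds, "results/predictions_step2.csv",
          row.names = FALSE, quote = FALSE)

correct <- preds$predicted_label == cohort$true_label
cat(sprintf("correct diagnoses: %d/%d\n", sum(correct), nrow(cohort)))
if (any(!correct)) {
  cat("misclassifications:\n")
  print(table(truth = cohort$true_label[!correct],
              predicted = preds$predicted_label[!correct]))
}
cat(sprintf("malignancy calls: %d (expected: %d)\n",
            sum(preds$predicted_malignancy != "NONE"),
            sum(cohort$true_malignancy != "NONE")))
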