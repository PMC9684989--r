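#!/usr/bin/env Rscript
# Step 1 of the study: per-disease feature prevalence and one-vs-rest
# chi-square significance on the 150-patient cohort. Writes the full
# prevalence/significance table and prints the discriminators that drive
# the diagnostic rules.

suppressMessages(library(fibrostep))

cohort <- read_cohort("results/cohort_step1.csv")
sig <- significance_table(cohort, correction = "none")
out <- sig
out$p_value <- format_p_value(sig$p_value)
write.csv(out, "results/significance_step1.csv",
          row.names = FALSE, quote = FALSE)

cat(sprintf("tested %d (disease, feature) cells; %d significant at 0.05\n",
            sum(!is.na(sig$p_value)), sum(sig$significant, na.rm = TRUE)))

key <- rbind(
  sig[sig$disease == "UIP_IPF" & sig$feature == "honeycombing", ],
  sig[sig$disease == "CHRONIC_HP" & sig$feature == "head_cheese_sign", ],
  sig[sig$disease == "PPFE" & sig$feature == "platy_thorax", ],
  sig[sig$disease == "SARCOIDOSIS" &
        sig$feature == "perilymphatic_nodules", ],
  sig[sig$disease == "POST_TB" & sig$feature == "calcific_random_nodules", ],
  sig[sig$disease == "POST_TB" & sig$feature == "smoking_history", ],
  sig[sig$disease == "PMF" & sig$feature == "occupational_dust_exposure", ],
  sig[sig$disease == "POST_IRRADIATION" &
        sig$feature == "malignancy_irradiation_history", ])
key$p_value <- format_p_value(key$p_value)
cat("\nrule-driving discriminators:\n")
print(key[, c("disease", "feature", "count", "n_disease", "percent",
              "p_value")], row.names = FALSE)
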