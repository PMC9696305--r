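#!/usr/bin/env Rscript

# Step 5: agreement between the two measurement channels.
#
# Pearson correlation over all individuals between the primary volume and
# the noisier second channel, with the t-based p-value — the cross-pipeline
# comparison that motivates trusting automated volumetry for these
# structures.

library(twinace)

cohort <- read_cohort("results/cohort.csv")

ag <- method_agreement(cohort, "putamen_volume", "putamen_volume_m2")
print(ag)

out <- data.frame(phenotype = "putamen_volume", r = ag$r,
                  ci_low = ag$ci_low, ci_high = ag$ci_high,
                  n_individuals = ag$n, p_value = ag$p_value)
write.csv(out, "results/method_agreement.csv", row.names = FALSE)
cat("Method agreement written to results/method_agreement.csv\n")
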