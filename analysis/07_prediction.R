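#!/usr/bin/env Rscript
# Stage 7: individual predictive performance.
#
# For every patient and cycle (from cycle 2), the random effects are
# estimated by empirical Bayes (MAP) from the preceding cycles, the next
# cycle's grade distribution is propagated from the last observed grade at
# the known dose, and the modal grade is compared with the observation.
# Grades >= 2 are the clinically relevant group (dose modifications start at
# grade 2): PPV is computed within predicted >= 2, NPV within predicted <= 1.

library(mctmm)

cohort <- read_dataset("results/cohort.csv")
params <- read_params("results/final_params.cfg")

tab <- prediction_table(cohort, params)
write.csv(as.data.frame(tab), "results/predictions.csv", row.names = FALSE)

pv <- ppv_npv(tab, by_cycle = TRUE)
pv$ppv <- round(100 * pv$ppv, 1)
pv$npv <- round(100 * pv$npv, 1)
names(pv)[3:4] <- c("ppv_pct", "npv_pct")
print(pv, row.names = FALSE)
write.csv(pv, "results/ppv_npv.csv", row.names = FALSE)
message("wrote results/predictions.csv and results/ppv_npv.csv")
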