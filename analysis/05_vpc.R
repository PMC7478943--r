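#!/usr/bin/env Rscript
# Stage 5: categorical visual predictive check of the final model.
#
# 1000 replicate datasets are simulated on the observed design; per cycle and
# grade the 2.5-97.5 percentile band of the simulated proportions is compared
# with the observed proportion. A well-calibrated model keeps nearly all
# observed proportions inside the bands.

library(mctmm)

cohort <- read_dataset("results/cohort.csv")
params <- read_params("results/final_params.cfg")

vpc <- categorical_vpc(cohort, params, n_sim = 1000, seed = 5)
write.csv(as.data.frame(vpc), "results/vpc.csv", row.names = FALSE)

coverage <- mean(vpc$observed_prop >= vpc$lo95 & vpc$observed_prop <= vpc$hi95)
message(sprintf("%.0f%% of cycle x grade bins inside the 95%% band",
                100 * coverage))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/vpc.pdf", plot_vpc(vpc), width = 7, height = 5)
  message("wrote results/vpc.csv and results/vpc.pdf")
} else {
  message("wrote results/vpc.csv")
}
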