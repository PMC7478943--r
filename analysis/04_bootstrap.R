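#!/usr/bin/env Rscript
# Stage 4: non-parametric bootstrap of the final model.
#
# Subjects are resampled with replacement to the original cohort size and the
# model is refit on each replicate; medians and percentile 95% confidence
# intervals summarize parameter uncertainty. 50 replicates by default
# (pass a number as the first argument for more; 1000 is the full analysis,
# roughly (n_replicates x 1 min) of runtime).

library(mctmm)

args <- commandArgs(trailingOnly = TRUE)
n_rep <- if (length(args)) as.integer(args[1]) else 50L

cohort <- read_dataset("results/cohort.csv")
params <- read_params("results/final_params.cfg")
fit <- mctmm_fit(cohort, start = params, quiet = TRUE, se = FALSE)

message("bootstrapping (", n_rep, " replicates) ...")
boot <- mctmm_bootstrap(cohort, fit, n_replicates = n_rep, seed = 4)
print(boot)
write.csv(boot$summary, "results/bootstrap_summary.csv", row.names = FALSE)
write.csv(boot$replicates, "results/bootstrap_replicates.csv",
          row.names = FALSE)
message("wrote results/bootstrap_summary.csv (",
        boot$n_fail, " failed replicates)")
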