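# Shared settings for the analysis drivers. Source()d by every numbered
# script; all randomness flows from MASTER_SEED.

library(bgsem)

OUT <- "results/analysis"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

MASTER_SEED <- 20180L     # study wave year, truncated to a small integer
COHORT_N <- 7777L         # analytic sample size of the study
MISSING_RATE <- 0.05      # MAR rate on the three need-factor mediators

# desk-scale MCMC profile used throughout the workflow
MCMC <- mcmc_config(chains = 2, iter = 1500, warmup = 750,
                    seed = MASTER_SEED)

out_path <- function(...) file.path(OUT, ...)
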