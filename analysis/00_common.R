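# Shared study configuration for the analysis scripts. Every stage rebuilds
# the world from this seed (generation is deterministic and takes seconds),
# so the scripts can be run independently or in order.
library(nh3trade)

study_config <- function() world_config(n_regions = 6, seed = 2012)
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
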