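#!/usr/bin/env Rscript
# Stage 2: embodied-emission accounting. Leontief total requirements link
# each economy's agricultural NH3 to the final consumption it serves;
# production- vs consumption-based accounts and the export-related
# emission shares follow.
source("analysis/00_common.R")

world <- synthetic_world(study_config(), ensemble_size = 2)
acc <- mrio_accounts(world)

acct <- acc$accounts
acct[-1] <- round(acct[-1], 2)
print(acct)
cat(sprintf("\nGlobal export share of agricultural NH3: %.1f %%\n",
            100 * sum(acc$accounts$EEE) / sum(acc$accounts$PBE)))
cat(sprintf("Conservation check |sum EEB| = %.2e Gg\n",
            abs(sum(acc$accounts$EEB))))

a <- acc$accounts
a$units <- "Gg a-1"
write.csv(a, file.path(results_dir, "trade_accounts.csv"), row.names = FALSE)
write.csv(as.data.frame(acc$flows$T),
          file.path(results_dir, "embodied_flows_T.csv"))
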