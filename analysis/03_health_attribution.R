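#!/usr/bin/env Rscript
# Stage 3: PM2.5 mortality attribution. Total attributable deaths come
# from the IER ensemble mean; export-related deaths per economy come from
# perturbing each economy's gridded agricultural NH3 by its embodied
# export fraction and rerunning the dispersion surrogate.
source("analysis/00_common.R")

world <- synthetic_world(study_config(), ensemble_size = 1000)
acc <- mrio_accounts(world)
g <- world$grids

mc <- monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine,
                            g$y0, world$ier)
cat(sprintf("Total PM2.5-attributable deaths: %.0f (95%% CI %.0f-%.0f)\n",
            mc$total, mc$ci[1], mc$ci[2]))

ed <- export_attributed_deaths(world, acc, total_mort = mc)
print(transform(ed, deaths_total = round(deaths_total, 1),
                deaths_crop = round(deaths_crop, 1),
                deaths_livestock = round(deaths_livestock, 1)))
cat(sprintf("\nExport-related deaths: %.0f (%.1f %% of the PM2.5 total)\n",
            sum(ed$deaths_total), 100 * sum(ed$deaths_total) / mc$total))
cat(sprintf("Livestock share of export-related deaths: %.1f %%\n",
            100 * sum(ed$deaths_livestock) / sum(ed$deaths_total)))

ed$units <- "deaths a-1"
write.csv(ed, file.path(results_dir, "export_mortality.csv"), row.names = FALSE)
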