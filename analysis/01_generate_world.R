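#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study world -- a balanced six-region
# economy with crop/livestock/other sectors, sectoral NH3 emissions,
# gridded population / PM2.5 / country mask, climate and capacity
# attributes, and a 1000-member IER parameter ensemble.
source("analysis/00_common.R")

world <- synthetic_world(study_config(), ensemble_size = 1000)
print(world)
print(world$mrio)

write_mrio_csv(world$mrio, file.path(results_dir, "mrio.csv"))
write_emissions_csv(world$emissions, file.path(results_dir, "emissions.csv"))
write_grid_csv(world$grids$pm25_total, file.path(results_dir, "pm25_total.csv"))
write_grid_csv(world$grids$population, file.path(results_dir, "population.csv"))
write_grid_csv(world$grids$mask_fine, file.path(results_dir, "country_mask.csv"))
write.csv(world$climate, file.path(results_dir, "climate_capacity.csv"),
          row.names = FALSE)

tot <- emission_totals(world$emissions)
cat(sprintf("\nAgricultural NH3: %.1f Gg crop + %.1f Gg livestock = %.1f Gg\n",
            sum(tot$crop), sum(tot$livestock), sum(tot$crop + tot$livestock)))
cat(sprintf("PM2.5 over the domain: %.1f-%.1f ug m-3 (background %.1f)\n",
            min(world$grids$pm25_total$values),
            max(world$grids$pm25_total$values),
            study_config()$background_pm25))
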