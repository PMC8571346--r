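#!/usr/bin/env Rscript
# Stage 5: NH3 mitigation scenarios -- the two trade-reallocation linear
# programs within each detected community, the production-side technology
# scenarios, the food-waste and beef-substitution consumption scenarios,
# and the health benefit of one selected scenario.
source("analysis/00_common.R")

world <- synthetic_world(study_config(), ensemble_size = 2)
acc <- mrio_accounts(world)
g <- world$grids
mc0 <- attributable_mortality(g$pm25_total, g$population, g$mask_fine,
                              g$y0, ier_default_params())
ed <- export_attributed_deaths(world, acc, total_mort = mc0,
                               by_sector = FALSE)
net <- bilateral_health_flows(setNames(ed$deaths_total, ed$region),
                              acc$flows$T, acc$accounts)
part <- detect_communities(net)

rows <- list()
for (com in sort(unique(part$membership))) {
  prob <- trade_problem(world, acc, part$membership, com)
  et <- export_transfer(prob)
  is_red <- sum(vapply(prob$members, function(r)
    import_substitution(prob, r)$reduction, numeric(1)))
  rows[[length(rows) + 1]] <- data.frame(community = com,
                                         scenario = "export_transfer",
                                         reduction_gg = et$reduction)
  rows[[length(rows) + 1]] <- data.frame(community = com,
                                         scenario = "import_substitution",
                                         reduction_gg = is_red)
}
tech <- c("fertilizer_overuse", "deep_placement", "enhanced_efficiency",
          "manure_moderate", "manure_drastic")
for (s in tech)
  rows[[length(rows) + 1]] <- data.frame(community = "all", scenario = s,
    reduction_gg = production_side_reduction(world$emissions, s)$reduction)
rows[[length(rows) + 1]] <- data.frame(community = "all",
  scenario = "food_waste",
  reduction_gg = food_waste_reduction(
    world$emissions,
    world$climate[, c("region", "waste_crop", "waste_meat")])$reduction)
for (cut in c(0.2, 0.5))
  rows[[length(rows) + 1]] <- data.frame(community = "all",
    scenario = sprintf("beef_cut%d", 100 * cut),
    reduction_gg = beef_substitution_reduction(
      world$emissions, world$climate[, c("region", "beef_share")],
      cut)$reduction)
tab <- do.call(rbind, rows)
tab$units <- "Gg a-1"
print(tab)
write.csv(tab, file.path(results_dir, "scenario_reductions.csv"),
          row.names = FALSE)

hb <- scenario_health_benefit(
  world, production_side_reduction(world$emissions, "fertilizer_overuse"))
cat(sprintf("\nRemoving fertilizer overuse avoids %.0f deaths a-1 (of %.0f)\n",
            hb$avoided_deaths, hb$baseline_deaths))
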