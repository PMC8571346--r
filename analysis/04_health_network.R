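#!/usr/bin/env Rscript
# Stage 4: the bilateral health-effect network. Export-related deaths are
# decomposed over consuming partners in proportion to embodied flows;
# centralities, communities and the intra-community flow share follow.
source("analysis/00_common.R")

world <- synthetic_world(study_config(), ensemble_size = 1000)
acc <- mrio_accounts(world)
g <- world$grids
mc <- monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine,
                            g$y0, world$ier)
ed <- export_attributed_deaths(world, acc, total_mort = mc)

net <- bilateral_health_flows(setNames(ed$deaths_total, ed$region),
                              acc$flows$T, acc$accounts)
print(net)
stopifnot(abs(sum(net$q) - sum(ed$deaths_total)) <=
            1e-6 * sum(ed$deaths_total))   # conservation audit

ds <- degrees_strengths(net)
ds$betweenness <- betweenness_centrality(net, weighted = TRUE)
ds$eigenvector <- eigenvector_centrality(net)$vector
ds$omega <- weighted_nn_degree(net)$omega_i
part <- detect_communities(net)
ds$community <- part$membership
print(ds)
cat(sprintf("\nCommunities: %d (Q = %.3f), intra-community flow share %.1f %%\n",
            part$n_communities, part$modularity,
            100 * community_flow_shares(net, part)$intra_share))
cat("(At six regions the dense toy network typically stays one community;\n",
    "the planted-structure tests show the detector resolves real blocks.)\n")

write.csv(ds, file.path(results_dir, "centrality.csv"), row.names = FALSE)
write_health_network(net, file.path(results_dir, "health_network.graphml"),
                     file.path(results_dir, "health_network_edges.csv"))
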