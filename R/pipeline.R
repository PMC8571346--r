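#' Pipeline configuration
#'
#' Bundles the world configuration with run options for the end-to-end
#' chain (generate, account, attribute, network, scenarios). A single
#' master seed fans out to per-stage substreams so stages are
#' individually reproducible.
#'
#' @param world a [world_config()].
#' @param out_dir output directory (created if missing).
#' @param stages subset of `c("generate", "account", "attribute",
#'   "network", "scenarios")`, executed in dependency order.
#' @param ensemble_size IER Monte-Carlo members.
#' @param network_threshold edge-existence threshold (deaths a-1).
#' @param grain_share grain fraction of crop NH3 for the fertilizer
#'   scenarios.
#' @param beef_cuts beef-consumption cut fractions to evaluate.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(world = world_config(),
                            out_dir = "nh3trade_run",
                            stages = c("generate", "account", "attribute",
                                       "network", "scenarios"),
                            ensemble_size = 1000,
                            network_threshold = 0,
                            grain_share = 1,
                            beef_cuts = c(0.2, 0.5)) {
  known <- c("generate", "account", "attribute", "network", "scenarios")
  if (!all(stages %in% known)) stop("unknown stage(s): ",
                                    paste(setdiff(stages, known), collapse = ", "))
  structure(list(world = world, out_dir = out_dir,
                 stages = intersect(known, stages),  # dependency order
                 ensemble_size = ensemble_size,
                 network_threshold = network_threshold,
                 grain_share = grain_share, beef_cuts = beef_cuts),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$out_dir <- NULL   # location is not part of the run identity
  yaml::write_yaml(lapply(x, function(el)
    if (inherits(el, "world_config")) unclass(el) else el), path)
  invisible(path)
}

run_stage <- function(name, enabled, fn) {
  if (!enabled) return(NULL)
  tryCatch(fn(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis chain
#'
#' Executes the enabled stages in dependency order, writes every
#' intermediate artifact (CSV/JSON/GraphML) under `config$out_dir`, audits
#' end-to-end conservation (total bilateral network flow equals the
#' export-mortality total), and writes a manifest with the seed and MD5
#' checksums of all outputs. The same config and seed reproduce the
#' outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  on <- function(s) s %in% config$stages
  world <- run_stage("generate", on("generate"), function() {
    world <- synthetic_world(config$world, ensemble_size = config$ensemble_size)
    write_mrio_csv(world$mrio, out("mrio.csv"))
    write_emissions_csv(world$emissions, out("emissions.csv"))
    write_grid_csv(world$grids$population, out("population.csv"))
    write_grid_csv(world$grids$pm25_total, out("pm25_total.csv"))
    write_grid_csv(world$grids$mask_fine, out("country_mask.csv"))
    utils::write.csv(cbind(region = rownames(world$grids$y0),
                           as.data.frame(world$grids$y0),
                           units = "deaths person-1 a-1"),
                     out("baseline_mortality.csv"), row.names = FALSE)
    utils::write.csv(world$climate, out("climate_capacity.csv"), row.names = FALSE)
    write_pipeline_config(config, out("config.yaml"))
    world
  })

  acc <- run_stage("account", on("account"), function() {
    acc <- mrio_accounts(world)
    a <- acc$accounts
    a$units <- "Gg a-1"
    utils::write.csv(a, out("trade_accounts.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(acc$flows$T), out("embodied_flows_T.csv"))
    acc
  })

  exp_deaths <- run_stage("attribute", on("attribute"), function() {
    g <- world$grids
    mc <- monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine,
                                g$y0, world$ier)
    exp_deaths <- export_attributed_deaths(world, acc, total_mort = mc)
    ed <- exp_deaths
    ed$units <- "deaths a-1"
    utils::write.csv(ed, out("export_mortality.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      total_pm25_deaths_mean = mc$total,
      total_pm25_deaths_ci = as.list(mc$ci),
      export_related_deaths = sum(exp_deaths$deaths_total),
      units = "deaths a-1"),
      out("mortality_summary.json"), auto_unbox = TRUE, digits = NA)
    exp_deaths
  })

  part <- run_stage("network", on("network"), function() {
    deaths <- stats::setNames(exp_deaths$deaths_total, exp_deaths$region)
    net <- bilateral_health_flows(deaths, acc$flows$T, acc$accounts)
    audit <- abs(sum(net$q) - sum(deaths)) / max(sum(deaths), 1e-12)
    if (audit > 1e-6)
      stop(sprintf("conservation audit failed: relative gap %.3g", audit))
    part <- detect_communities(net)
    ds <- degrees_strengths(net, config$network_threshold)
    ds$betweenness <- betweenness_centrality(net, weighted = TRUE,
                                             threshold = config$network_threshold)
    ev <- eigenvector_centrality(net, threshold = config$network_threshold)
    ds$eigenvector <- ev$vector
    wnn <- weighted_nn_degree(net, config$network_threshold)
    ds$omega <- wnn$omega_i
    ds$community <- part$membership
    utils::write.csv(ds, out("centrality.csv"), row.names = FALSE)
    write_health_network(net, out("health_network.graphml"),
                         out("health_network_edges.csv"))
    flows <- community_flow_shares(net, part)
    jsonlite::write_json(list(
      n_communities = part$n_communities,
      modularity = part$modularity,
      intra_share = flows$intra_share,
      eigenvalue = ev$value,
      conservation_gap = audit),
      out("network_summary.json"), auto_unbox = TRUE, digits = NA)
    part
  })

  run_stage("scenarios", on("scenarios"), function() {
    rows <- list()
    membership <- part$membership
    for (com in sort(unique(membership))) {
      prob <- trade_problem(world, acc, membership, com)
      et <- export_transfer(prob)
      is_red <- sum(vapply(prob$members, function(r)
        import_substitution(prob, r)$reduction, numeric(1)))
      rows[[length(rows) + 1]] <- data.frame(
        community = com, scenario = "export_transfer", reduction_gg = et$reduction)
      rows[[length(rows) + 1]] <- data.frame(
        community = com, scenario = "import_substitution", reduction_gg = is_red)
    }
    wr <- world$climate[, c("region", "waste_crop", "waste_meat")]
    names(wr) <- c("region", "waste_crop", "waste_meat")
    prod_scen <- names(production_rates())
    per_region <- list(
      food_waste = food_waste_reduction(world$emissions, wr))
    for (s in prod_scen)
      per_region[[s]] <- production_side_reduction(world$emissions, s,
                                                   grain_share = config$grain_share)
    for (cut in config$beef_cuts)
      per_region[[sprintf("beef_cut%d", round(100 * cut))]] <-
        beef_substitution_reduction(
          world$emissions,
          world$climate[, c("region", "beef_share")], cut)
    for (nm in names(per_region)) {
      byc <- tapply(per_region[[nm]]$by_region[names(membership)],
                    membership, sum)
      for (com in names(byc))
        rows[[length(rows) + 1]] <- data.frame(
          community = com, scenario = nm, reduction_gg = unname(byc[com]))
    }
    tab <- do.call(rbind, rows)
    tab$units <- "Gg a-1"
    utils::write.csv(tab, out("scenario_reductions.csv"), row.names = FALSE)
    hb <- scenario_health_benefit(world, per_region$fertilizer_overuse)
    jsonlite::write_json(list(
      scenario = "fertilizer_overuse",
      avoided_deaths = hb$avoided_deaths,
      baseline_deaths = hb$baseline_deaths,
      units = "deaths a-1"),
      out("scenario_health_benefit.json"), auto_unbox = TRUE, digits = NA)
  })

  files <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = config$world$seed,
    stages = config$stages,
    package_version = as.character(utils::packageVersion("nh3trade")),
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate a written world directory
#'
#' Machine-readable checks on the artifacts of a pipeline run: MRIO
#' balance and invertibility, non-negative emissions restricted to
#' agricultural sectors, shared grid definitions, full mask coverage, and
#' baseline-mortality ranges.
#'
#' @param dir directory written by [run_pipeline()].
#' @return data frame with columns check, pass, detail.
#' @export
validate_inputs <- function(dir) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(check = name, pass = pass,
                                                detail = detail)
  }
  mrio <- tryCatch(read_mrio_csv(file.path(dir, "mrio.csv")), error = identity)
  if (inherits(mrio, "error")) {
    add("mrio_balance", FALSE, conditionMessage(mrio))
  } else {
    bal <- mrio$X - rowSums(mrio$Z) - rowSums(mrio$F)
    rel <- abs(bal) / pmax(mrio$X, 1e-300)
    if (max(rel) <= 1e-9) add("mrio_balance", TRUE)
    else add("mrio_balance", FALSE,
             paste("row", names(mrio$X)[which.max(rel)],
                   sprintf("rel error %.3g", max(rel))))
    rho <- max(Mod(eigen(technical_coefficients(mrio), only.values = TRUE)$values))
    add("leontief_invertible", rho < 1, sprintf("spectral radius %.4f", rho))
  }
  em <- tryCatch(read_emissions_csv(file.path(dir, "emissions.csv")),
                 error = identity)
  if (inherits(em, "error")) add("emissions", FALSE, conditionMessage(em))
  else add("emissions", all(em$emissions >= 0) &&
             all(em$emissions[em$category == "other"] == 0),
           "non-negative, agricultural only")
  grids <- lapply(c(pm25 = "pm25_total.csv", pop = "population.csv",
                    mask = "country_mask.csv"),
                  function(f) tryCatch(read_grid_csv(file.path(dir, f)),
                                       error = identity))
  if (any(vapply(grids, inherits, TRUE, "error"))) {
    add("grid_consistency", FALSE, "unreadable grid file")
  } else {
    add("grid_consistency",
        same_grid(grids$pm25, grids$pop) && same_grid(grids$pm25, grids$mask),
        "all fields share one grid")
    if (!inherits(mrio, "error")) {
      covered <- sort(unique(as.integer(grids$mask$values)))
      add("mask_coverage",
          length(covered) == length(mrio$regions) &&
            all(covered == seq_along(mrio$regions)),
          sprintf("%d region codes on the grid", length(covered)))
    }
  }
  y0 <- tryCatch(utils::read.csv(file.path(dir, "baseline_mortality.csv")),
                 error = identity)
  if (inherits(y0, "error")) add("baseline_mortality", FALSE, conditionMessage(y0))
  else {
    rates <- as.matrix(y0[, !(names(y0) %in% c("region", "units")), drop = FALSE])
    add("baseline_mortality", all(rates >= 0) && all(rates < 0.1),
        "rates in [0, 0.1) per person per year")
  }
  do.call(rbind, checks)
}
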