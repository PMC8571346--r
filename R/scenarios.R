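#' Climate compatibility indicator for trade substitution
#'
#' Agricultural production can only move between economies with similar
#' growing conditions: I_ij = 1 iff |AVT_i - AVT_j| <= 5 degC and
#' |PCP_i - PCP_j| <= 500 mm (closed intervals at the boundary). The
#' matrix is symmetric with a unit diagonal.
#'
#' @param climate data frame with columns region, avt (degC), pcp
#'   (mm a-1).
#' @param dt,dp window half-widths (defaults 5 degC, 500 mm).
#' @return n x n 0/1 matrix with region dimnames.
#' @export
climate_compatibility <- function(climate, dt = 5, dp = 500) {
  if (any(is.na(climate$avt)) || any(is.na(climate$pcp)))
    stop("missing climate entries")
  ok <- (abs(outer(climate$avt, climate$avt, `-`)) <= dt) &
    (abs(outer(climate$pcp, climate$pcp, `-`)) <= dp)
  I <- ok * 1
  dimnames(I) <- list(climate$region, climate$region)
  I
}

#' Build the trade-reallocation problem data for one community
#'
#' Collects bilateral agricultural imports (embodied in final
#' consumption), agricultural NH3 emission intensities, original exports,
#' capacities and the climate-compatibility matrix for the member
#' economies of a community.
#'
#' @param world a `synthetic_world`.
#' @param accounts output of [mrio_accounts()].
#' @param membership community labels per region (a `partition` or named
#'   vector).
#' @param community the community label to extract.
#' @return a `trade_problem` list: members, `IM` (imports, importer x
#'   exporter, monetary), `EI` (Gg per monetary unit), `EX0` (monetary
#'   exports), `AC` (capacity, monetary), `I` (compatibility).
#' @export
trade_problem <- function(world, accounts, membership, community) {
  if (inherits(membership, "partition")) membership <- membership$membership
  members <- names(membership)[membership == community]
  if (length(members) == 0) stop("community has no members")
  mrio <- world$mrio
  idx <- mrio$index
  ag <- idx$category != "other"
  # agricultural trade flows (monetary): producing region x consuming
  # region, intermediate plus final use of agricultural output
  n <- length(mrio$regions)
  rblock <- match(idx$region, mrio$regions)
  flow <- matrix(0, n, n, dimnames = list(mrio$regions, mrio$regions))
  for (s in seq_len(n)) for (t in seq_len(n)) {
    zi <- sum(mrio$Z[ag & rblock == s, rblock == t])
    fi <- sum(mrio$F[ag & rblock == s, t])
    flow[s, t] <- zi + fi
  }
  ag_out <- vapply(mrio$regions, function(r) sum(mrio$X[ag & idx$region == r]),
                   numeric(1))
  ag_em <- vapply(mrio$regions, function(r)
    sum(world$emissions$emissions[world$emissions$region == r]), numeric(1))
  EI <- ifelse(ag_out > 0, ag_em / ag_out, 0)
  off <- flow
  diag(off) <- 0
  clim <- world$climate[match(members, world$climate$region), ]
  structure(list(
    members = members,
    IM = t(off[members, members, drop = FALSE]),  # importer x exporter
    EI = EI[members],
    EX0 = rowSums(off)[members],
    AC = stats::setNames(clim$ac, members),
    I = climate_compatibility(clim)), class = "trade_problem")
}

#' Import-substitution linear program for one importer
#'
#' Replaces imports IM_ij from dirtier partners with domestic production:
#' maximize sum_j (EI_j - EI_i) ST_ij subject to the importer's capacity
#' sum_j ST_ij <= AC_i, flow bounds 0 <= ST_ij <= IM_ij, and climate
#' compatibility I_ij = 1. Substituting nothing is always feasible, so
#' the attained reduction is non-negative.
#'
#' @param problem a `trade_problem`.
#' @param region importer label (member of the community).
#' @return a `scenario_outcome`: `reduction` (Gg), `ST` (named substituted
#'   amounts), `scenario` name.
#' @export
import_substitution <- function(problem, region) {
  i <- match(region, problem$members)
  if (is.na(i)) stop("region is not in the community")
  partners <- setdiff(seq_along(problem$members), i)
  elig <- partners[problem$I[i, partners] == 1 &
                     problem$IM[i, partners] > 0]
  ST <- stats::setNames(numeric(length(problem$members)), problem$members)
  if (length(elig) > 0) {
    gain <- problem$EI[elig] - problem$EI[i]
    ub <- problem$IM[i, elig]
    sol <- boot::simplex(a = gain,
                         A1 = rbind(rep(1, length(elig)), diag(length(elig))),
                         b1 = c(problem$AC[i], ub),
                         maxi = TRUE)
    if (sol$solved < 0) stop("import-substitution LP failed to solve")
    ST[elig] <- sol$soln
  }
  reduction <- sum((problem$EI - problem$EI[i]) * ST)
  structure(list(scenario = "import_substitution", region = region,
                 reduction = max(reduction, 0), ST = ST),
            class = "scenario_outcome")
}

#' Export-transfer linear program for a community
#'
#' Reorganizes the community's export production to minimize embodied
#' NH3: minimize sum_i EX_i^AF EI_i subject to (1) total exports
#' conserved, sum EX^AF = sum EX0; (2) capacity, EX_i^AF <= AC_i + EX0_i;
#' (3) climate-compatible coverage, EX0_i <= sum_j I_ij EX_j^AF. The
#' original export vector is always feasible, so the reduction is
#' non-negative.
#'
#' @param problem a `trade_problem`.
#' @return a `scenario_outcome` with `reduction` (Gg), `EX_AF`, and the
#'   active-constraint set.
#' @export
export_transfer <- function(problem) {
  m <- length(problem$members)
  EX0 <- problem$EX0
  sol <- boot::simplex(
    a = problem$EI,
    A1 = diag(m), b1 = problem$AC + EX0,          # capacity
    A2 = problem$I, b2 = EX0,                     # compatible coverage
    A3 = matrix(1, 1, m), b3 = sum(EX0),          # conservation
    maxi = FALSE)
  if (sol$solved < 0) stop("export-transfer LP infeasible or unsolved; ",
                           "check capacity and compatibility inputs")
  EX_AF <- stats::setNames(sol$soln, problem$members)
  baseline <- sum(EX0 * problem$EI)
  active <- list(
    capacity = problem$members[abs(EX_AF - (problem$AC + EX0)) < 1e-9],
    coverage = problem$members[abs(as.numeric(problem$I %*% EX_AF) - EX0) < 1e-9])
  structure(list(scenario = "export_transfer",
                 reduction = max(baseline - sol$value, 0),
                 EX_AF = EX_AF, baseline_emissions = baseline,
                 active_constraints = active),
            class = "scenario_outcome")
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat(sprintf("<scenario_outcome> %s: %.3f Gg NH3 reduced\n",
              x$scenario, x$reduction))
  invisible(x)
}

production_rates <- function(grain_share = 1) {
  list(
    fertilizer_overuse = list(rate = 0.14, base = "crop", share = 1),
    deep_placement = list(rate = 0.55, base = "crop", share = grain_share),
    enhanced_efficiency = list(rate = 0.54, base = "crop", share = grain_share),
    manure_moderate = list(rate = 0.35, base = "livestock", share = 1),
    manure_drastic = list(rate = 0.70, base = "livestock", share = 1))
}

#' Production-side technology reduction scenarios
#'
#' Fixed literature-based reduction rates applied to the relevant
#' emission base per region: removing nitrogen-fertilizer overuse cuts
#' crop NH3 by 14 %; deep fertilizer placement cuts grain-crop NH3 by
#' 55 % and enhanced-efficiency fertilizers by 54 % (both scaled by a
#' configurable grain share of crop NH3); moderate and drastic manure
#' management cut livestock NH3 by 35 % and 70 %.
#'
#' @param emissions a `sector_emissions` table.
#' @param scenario one of `fertilizer_overuse`, `deep_placement`,
#'   `enhanced_efficiency`, `manure_moderate`, `manure_drastic`.
#' @param grain_share grain fraction of crop NH3 (default 1).
#' @return a `scenario_outcome` with per-region and total reductions (Gg).
#' @export
production_side_reduction <- function(emissions, scenario, grain_share = 1) {
  rates <- production_rates(grain_share)
  if (!scenario %in% names(rates))
    stop("unknown scenario '", scenario, "'; choose one of ",
         paste(names(rates), collapse = ", "))
  r <- rates[[scenario]]
  totals <- emission_totals(emissions)
  red <- totals[[r$base]] * r$rate * r$share
  structure(list(scenario = scenario,
                 by_region = stats::setNames(red, totals$region),
                 base_category = r$base,
                 reduction = sum(red)), class = "scenario_outcome")
}

#' Eliminating food waste and loss
#'
#' Reduction = crop baseline x crop waste/loss ratio + livestock baseline
#' x meat waste/loss ratio, per region.
#'
#' @param emissions a `sector_emissions` table.
#' @param waste_ratios data frame with columns region, waste_crop,
#'   waste_meat (fractions in \[0, 1\]).
#' @return a `scenario_outcome`.
#' @export
food_waste_reduction <- function(emissions, waste_ratios) {
  if (any(waste_ratios$waste_crop < 0 | waste_ratios$waste_crop > 1) ||
      any(waste_ratios$waste_meat < 0 | waste_ratios$waste_meat > 1))
    stop("waste ratios must lie in [0, 1]")
  totals <- emission_totals(emissions)
  wr <- waste_ratios[match(totals$region, waste_ratios$region), ]
  red <- totals$crop * wr$waste_crop + totals$livestock * wr$waste_meat
  structure(list(scenario = "food_waste",
                 by_region = stats::setNames(red, totals$region),
                 base_category = "both",
                 reduction = sum(red)), class = "scenario_outcome")
}

#' Beef-to-soy dietary substitution
#'
#' Reduction = livestock NH3 x beef share x consumption cut; the
#' additional soybean NH3 is negligible and treated as zero, so the
#' reduction is exactly linear in the cut fraction.
#'
#' @param emissions a `sector_emissions` table.
#' @param beef_share per-region fraction of livestock NH3 from beef
#'   (data frame region, beef_share, or a single number).
#' @param cut_fraction consumption cut in \[0, 1\] (e.g. 0.2 or 0.5).
#' @return a `scenario_outcome`.
#' @export
beef_substitution_reduction <- function(emissions, beef_share, cut_fraction) {
  if (cut_fraction < 0 || cut_fraction > 1)
    stop("cut_fraction must lie in [0, 1]")
  totals <- emission_totals(emissions)
  share <- if (is.data.frame(beef_share))
    beef_share$beef_share[match(totals$region, beef_share$region)]
  else rep(beef_share, nrow(totals))
  if (any(share < 0 | share > 1)) stop("beef_share must lie in [0, 1]")
  red <- totals$livestock * share * cut_fraction
  structure(list(scenario = sprintf("beef_substitution_%d", round(100 * cut_fraction)),
                 by_region = stats::setNames(red, totals$region),
                 base_category = "livestock",
                 reduction = sum(red)), class = "scenario_outcome")
}

#' Health benefit of an emission-reduction scenario
#'
#' Applies each region's reduction as a uniform within-region scaling of
#' its gridded agricultural NH3, reruns the dispersion surrogate and the
#' IER mortality chain with population and baseline mortality held fixed,
#' and reports deaths avoided relative to the unperturbed world.
#'
#' @param world a `synthetic_world`.
#' @param outcome a `scenario_outcome` carrying `by_region` reductions
#'   (Gg) and `base_category`, or a named per-region vector of all-
#'   agriculture reductions.
#' @param params IER parameter table (default central values).
#' @return list `avoided_deaths`, `baseline_deaths`, `scenario_deaths`.
#' @export
scenario_health_benefit <- function(world, outcome,
                                    params = ier_default_params()) {
  g <- world$grids
  cfg <- world$config
  totals <- emission_totals(world$emissions)
  if (inherits(outcome, "scenario_outcome")) {
    red <- outcome$by_region
    base_cat <- outcome$base_category
  } else {
    red <- outcome
    base_cat <- "both"
  }
  scaled <- totals
  for (r in names(red)) {
    i <- scaled$region == r
    if (!any(i)) next
    cats <- if (identical(base_cat, "both")) c("crop", "livestock") else base_cat
    base <- sum(unlist(scaled[i, cats]))
    if (base <= 0) next
    s <- 1 - red[[r]] / base
    if (s < -1e-9 || s > 1 + 1e-9)
      stop("reduction outside [0, baseline] for region ", r)
    scaled[i, cats] <- scaled[i, cats] * min(max(s, 0), 1)
  }
  mort_of <- function(tt) {
    ef <- emission_field(cfg, g$mask_coarse, tt)
    conc <- surrogate_dispersion(ef, cfg$kernel_scale, strength = cfg$pm25_per_gg)
    nest <- nesting_index(g$mask_coarse, g$pm25_total)
    pm_fine <- grid_field(cfg$background_pm25 + conc$values[nest$ilat, nest$ilon],
                          g$pm25_total$lat, g$pm25_total$lon,
                          units = "ug m-3", name = "pm25_total")
    attributable_mortality(pm_fine, g$population, g$mask_fine, g$y0, params)$total
  }
  baseline <- mort_of(totals)
  scenario <- mort_of(scaled)
  list(avoided_deaths = baseline - scenario,
       baseline_deaths = baseline, scenario_deaths = scenario)
}
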