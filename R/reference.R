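#' Published 2012 reference values
#'
#' Small tables of published global 2012 values shipped with the package:
#' the NH3 emission inventory totals (`"inventory"`), the trade-related
#' premature-mortality components by sector and region (`"mortality"`),
#' and the community-level mitigation-scenario reductions
#' (`"scenarios"`). They anchor the worked-arithmetic checks and give the
#' synthetic world a real-world yardstick; they are inputs, never
#' recomputed.
#'
#' @param which one of `"inventory"`, `"mortality"`, `"scenarios"`.
#' @return a data frame.
#' @export
nh3_reference <- function(which = c("inventory", "mortality", "scenarios")) {
  which <- match.arg(which)
  file <- switch(which,
                 inventory = "global_inventory_2012.csv",
                 mortality = "export_mortality_2012.csv",
                 scenarios = "community_scenarios_2012.csv")
  utils::read.csv(system.file("extdata", file, package = "nh3trade",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

ref_value <- function(tab, key, keycol = 1, valcol = 2) {
  v <- tab[tab[[keycol]] == key, valcol]
  if (length(v) != 1) stop("reference key not found: ", key)
  v
}

#' Worked arithmetic on the published reference values
#'
#' Recomputes, from the shipped reference tables, the headline derived
#' quantities: the agricultural share of total NH3 emissions, the global
#' trade-related mortality as the sum of its sectoral components, the
#' linear scaling of the community-1 beef-substitution pair through
#' [beef_substitution_reduction()], and the largest single-country share
#' of the Southeast-Asia mortality total.
#'
#' @return named list of derived values (percentages on the 0-100 scale,
#'   deaths in thousands, emissions in Gg).
#' @export
reference_worked_values <- function() {
  inv <- nh3_reference("inventory")
  mort <- nh3_reference("mortality")
  scen <- nh3_reference("scenarios")

  agri_share_pct <- 100 * ref_value(inv, "agricultural_nh3") /
    ref_value(inv, "total_nh3")
  trade_deaths_thousand <- ref_value(mort, "crop_export") +
    ref_value(mort, "livestock_export")

  # community-1 beef pair: infer the implied livestock base from the 20 %
  # cut at the global 30 % beef share, then evaluate the 50 % cut with the
  # package's scenario operator
  beef20 <- ref_value(scen, "beef_cut20")
  base_livestock <- beef20 / (0.3 * 0.2)
  em <- data.frame(region = "C1", sector = c("c1", "l1", "o1"),
                   category = c("crop", "livestock", "other"),
                   output = 1,
                   emissions = c(0, base_livestock, 0),
                   stringsAsFactors = FALSE)
  class(em) <- c("sector_emissions", "data.frame")
  beef50 <- beef_substitution_reduction(em, 0.3, 0.5)$reduction

  se_total <- ref_value(mort, "southeast_asia")
  bgd_share_pct <- 100 * ref_value(mort, "bangladesh") / se_total

  list(agricultural_share_pct = agri_share_pct,
       trade_related_deaths_thousand = trade_deaths_thousand,
       beef_cut20_community1_gg = beef_substitution_reduction(em, 0.3, 0.2)$reduction,
       beef_cut50_community1_gg = beef50,
       bangladesh_share_of_se_asia_pct = bgd_share_pct)
}
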