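#' Fractional contribution of a source to PM2.5
#'
#' fraction = (total - perturbed) / total, clipped to \[0, 1\], with zero
#' where the total concentration is zero. Computed on the coarse
#' (transport-model) grid; clipping events guard against surrogate
#' nonlinearity and are reported via a message.
#'
#' @param total_field,perturbed_field coarse `grid_field`s of PM2.5.
#' @return `grid_field` of dimensionless fractions.
#' @export
fractional_contribution <- function(total_field, perturbed_field) {
  stop_if_grid_mismatch(total_field, perturbed_field)
  tot <- total_field$values
  f <- ifelse(tot > 0, (tot - perturbed_field$values) / tot, 0)
  n_clip <- sum(f < 0 | f > 1)
  if (n_clip > 0)
    message(n_clip, " fractional contributions clipped to [0, 1]")
  grid_field(pmin(pmax(f, 0), 1), total_field$lat, total_field$lon,
             units = "1", name = "fractional_contribution")
}

#' Transfer a coarse fraction field to a nested fine grid
#'
#' Each fine cell takes the value of the coarse cell containing its
#' center (block-constant downscaling); values stay in \[0, 1\].
#'
#' @param coarse coarse `grid_field`.
#' @param fine_grid grid definition (from [make_grid()]) or `grid_field`.
#' @return fine `grid_field`.
#' @export
regrid_fractions <- function(coarse, fine_grid) {
  nest <- nesting_index(coarse, fine_grid)
  grid_field(coarse$values[nest$ilat, nest$ilon, drop = FALSE],
             fine_grid$lat, fine_grid$lon,
             units = coarse$units, name = coarse$name)
}

#' Synthetic integrated exposure-response parameter set
#'
#' One shape-parameter set (alpha, gamma, delta, counterfactual C0) per
#' disease. Central values are synthetic but of plausible magnitude for
#' the four causes; real parameter tables can be supplied in the same
#' layout.
#'
#' @return data frame with columns disease, alpha, gamma, delta, c0.
#' @export
ier_default_params <- function() {
  data.frame(
    disease = c("ihd", "copd", "stroke", "lung_cancer"),
    alpha = c(1.4, 0.6, 1.1, 0.5),
    gamma = c(0.04, 0.03, 0.05, 0.03),
    delta = c(0.8, 1.0, 0.75, 1.1),
    c0 = c(7.3, 7.3, 7.3, 7.3),
    stringsAsFactors = FALSE)
}

#' Ensemble of IER parameter sets for Monte-Carlo uncertainty
#'
#' Members are drawn log-normally around the central shape parameters
#' (20 % coefficient of variation) with the counterfactual drawn uniformly
#' in the published 5.8-8.8 ug m-3 minimum-risk range; generation is a
#' pure function of the seed.
#'
#' @param n_members ensemble size (default 1000).
#' @param seed integer seed.
#' @param central central parameter table, as [ier_default_params()].
#' @return list of parameter data frames, with the seed as an attribute.
#' @export
ier_ensemble <- function(n_members = 1000, seed = 1L,
                         central = ier_default_params()) {
  if (n_members < 1) stop("ensemble must be non-empty")
  with_seed(seed, {
    members <- lapply(seq_len(n_members), function(m) {
      p <- central
      k <- nrow(p)
      p$alpha <- p$alpha * exp(stats::rnorm(k, 0, 0.2))
      p$gamma <- p$gamma * exp(stats::rnorm(k, 0, 0.2))
      p$delta <- p$delta * exp(stats::rnorm(k, 0, 0.1))
      p$c0 <- stats::runif(k, 5.8, 8.8)
      p
    })
    attr(members, "seed") <- seed
    members
  })
}

#' Integrated exposure-response relative risk
#'
#' RR(C) = 1 + alpha (1 - exp(-gamma (C - C0)^delta)) above the
#' counterfactual C0 and exactly 1 at or below it; continuous at C0,
#' non-decreasing in C and bounded by 1 + alpha.
#'
#' @param C PM2.5 concentration(s), ug m-3, >= 0.
#' @param params one-row slice of an IER parameter table, or the full
#'   table together with `disease`.
#' @param disease disease label selecting the row when `params` has
#'   several.
#' @return relative risk, same shape as `C`.
#' @export
ier_relative_risk <- function(C, params, disease = NULL) {
  if (!is.null(disease)) params <- params[params$disease == disease, ]
  if (nrow(params) != 1) stop("params must resolve to a single disease row")
  if (any(C < 0)) stop("concentrations must be non-negative")
  if (params$alpha <= 0 || params$gamma <= 0 || params$delta <= 0)
    stop("invalid IER parameters: alpha, gamma, delta must be positive")
  excess <- pmax(C - params$c0, 0)
  1 + params$alpha * (1 - exp(-params$gamma * excess^params$delta))
}

#' Fit IER shape parameters to a relative-risk curve
#'
#' Least-squares recovery of (alpha, gamma, delta) from RR evaluations at
#' known concentrations with C0 fixed; used to sanity-check the IER
#' implementation by round-tripping noiseless curves.
#'
#' @param C concentrations, ug m-3.
#' @param RR observed relative risks.
#' @param c0 counterfactual concentration (fixed).
#' @param start optional starting values `c(alpha, gamma, delta)`.
#' @return named vector `alpha`, `gamma`, `delta`.
#' @export
fit_ier <- function(C, RR, c0, start = c(alpha = 1, gamma = 0.05, delta = 1)) {
  obj <- function(par) {
    p <- data.frame(disease = "x", alpha = exp(par[1]), gamma = exp(par[2]),
                    delta = exp(par[3]), c0 = c0)
    sum((ier_relative_risk(C, p) - RR)^2)
  }
  fit <- stats::optim(log(start), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  out <- exp(fit$par)
  names(out) <- c("alpha", "gamma", "delta")
  out
}

#' PM2.5-attributable premature mortality on a grid
#'
#' Per cell and disease, Mort = y0 x pop x (1 - 1/RR), using the baseline
#' mortality rate of the region owning the cell; the four diseases are
#' summed for the total.
#'
#' @param C_field fine `grid_field` of PM2.5 (ug m-3).
#' @param pop fine `grid_field` of population.
#' @param mask fine `grid_field` of region codes.
#' @param y0 region x disease matrix of baseline mortality rates
#'   (deaths per person per year), rownames = region labels.
#' @param params IER parameter table (one row per disease).
#' @return a `mortality_result`: total grid, per-region-by-disease table,
#'   and the grand total (deaths per year).
#' @export
attributable_mortality <- function(C_field, pop, mask, y0, params) {
  stop_if_grid_mismatch(C_field, pop)
  stop_if_grid_mismatch(C_field, mask)
  if (any(y0 < 0)) stop("baseline mortality must be non-negative")
  codes <- sort(unique(as.integer(mask$values)))
  if (length(codes) > nrow(y0))
    stop("region in mask without a baseline-mortality entry")
  total <- matrix(0, nrow(C_field$values), ncol(C_field$values))
  by_region <- matrix(0, nrow(y0), nrow(params),
                      dimnames = list(rownames(y0), params$disease))
  for (d in seq_len(nrow(params))) {
    rr <- ier_relative_risk(C_field$values, params[d, ])
    paf <- 1 - 1 / rr
    y0_cell <- y0[as.integer(mask$values), d]
    mort_d <- matrix(y0_cell, nrow(total)) * pop$values * paf
    total <- total + mort_d
    by_region[, d] <- vapply(seq_len(nrow(y0)), function(r)
      sum(mort_d[mask$values == r]), numeric(1))
  }
  structure(list(
    grid = grid_field(total, C_field$lat, C_field$lon,
                      units = "deaths a-1", name = "attributable_mortality"),
    by_region = by_region,
    total = sum(total)), class = "mortality_result")
}

#' @export
print.mortality_result <- function(x, ...) {
  cat(sprintf("<mortality_result> %.1f deaths a-1 total\n", x$total))
  print(round(x$by_region, 2))
  invisible(x)
}

#' Attribute gridded mortality to a source by its PM2.5 share
#'
#' Cellwise product of a fractional-contribution field (in \[0, 1\], on the
#' fine grid) with the total PM2.5-attributable mortality; running one
#' perturbation per source country and sector yields the bilateral and
#' sectoral splits.
#'
#' @param total_mort a `mortality_result` for total PM2.5.
#' @param fraction fine `grid_field` of source shares.
#' @param mask optional fine mask to rebuild per-region sums.
#' @return a `mortality_result` for the source.
#' @export
source_attributed_mortality <- function(total_mort, fraction, mask = NULL) {
  stop_if_grid_mismatch(total_mort$grid, fraction)
  if (any(fraction$values < -1e-12 | fraction$values > 1 + 1e-12))
    stop("fractions must lie in [0, 1]")
  vals <- total_mort$grid$values * fraction$values
  by_region <- NULL
  if (!is.null(mask)) {
    codes <- sort(unique(as.integer(mask$values)))
    by_region <- vapply(codes, function(r) sum(vals[mask$values == r]),
                        numeric(1))
    names(by_region) <- codes
  }
  structure(list(
    grid = grid_field(vals, fraction$lat, fraction$lon,
                      units = "deaths a-1", name = "source_attributed_mortality"),
    by_region = by_region,
    total = sum(vals)), class = "mortality_result")
}

#' Ensemble-mean mortality with empirical uncertainty interval
#'
#' Evaluates [attributable_mortality()] for every IER ensemble member and
#' reports the mean (the headline value) with empirical 2.5/97.5
#' percentiles of the total. Averaging is over mortality, not over
#' parameters.
#'
#' @inheritParams attributable_mortality
#' @param ensemble list of parameter tables from [ier_ensemble()].
#' @return a `mortality_result` with the mean grid plus `ci` (2.5 %,
#'   97.5 %) and `member_totals`.
#' @export
monte_carlo_mortality <- function(C_field, pop, mask, y0, ensemble) {
  if (length(ensemble) == 0) stop("ensemble must be non-empty")
  acc <- NULL
  totals <- numeric(length(ensemble))
  by_region_acc <- NULL
  for (m in seq_along(ensemble)) {
    res <- attributable_mortality(C_field, pop, mask, y0, ensemble[[m]])
    if (is.null(acc)) {
      acc <- res$grid$values
      by_region_acc <- res$by_region
    } else {
      acc <- acc + res$grid$values
      by_region_acc <- by_region_acc + res$by_region
    }
    totals[m] <- res$total
  }
  k <- length(ensemble)
  structure(list(
    grid = grid_field(acc / k, C_field$lat, C_field$lon,
                      units = "deaths a-1", name = "attributable_mortality_mean"),
    by_region = by_region_acc / k,
    total = mean(totals),
    ci = stats::quantile(totals, c(0.025, 0.975), names = TRUE),
    member_totals = totals), class = "mortality_result")
}

#' Aggregate gridded deaths over a region or a lat/lon box
#'
#' Country totals use the mask; box selections include cells whose
#' centers fall inside the (closed) bounds.
#'
#' @param result a `mortality_result`.
#' @param region integer region code (requires `mask`).
#' @param mask fine `grid_field` of region codes.
#' @param lat_min,lat_max,lon_min,lon_max box bounds in degrees.
#' @return deaths per year in the selection.
#' @export
aggregate_mortality <- function(result, region = NULL, mask = NULL,
                                lat_min = -Inf, lat_max = Inf,
                                lon_min = -Inf, lon_max = Inf) {
  g <- result$grid
  keep <- outer(g$lat >= lat_min & g$lat <= lat_max,
                g$lon >= lon_min & g$lon <= lon_max, `&`)
  if (!is.null(region)) {
    if (is.null(mask)) stop("region selection requires a mask")
    stop_if_grid_mismatch(g, mask)
    keep <- keep & mask$values == region
  }
  if (!any(keep)) stop("empty selection")
  sum(g$values[keep])
}

#' Export-related premature deaths per source economy
#'
#' The full attribution chain: for each source economy (and optionally
#' each agricultural sector), perturb its gridded NH3 by the embodied
#' export fraction, rerun the dispersion surrogate, form the fractional
#' PM2.5 contribution on the coarse grid, downscale it, and multiply by
#' the total PM2.5-attributable mortality field.
#'
#' @param world a `synthetic_world`.
#' @param accounts output of [mrio_accounts()].
#' @param total_mort a `mortality_result` for total PM2.5 (e.g. the
#'   Monte-Carlo mean); defaults to a single central-parameter run.
#' @param by_sector also compute the crop/livestock split.
#' @return data frame per region: export-related deaths (total and, when
#'   requested, per sector), with the fraction fields as an attribute.
#' @export
export_attributed_deaths <- function(world, accounts, total_mort = NULL,
                                     by_sector = TRUE) {
  g <- world$grids
  cfg <- world$config
  if (is.null(total_mort))
    total_mort <- attributable_mortality(g$pm25_total, g$population,
                                         g$mask_fine, g$y0,
                                         ier_default_params())
  totals <- emission_totals(world$emissions)
  base_field <- g$emission_field
  base_conc <- surrogate_dispersion(base_field, cfg$kernel_scale,
                                    strength = cfg$pm25_per_gg)
  total_coarse <- grid_field(cfg$background_pm25 + base_conc$values,
                             base_conc$lat, base_conc$lon,
                             units = "ug m-3", name = "pm25_total_coarse")
  frac <- list(
    crop = export_emission_fraction(accounts$accounts_crop),
    livestock = export_emission_fraction(accounts$accounts_livestock))
  regions <- region_labels(cfg)
  run_one <- function(r, categories) {
    pert_tot <- totals
    i <- pert_tot$region == regions[r]
    for (cat in categories)
      pert_tot[i, cat] <- pert_tot[i, cat] * (1 - frac[[cat]][regions[r]])
    pert_field <- emission_field(cfg, g$mask_coarse, pert_tot,
                                 categories = c("crop", "livestock"))
    pert_conc <- surrogate_dispersion(pert_field, cfg$kernel_scale,
                                      strength = cfg$pm25_per_gg)
    pert_total <- grid_field(cfg$background_pm25 + pert_conc$values,
                             pert_conc$lat, pert_conc$lon,
                             units = "ug m-3", name = "pm25_perturbed")
    fr_coarse <- fractional_contribution(total_coarse, pert_total)
    fr_fine <- regrid_fractions(fr_coarse, g$pm25_total)
    source_attributed_mortality(total_mort, fr_fine)$total
  }
  n <- cfg$n_regions
  out <- data.frame(region = regions,
                    deaths_total = vapply(seq_len(n), run_one,
                                          numeric(1),
                                          categories = c("crop", "livestock")))
  if (by_sector) {
    out$deaths_crop <- vapply(seq_len(n), run_one, numeric(1),
                              categories = "crop")
    out$deaths_livestock <- vapply(seq_len(n), run_one, numeric(1),
                                   categories = "livestock")
  }
  out
}
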