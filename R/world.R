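#' Configuration for the synthetic world generator
#'
#' Defines the toy study system: a balanced multi-region economy with crop,
#' livestock and non-agricultural sectors, heterogeneous NH3 emission
#' intensities, a heavy-tailed international trade network, and spatially
#' smooth PM2.5 fields dominated by near-source contributions.
#'
#' @param n_regions number of economies (>= 2).
#' @param sectors_per_region character vector of category tags, one per
#'   sector, each in `c("crop", "livestock", "other")`; every region carries
#'   the same sector list and must have at least one sector of each category.
#' @param grid_resolution_fine fine-grid cell size in degrees (0.5 default;
#'   0.1 emulates the full-scale exposure grid).
#' @param grid_resolution_coarse coarse (transport-model) cell size,
#'   `(lat, lon)` degrees; defaults to 2 x 2.5.
#' @param lat_range,lon_range toy domain edges (degrees).
#' @param seed integer master seed; all generation is a pure function of
#'   the config including this seed.
#' @param trade_density probability in \[0,1\] that an ordered region pair
#'   trades at all (off-diagonal block non-zero).
#' @param intensity_dispersion log-scale standard deviation of regional
#'   emission intensities.
#' @param uncertainty_factor multiplicative inventory uncertainty bound
#'   (emission inventories are typically known within a factor 2-3).
#' @param background_pm25 non-NH3 PM2.5 background, ug m-3.
#' @param world_population total population summed over the grid.
#' @param kernel_scale e-folding scale (degrees) of the dispersion kernel.
#' @param pm25_per_gg concentration produced in a coarse cell per Gg of
#'   NH3 emitted in it, ug m-3 per Gg (surrogate source-receptor strength).
#' @return object of class `world_config`.
#' @export
world_config <- function(n_regions = 4,
                         sectors_per_region = c("crop", "livestock", "other"),
                         grid_resolution_fine = 0.5,
                         grid_resolution_coarse = c(2, 2.5),
                         lat_range = c(-20, 20),
                         lon_range = c(-25, 25),
                         seed = 1L,
                         trade_density = 0.7,
                         intensity_dispersion = 0.5,
                         uncertainty_factor = 2.5,
                         background_pm25 = 12,
                         world_population = 1e9,
                         kernel_scale = 3,
                         pm25_per_gg = 5) {
  cats <- c("crop", "livestock", "other")
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (!all(sectors_per_region %in% cats))
    stop("sector categories must be in {crop, livestock, other}")
  if (!all(cats %in% sectors_per_region))
    stop("every region needs at least one crop, one livestock and one other sector")
  if (trade_density < 0 || trade_density > 1) stop("trade_density must be in [0,1]")
  if (uncertainty_factor < 1) stop("uncertainty_factor must be >= 1")
  if (length(grid_resolution_coarse) == 1)
    grid_resolution_coarse <- rep(grid_resolution_coarse, 2)
  ratio <- grid_resolution_coarse / grid_resolution_fine
  if (any(abs(ratio - round(ratio)) > 1e-9))
    stop("fine resolution must divide the coarse cell size evenly")
  structure(list(
    n_regions = as.integer(n_regions),
    sectors_per_region = sectors_per_region,
    grid_resolution_fine = grid_resolution_fine,
    grid_resolution_coarse = grid_resolution_coarse,
    lat_range = lat_range, lon_range = lon_range,
    seed = as.integer(seed),
    trade_density = trade_density,
    intensity_dispersion = intensity_dispersion,
    uncertainty_factor = uncertainty_factor,
    background_pm25 = background_pm25,
    world_population = world_population,
    kernel_scale = kernel_scale,
    pm25_per_gg = pm25_per_gg), class = "world_config")
}

region_labels <- function(config) sprintf("R%02d", seq_len(config$n_regions))

sector_index <- function(config) {
  regions <- region_labels(config)
  k <- length(config$sectors_per_region)
  sec <- sprintf("%s%d", substr(config$sectors_per_region, 1, 1),
                 stats::ave(seq_len(k), config$sectors_per_region, FUN = seq_along))
  data.frame(
    region = rep(regions, each = k),
    sector = rep(sec, config$n_regions),
    category = rep(config$sectors_per_region, config$n_regions),
    stringsAsFactors = FALSE)
}

#' Generate a balanced multiregional input-output table
#'
#' Draws heavy-tailed regional gross outputs and a sparse, heavy-tailed
#' inter-regional transaction structure, then balances the transaction
#' matrix by iterative proportional fitting (IPF) against intermediate-use
#' row and column margins. Final demand is the exact row residual, so the
#' accounting identity X = Z 1 + F 1 holds to machine precision, and column
#' intermediate shares below one guarantee a Leontief-invertible table
#' (spectral radius of Z diag(X)^-1 < 1). Final demand is stored by
#' destination region so consumption-based accounts need no disaggregation.
#'
#' @param config a [world_config()].
#' @param max_iter,tol IPF iteration cap and relative margin tolerance.
#' @return an `mrio_table`: list with transactions `Z` (N x N), final demand
#'   `F` (N x n, by consuming region), gross output `X` (N), and the
#'   region/sector/category index.
#' @export
generate_economy <- function(config, max_iter = 20000, tol = 1e-10) {
  idx <- sector_index(config)
  n <- config$n_regions
  N <- nrow(idx)
  regions <- region_labels(config)
  with_seed(stage_seed(config$seed, "economy"), {
    # heavy-tailed regional size so a few hub economies dominate trade
    size <- (1 / stats::runif(n))^0.8          # Pareto-like
    size <- size / sum(size) * n
    sector_share <- matrix(stats::rlnorm(N, 0, 0.4), nrow = n, byrow = TRUE)
    X <- as.numeric(t(sector_share * size)) * 1000  # monetary units
    names(X) <- paste(idx$region, idx$sector, sep = ":")

    # region-pair trade links (symmetric existence so the balancing
    # problem stays non-degenerate; magnitudes remain asymmetric and
    # heavy-tailed so a few hub pairs dominate)
    link <- matrix(FALSE, n, n)
    link[upper.tri(link)] <- stats::runif(n * (n - 1) / 2) < config$trade_density
    link <- link | t(link)
    diag(link) <- TRUE
    link_w <- matrix((1 / stats::runif(n * n))^0.7, n, n)
    link_w[!link] <- 0
    diag(link_w) <- 1

    # column intermediate-input shares (< 1 keeps the table invertible)
    phi <- stats::runif(N, 0.25, 0.55)
    # row intermediate-sales shares, rescaled within each region so the
    # within-region margins are consistent (IPF then converges even for
    # an autarkic block-diagonal support)
    psi <- stats::runif(N, 0.2, 0.7)
    for (r in regions) {
      i <- which(idx$region == r)
      target <- sum(phi[i] * X[i])       # < 0.55 sum(X[i]), so feasible
      psi[i] <- psi[i] * target / sum(psi[i] * X[i])
      # cap at 0.9 and push the excess onto the uncapped sectors
      for (pass in 1:20) {
        over <- psi[i] > 0.9
        if (!any(over)) break
        psi[i][over] <- 0.9
        free <- i[!over]
        deficit <- target - sum(psi[i] * X[i])
        psi[free] <- psi[free] + deficit * psi[free] * X[free] /
          sum(psi[free] * X[free]) / X[free]
      }
      if (any(psi[i] > 0.9 + 1e-9))
        stop("economy balancing failed: intermediate-sales shares infeasible")
    }

    seedZ <- matrix(stats::runif(N * N, 0.5, 1.5), N, N)
    rblock <- match(idx$region, regions)
    seedZ <- seedZ * link_w[cbind(rep(rblock, times = N),
                                  rep(rblock, each = N))]

    rmarg <- psi * X
    cmarg <- phi * X
    Z <- seedZ
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      rs <- rowSums(Z)
      Z <- Z * (rmarg / pmax(rs, 1e-300))
      cs <- colSums(Z)
      Z <- Z * rep(cmarg / pmax(cs, 1e-300), each = N)
      if (max(abs(rowSums(Z) - rmarg) / pmax(rmarg, 1e-300)) < tol) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("economy balancing failed: IPF did not converge within ",
                  max_iter, " iterations")

    # final demand = exact row residual, split by consuming region with a
    # strong home bias and heavy-tailed partner shares over trade links
    Ftot <- X - rowSums(Z)
    if (any(Ftot < -1e-9 * X)) stop("economy balancing failed: negative final demand")
    Ftot <- pmax(Ftot, 0)
    home <- stats::runif(N, 0.55, 0.85)
    Fmat <- matrix(0, N, n, dimnames = list(names(X), regions))
    for (i in seq_len(N)) {
      r <- rblock[i]
      partners <- which(link[r, ] & seq_len(n) != r)
      if (length(partners) == 0) {
        Fmat[i, r] <- Ftot[i]
      } else {
        w <- link_w[r, partners] * stats::runif(length(partners), 0.5, 1.5)
        Fmat[i, partners] <- (1 - home[i]) * Ftot[i] * w / sum(w)
        Fmat[i, r] <- home[i] * Ftot[i]
      }
    }
    # restore exact row balance after rounding in the split
    Fmat <- Fmat * ifelse(Ftot > 0, Ftot / pmax(rowSums(Fmat), 1e-300), 0)

    mrio <- structure(list(Z = Z, F = Fmat, X = X, index = idx,
                           regions = regions),
                      class = "mrio_table")
    dimnames(mrio$Z) <- list(names(X), names(X))
    validate_mrio(mrio)
    mrio
  })
}

#' Validate an MRIO table
#'
#' Checks non-negativity, the accounting balance X = Z 1 + F 1, and
#' Leontief invertibility (spectral radius of the technical-coefficient
#' matrix below one).
#'
#' @param mrio an `mrio_table`.
#' @param tol relative balance tolerance.
#' @return invisibly `TRUE`; stops with a message naming the failure.
#' @export
validate_mrio <- function(mrio, tol = 1e-9) {
  if (any(mrio$Z < 0) || any(mrio$F < 0) || any(mrio$X < 0))
    stop("MRIO entries must be non-negative")
  bal <- mrio$X - rowSums(mrio$Z) - rowSums(mrio$F)
  rel <- max(abs(bal) / pmax(mrio$X, 1e-300))
  if (rel > tol)
    stop(sprintf("MRIO row balance violated (max rel error %.3g) at %s",
                 rel, names(mrio$X)[which.max(abs(bal) / pmax(mrio$X, 1e-300))]))
  A <- technical_coefficients(mrio)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("technical coefficient matrix not invertible (spectral radius %.4f)", rho))
  invisible(TRUE)
}

#' @export
print.mrio_table <- function(x, ...) {
  cat(sprintf("<mrio_table> %d regions x %d sectors (N = %d)\n",
              length(x$regions), nrow(x$index) / length(x$regions),
              length(x$X)))
  cat(sprintf("  gross output %.4g, intermediate %.4g, final demand %.4g\n",
              sum(x$X), sum(x$Z), sum(x$F)))
  invisible(x)
}

#' Generate sectoral NH3 emissions for a synthetic economy
#'
#' Each region draws one crop and one livestock emission intensity
#' (log-normally dispersed across regions around field-realistic central
#' values, livestock more intensive than crops per unit output); sectoral
#' emissions are intensity times gross output, and non-agricultural
#' sectors emit nothing.
#'
#' @param config a [world_config()].
#' @param mrio the matching `mrio_table`.
#' @return a `sector_emissions` data frame: region, sector, category,
#'   output, emissions (Gg per year).
#' @export
generate_emissions <- function(config, mrio) {
  idx <- mrio$index
  with_seed(stage_seed(config$seed, "emissions"), {
    n <- config$n_regions
    base <- c(crop = 0.004, livestock = 0.009, other = 0)  # Gg per monetary unit
    disp <- matrix(exp(stats::rnorm(2 * n, 0, config$intensity_dispersion)),
                   nrow = n, dimnames = list(region_labels(config),
                                             c("crop", "livestock")))
    intensity <- numeric(nrow(idx))
    ag <- idx$category %in% c("crop", "livestock")
    intensity[ag] <- base[idx$category[ag]] *
      disp[cbind(idx$region[ag], idx$category[ag])]
    out <- data.frame(idx, output = unname(mrio$X),
                      emissions = unname(intensity * mrio$X),
                      stringsAsFactors = FALSE)
    class(out) <- c("sector_emissions", "data.frame")
    out
  })
}

#' Region by category emission totals
#'
#' @param emissions a `sector_emissions` table.
#' @return data frame region x category (crop, livestock) totals in Gg.
#' @export
emission_totals <- function(emissions) {
  regions <- sort(unique(emissions$region))
  tot <- function(cat) vapply(regions, function(r)
    sum(emissions$emissions[emissions$region == r & emissions$category == cat]),
    numeric(1))
  data.frame(region = regions, crop = tot("crop"), livestock = tot("livestock"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Perturb an emission inventory within a multiplicative uncertainty bound
#'
#' Multiplies each region-by-category mass by an independent log-uniform
#' draw in `[1/factor_bound, factor_bound]`, emulating inventory
#' uncertainty within a factor of 2-3.
#'
#' @param emissions a `sector_emissions` table.
#' @param factor_bound multiplicative bound, >= 1.
#' @param seed integer seed; the same seed reproduces the perturbation.
#' @return perturbed `sector_emissions`.
#' @export
perturb_inventory <- function(emissions, factor_bound, seed) {
  if (factor_bound < 1) stop("factor_bound must be >= 1")
  key <- interaction(emissions$region, emissions$category, drop = FALSE)
  with_seed(seed, {
    lev <- levels(key)
    f <- exp(stats::runif(length(lev), -log(factor_bound), log(factor_bound)))
    names(f) <- lev
    emissions$emissions <- emissions$emissions * f[as.character(key)]
    emissions
  })
}

#' Generate the gridded world: country mask, population, mortality, PM2.5
#'
#' Regions occupy contiguous longitude bands of the toy domain. Population
#' concentrates in a few city cells per region (plus a thin rural spread)
#' and sums to the configured world total. The total PM2.5 field is the
#' configured background plus the surrogate-dispersion contribution of each
#' region's agricultural NH3, allocated uniformly over the region's coarse
#' mask cells. Per-region baseline mortality rates are drawn for the four
#' leading causes (ischemic heart disease, COPD, stroke, lung cancer).
#'
#' @param config a [world_config()].
#' @param emissions a `sector_emissions` table for the same world.
#' @return list of grids and tables: `mask_coarse`, `mask_fine`,
#'   `population`, `pm25_total` (fine), `emission_field` (coarse, all
#'   agriculture), per-category emission fields, and `y0` (region x disease
#'   baseline mortality rates, per person per year).
#' @export
generate_grids <- function(config, emissions) {
  coarse <- make_grid(config$grid_resolution_coarse, config$lat_range, config$lon_range)
  fine <- make_grid(config$grid_resolution_fine, config$lat_range, config$lon_range)
  n <- config$n_regions
  regions <- region_labels(config)
  if (length(coarse$lon) < n)
    stop("resolution mismatch: fewer coarse longitude columns than regions")

  # contiguous longitude bands, one per region, on the coarse grid
  band <- as.integer(cut(seq_along(coarse$lon), breaks = n, labels = FALSE))
  mask_c <- matrix(rep(band, each = length(coarse$lat)),
                   nrow = length(coarse$lat))
  mask_coarse <- grid_field(mask_c, coarse$lat, coarse$lon,
                            units = "region code", name = "country_mask")
  nest <- nesting_index(coarse, fine)
  mask_fine <- grid_field(mask_c[nest$ilat, nest$ilon], fine$lat, fine$lon,
                          units = "region code", name = "country_mask")

  totals <- emission_totals(emissions)
  with_seed(stage_seed(config$seed, "grids"), {
    # population: a few lognormal-weighted cities per region + rural spread
    pop <- matrix(0, length(fine$lat), length(fine$lon))
    reg_share <- stats::rlnorm(n, 0, 0.6)
    reg_share <- reg_share / sum(reg_share)
    for (r in seq_len(n)) {
      cells <- which(mask_fine$values == r)
      ncity <- min(3L, length(cells))
      city <- sample(cells, ncity)
      w <- stats::rlnorm(ncity, 0, 1)
      pop[city] <- pop[city] + 0.9 * w / sum(w) * reg_share[r]
      pop[cells] <- pop[cells] + 0.1 * reg_share[r] / length(cells)
    }
    pop <- pop / sum(pop) * config$world_population
    population <- grid_field(pop, fine$lat, fine$lon,
                             units = "persons", name = "population")

    diseases <- c("ihd", "copd", "stroke", "lung_cancer")
    base_y0 <- c(ihd = 1.5e-3, copd = 5e-4, stroke = 1.1e-3, lung_cancer = 3e-4)
    y0 <- matrix(stats::rlnorm(n * 4, 0, 0.3), n, 4,
                 dimnames = list(regions, diseases))
    y0 <- sweep(y0, 2, base_y0, `*`)

    emf_all <- emission_field(config, mask_coarse, totals,
                              categories = c("crop", "livestock"))
    emf_crop <- emission_field(config, mask_coarse, totals, categories = "crop")
    emf_liv <- emission_field(config, mask_coarse, totals, categories = "livestock")
    contrib <- surrogate_dispersion(emf_all, config$kernel_scale,
                                    strength = config$pm25_per_gg)
    pm_fine <- config$background_pm25 +
      contrib$values[nest$ilat, nest$ilon]
    pm25_total <- grid_field(pm_fine, fine$lat, fine$lon,
                             units = "ug m-3", name = "pm25_total")

    list(mask_coarse = mask_coarse, mask_fine = mask_fine,
         population = population, pm25_total = pm25_total,
         emission_field = emf_all,
         emission_field_crop = emf_crop,
         emission_field_livestock = emf_liv,
         contribution = contrib,
         y0 = y0)
  })
}

#' Allocate regional emission totals uniformly over mask cells
#'
#' @param config a [world_config()].
#' @param mask_coarse coarse `grid_field` of region codes.
#' @param totals region x category totals from [emission_totals()].
#' @param categories categories to include.
#' @return coarse `grid_field` of NH3 mass (Gg) per cell.
#' @export
emission_field <- function(config, mask_coarse, totals,
                           categories = c("crop", "livestock")) {
  vals <- matrix(0, length(mask_coarse$lat), length(mask_coarse$lon))
  for (r in seq_len(config$n_regions)) {
    cells <- which(mask_coarse$values == r)
    mass <- sum(unlist(totals[totals$region == region_labels(config)[r],
                              categories, drop = FALSE]))
    vals[cells] <- mass / length(cells)
  }
  grid_field(vals, mask_coarse$lat, mask_coarse$lon,
             units = "Gg", name = paste0("nh3_", paste(categories, collapse = "_")))
}

#' Linear source-receptor surrogate for atmospheric dispersion
#'
#' Convolves a gridded emission field with an isotropic Gaussian kernel
#' (planar degree distance, mass-normalized over the domain), standing in
#' for chemical-transport-model sensitivity runs. The operator is strictly
#' linear in emissions, and a point source produces its maximum
#' contribution in the source cell with monotone decay outward.
#'
#' @param emissions_field coarse `grid_field` of emitted mass (Gg).
#' @param kernel_scale Gaussian e-folding scale, degrees.
#' @param strength concentration per unit emitted mass, ug m-3 per Gg.
#' @return `grid_field` of concentration contributions (ug m-3).
#' @export
surrogate_dispersion <- function(emissions_field, kernel_scale, strength = 5) {
  E <- emissions_field$values
  if (any(E < 0)) stop("negative emissions rejected")
  lat <- emissions_field$lat
  lon <- emissions_field$lon
  # separable Gaussian kernel; each source cell's kernel is normalized to
  # unit domain-summed weight so emitted mass is redistributed, not created
  Kl <- exp(-outer(lat, lat, `-`)^2 / (2 * kernel_scale^2))
  Ko <- exp(-outer(lon, lon, `-`)^2 / (2 * kernel_scale^2))
  norm <- outer(colSums(Kl), colSums(Ko))
  W <- Kl %*% (E / norm) %*% Ko
  grid_field(strength * W, lat, lon,
             units = "ug m-3", name = "pm25_contribution")
}

#' Generate a complete synthetic world
#'
#' Runs the economy, emission, grid, climate/capacity and IER-ensemble
#' generators under one master seed.
#'
#' @param config a [world_config()].
#' @param ensemble_size number of IER parameter sets (default 1000).
#' @return a `synthetic_world` list: `config`, `mrio`, `emissions`,
#'   `grids`, `climate` (region AVT degC, PCP mm/yr, capacity AC),
#'   `waste_ratios`, `beef_share`, `ier`.
#' @export
synthetic_world <- function(config, ensemble_size = 1000) {
  mrio <- generate_economy(config)
  emissions <- generate_emissions(config, mrio)
  grids <- generate_grids(config, emissions)
  n <- config$n_regions
  regions <- region_labels(config)
  climate <- with_seed(stage_seed(config$seed, "grids") + 1L, {
    data.frame(
      region = regions,
      avt = stats::runif(n, 2, 26),                 # degC
      pcp = stats::runif(n, 300, 1800),             # mm per year
      ac = stats::runif(n, 0.1, 0.5) *
        vapply(regions, function(r)
          sum(mrio$X[mrio$index$region == r & mrio$index$category != "other"]),
          numeric(1)),
      waste_crop = stats::runif(n, 0.15, 0.4),
      waste_meat = stats::runif(n, 0.1, 0.3),
      beef_share = stats::runif(n, 0.2, 0.4),
      stringsAsFactors = FALSE)
  })
  ier <- ier_ensemble(n_members = ensemble_size,
                      seed = stage_seed(config$seed, "ier"))
  structure(list(config = config, mrio = mrio, emissions = emissions,
                 grids = grids, climate = climate, ier = ier),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  tot <- emission_totals(x$emissions)
  cat(sprintf("<synthetic_world> %d regions, seed %d\n",
              x$config$n_regions, x$config$seed))
  cat(sprintf("  agricultural NH3: %.1f Gg crop, %.1f Gg livestock\n",
              sum(tot$crop), sum(tot$livestock)))
  invisible(x)
}
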