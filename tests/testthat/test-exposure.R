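coarse_grid <- make_grid(c(2, 2.5), c(-4, 4), c(-5, 5))
fine_grid <- make_grid(0.5, c(-4, 4), c(-5, 5))

cg_field <- function(vals, name = "f", units = "1")
  grid_field(vals, coarse_grid$lat, coarse_grid$lon, units = units, name = name)

test_that("fractional contribution handles the limits and clips", {
  tot <- cg_field(matrix(10, 4, 4), "pm25_total")
  expect_true(all(fractional_contribution(tot, tot)$values == 0))
  zero <- cg_field(matrix(0, 4, 4), "pm25_perturbed")
  expect_true(all(fractional_contribution(tot, zero)$values == 1))
  tot0 <- cg_field(matrix(0, 4, 4), "pm25_total")
  expect_true(all(fractional_contribution(tot0, zero)$values == 0))
  over <- cg_field(matrix(11, 4, 4), "pm25_perturbed")
  expect_message(fr <- fractional_contribution(tot, over), "clipped")
  expect_true(all(fr$values == 0))
})

test_that("fraction of a partial emission cut equals share times cut under linearity", {
  # one source at 50 % reduction in a two-source field
  e_a <- cg_field(matrix(0, 4, 4)); e_a$values[2, 2] <- 10
  e_b <- cg_field(matrix(0, 4, 4)); e_b$values[3, 3] <- 4
  both <- cg_field(e_a$values + e_b$values)
  background <- 7
  tot <- surrogate_dispersion(both, 2)
  tot$values <- tot$values + background
  half_a <- cg_field(0.5 * e_a$values + e_b$values)
  pert <- surrogate_dispersion(half_a, 2)
  pert$values <- pert$values + background
  fr <- fractional_contribution(tot, pert)
  share_a <- surrogate_dispersion(e_a, 2)$values / tot$values
  expect_equal(fr$values, 0.5 * share_a, tolerance = 1e-10)
})

test_that("coarse-to-fine regridding is block-constant and idempotent", {
  u <- cg_field(matrix(0.5, 4, 4))
  fu <- regrid_fractions(u, fine_grid)
  expect_true(all(fu$values == 0.5))
  expect_equal(dim(fu$values), c(16L, 20L))

  checker <- cg_field(outer(1:4, 1:4, function(i, j) (i + j) %% 2))
  fc <- regrid_fractions(checker, fine_grid)
  # exact block edges: fine cell (i, j) belongs to coarse cell (ceil(i/4), ceil(j/5))
  for (i in c(1, 4, 5, 16)) for (j in c(1, 5, 6, 20))
    expect_equal(fc$values[i, j],
                 checker$values[ceiling(i / 4), ceiling(j / 5)])
  # coarse-averaging a block-constant field recovers the original
  back <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    back[i, j] <- mean(fc$values[(4 * i - 3):(4 * i), (5 * j - 4):(5 * j)])
  expect_equal(back, checker$values)
  expect_error(regrid_fractions(u, make_grid(c(0.8, 1), c(-4, 4), c(-5, 5))),
               "nest")
})

test_that("IER relative risk matches hand evaluations and its bounds", {
  p <- data.frame(disease = "x", alpha = 1, gamma = log(2), delta = 1, c0 = 6)
  expect_equal(ier_relative_risk(6, p), 1)
  expect_equal(ier_relative_risk(0, p), 1)
  expect_equal(ier_relative_risk(7, p), 1.5)   # alpha=1, gamma=ln2, C-C0=1
  expect_equal(ier_relative_risk(1e6, p), 2, tolerance = 1e-12)
  C <- seq(0, 120, by = 0.25)
  rr <- ier_relative_risk(C, p)
  expect_true(all(diff(rr) >= 0))
  expect_true(all(rr >= 1 & rr <= 1 + p$alpha))
  expect_error(ier_relative_risk(-1, p), "non-negative")
  expect_error(ier_relative_risk(1, transform(p, gamma = -1)), "positive")
})

test_that("IER parameter fit recovers a known noiseless curve", {
  truth <- data.frame(disease = "x", alpha = 1.3, gamma = 0.04,
                      delta = 0.9, c0 = 7)
  C <- seq(8, 150, by = 2)
  fit <- fit_ier(C, ier_relative_risk(C, truth), c0 = 7)
  expect_lt(abs(fit[["alpha"]] - 1.3), 1e-4)
  expect_lt(abs(fit[["gamma"]] - 0.04), 1e-4)
  expect_lt(abs(fit[["delta"]] - 0.9), 1e-4)
})

test_that("attributable mortality reproduces the hand case and scales with population", {
  fg <- make_grid(1, c(-1, 1), c(-1, 1))   # 2 x 2 cells
  # alpha=2, gamma=ln2, delta=1 at C = C0 + 1 gives RR = 2 exactly
  p <- data.frame(disease = "ihd", alpha = 2, gamma = log(2), delta = 1, c0 = 6)
  C <- grid_field(matrix(7, 2, 2), fg$lat, fg$lon, name = "pm25")
  pop <- grid_field(matrix(1000, 2, 2), fg$lat, fg$lon, name = "pop")
  mask <- grid_field(matrix(1, 2, 2), fg$lat, fg$lon, name = "mask")
  y0 <- matrix(0.01, 1, 1, dimnames = list("R01", "ihd"))
  res <- attributable_mortality(C, pop, mask, y0, p)
  expect_equal(res$grid$values, matrix(5, 2, 2))   # y0 pop (1 - 1/RR)
  expect_equal(res$total, 20)

  pop2 <- pop
  pop2$values <- 2 * pop$values
  expect_equal(attributable_mortality(C, pop2, mask, y0, p)$total, 40)

  Cbelow <- C
  Cbelow$values[] <- 5
  expect_equal(attributable_mortality(Cbelow, pop, mask, y0, p)$total, 0)
  expect_lt(res$total, sum(y0[1, 1] * pop$values))   # Mort < y0 * pop
})

test_that("source attribution is multiplicative and additive across sectors", {
  cfg <- small_config(seed = 19, n_regions = 3)
  w <- synthetic_world(cfg, ensemble_size = 2)
  g <- w$grids
  mort <- attributable_mortality(g$pm25_total, g$population, g$mask_fine,
                                 g$y0, ier_default_params())
  ones <- grid_field(matrix(1, nrow(mort$grid$values), ncol(mort$grid$values)),
                     mort$grid$lat, mort$grid$lon, name = "fr")
  expect_equal(source_attributed_mortality(mort, ones)$total, mort$total)
  half <- ones
  half$values[] <- 0.5
  expect_equal(source_attributed_mortality(mort, half)$total, mort$total / 2)

  acc <- mrio_accounts(w)
  ed <- export_attributed_deaths(w, acc, total_mort = mort)
  # linear surrogate: sector fractions add to the all-agriculture fraction
  expect_equal(ed$deaths_crop + ed$deaths_livestock, ed$deaths_total,
               tolerance = 1e-6)
  expect_true(all(ed$deaths_total >= 0))
  expect_true(all(ed$deaths_total <= mort$total))
})

test_that("raising an export fraction cannot decrease attributed deaths", {
  cfg <- small_config(seed = 23, n_regions = 3)
  w <- synthetic_world(cfg, ensemble_size = 2)
  acc <- mrio_accounts(w)
  mort <- attributable_mortality(w$grids$pm25_total, w$grids$population,
                                 w$grids$mask_fine, w$grids$y0,
                                 ier_default_params())
  deaths_at <- function(scale) {
    acc2 <- acc
    for (nm in c("accounts_crop", "accounts_livestock")) {
      acc2[[nm]]$EEE[1] <- pmin(acc[[nm]]$EEE[1] * scale, acc[[nm]]$PBE[1])
    }
    export_attributed_deaths(w, acc2, total_mort = mort,
                             by_sector = FALSE)$deaths_total[1]
  }
  d <- vapply(c(0.5, 0.75, 1, 1.25), deaths_at, numeric(1))
  expect_true(all(diff(d) >= -1e-9))
})

test_that("Monte-Carlo mortality is convex, reproducible and degenerate-safe", {
  cfg <- small_config(seed = 29, n_regions = 2)
  w <- synthetic_world(cfg, ensemble_size = 2)
  g <- w$grids
  central <- ier_default_params()
  same <- replicate(5, central, simplify = FALSE)
  mc_same <- monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine,
                                   g$y0, same)
  single <- attributable_mortality(g$pm25_total, g$population, g$mask_fine,
                                   g$y0, central)
  expect_equal(mc_same$total, single$total, tolerance = 1e-12)

  ens <- ier_ensemble(50, seed = 99)
  mc1 <- monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine, g$y0, ens)
  mc2 <- monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine, g$y0,
                               ier_ensemble(50, seed = 99))
  expect_identical(mc1$total, mc2$total)
  expect_gte(mc1$total, min(mc1$member_totals))
  expect_lte(mc1$total, max(mc1$member_totals))
  expect_true(mc1$ci[1] <= mc1$total && mc1$total <= mc1$ci[2])
  expect_error(monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine,
                                     g$y0, list()), "non-empty")
})

test_that("a reduced ensemble mean falls inside the large-ensemble interval", {
  cfg <- small_config(seed = 31, n_regions = 2)
  w <- synthetic_world(cfg, ensemble_size = 2)
  g <- w$grids
  big <- monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine, g$y0,
                               ier_ensemble(400, seed = 7))
  small <- monte_carlo_mortality(g$pm25_total, g$population, g$mask_fine, g$y0,
                                 ier_ensemble(100, seed = 8))
  expect_gte(small$total, big$ci[1])
  expect_lte(small$total, big$ci[2])
})

test_that("mortality aggregation is additive over boxes and honors the mask", {
  fg <- make_grid(1, c(20, 60), c(-2, 2))   # latitudes 20.5 .. 59.5
  vals <- matrix(0, 40, 4)
  vals[25, 2] <- 100                        # concentrated near 44.5 N
  vals[5, 1] <- 0.5
  res <- structure(list(grid = grid_field(vals, fg$lat, fg$lon,
                                          units = "deaths a-1", name = "m"),
                        total = sum(vals)), class = "mortality_result")
  whole <- aggregate_mortality(res)
  expect_equal(whole, sum(vals))
  north <- aggregate_mortality(res, lat_min = 30)
  south <- aggregate_mortality(res, lat_max = 29.9)
  expect_equal(north + south, whole)
  expect_gte(north / whole, 0.99)
  mask <- grid_field(matrix(1, 40, 4), fg$lat, fg$lon, name = "mask")
  expect_equal(aggregate_mortality(res, region = 1, mask = mask), whole)
  expect_error(aggregate_mortality(res, lat_min = 90), "empty")
})
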