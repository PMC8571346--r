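test_that("climate window is symmetric, closed at the boundary, and exclusive beyond", {
  clim <- data.frame(region = c("a", "b", "c", "d"),
                     avt = c(10, 10, 16, 15),
                     pcp = c(800, 800, 800, 1300))
  I <- climate_compatibility(clim)
  expect_true(all(diag(I) == 1))
  expect_equal(I, t(I))
  expect_equal(unname(I["a", "b"]), 1)   # identical climates
  expect_equal(unname(I["a", "c"]), 0)   # dAVT = 6
  expect_equal(unname(I["a", "d"]), 1)   # boundary: dAVT = 5, dPCP = 500
  clim$avt[1] <- NA
  expect_error(climate_compatibility(clim), "missing")
})

test_that("import substitution solves the capacity-binding hand case", {
  # one partner, IM = 10, intensity gap 1, capacity 5 -> substitute 5
  p <- manual_problem(c("i", "j"),
                      IM = matrix(c(0, 10, 0, 0), 2, 2, byrow = TRUE),
                      EI = c(1, 2), EX0 = c(0, 10), AC = c(5, 100))
  out <- import_substitution(p, "i")
  expect_equal(out$reduction, 5)
  expect_equal(unname(out$ST["j"]), 5)
  # cleaner partners only: no beneficial substitution
  p2 <- manual_problem(c("i", "j"),
                       IM = matrix(c(0, 10, 0, 0), 2, 2, byrow = TRUE),
                       EI = c(3, 2), EX0 = c(0, 10), AC = c(5, 100))
  out2 <- import_substitution(p2, "i")
  expect_equal(out2$reduction, 0)
  # incompatible climate blocks the substitution entirely
  I0 <- matrix(c(1, 0, 0, 1), 2, 2)
  p3 <- manual_problem(c("i", "j"),
                       IM = matrix(c(0, 10, 0, 0), 2, 2, byrow = TRUE),
                       EI = c(1, 2), EX0 = c(0, 10), AC = c(5, 100), I = I0)
  expect_equal(import_substitution(p3, "i")$reduction, 0)
})

test_that("import substitution equals vertex enumeration on 3-region problems", {
  set.seed(55)
  for (rep in 1:8) {
    IM <- matrix(stats::runif(9, 0, 10), 3, 3)
    diag(IM) <- 0
    EI <- stats::runif(3, 0.5, 3)
    AC <- stats::runif(3, 1, 8)
    p <- manual_problem(c("x", "y", "z"), IM, EI, EX0 = rowSums(IM), AC = AC)
    out <- import_substitution(p, "x")
    # oracle: maximize gains subject to sum <= AC, 0 <= ST <= IM
    gain <- EI[2:3] - EI[1]
    oracle <- lp_enumerate(gain,
                           A = rbind(c(1, 1), diag(2)),
                           b = c(AC[1], IM[1, 2], IM[1, 3]),
                           dir = rep("<=", 3), maximize = TRUE)
    expect_lt(abs(out$reduction - max(oracle$value, 0)), 1e-7)
  }
})

test_that("export transfer solves the hand case and conserves total exports", {
  # all exports move to the clean producer with ample capacity
  p <- manual_problem(c("d", "c"),
                      IM = matrix(0, 2, 2),
                      EI = c(2, 1), EX0 = c(10, 0), AC = c(5, 15))
  out <- export_transfer(p)
  expect_equal(unname(out$EX_AF), c(0, 10), tolerance = 1e-9)
  expect_equal(out$reduction, 10, tolerance = 1e-9)
  expect_equal(sum(out$EX_AF), sum(p$EX0), tolerance = 1e-12)
  # equal intensities: nothing to gain
  peq <- manual_problem(c("d", "c"),
                        IM = matrix(0, 2, 2),
                        EI = c(1, 1), EX0 = c(10, 5), AC = c(5, 5))
  expect_equal(export_transfer(peq)$reduction, 0, tolerance = 1e-9)
})

test_that("export transfer equals vertex enumeration on 3-region problems", {
  set.seed(66)
  for (rep in 1:8) {
    EI <- stats::runif(3, 0.5, 3)
    EX0 <- stats::runif(3, 0, 10)
    AC <- stats::runif(3, 0, 10)
    I <- matrix(1, 3, 3)
    if (rep %% 2 == 0) { I[1, 3] <- I[3, 1] <- 0 }   # partial compatibility
    p <- manual_problem(c("x", "y", "z"), matrix(0, 3, 3), EI, EX0, AC, I)
    out <- export_transfer(p)
    # oracle: min EI'x s.t. x <= AC+EX0, I x >= EX0, 1'x = sum(EX0), x >= 0
    oracle <- lp_enumerate(EI,
                           A = rbind(diag(3), I, rep(1, 3)),
                           b = c(AC + EX0, EX0, sum(EX0)),
                           dir = c(rep("<=", 3), rep(">=", 3), "="),
                           maximize = FALSE)
    red_oracle <- sum(EX0 * EI) - oracle$value
    expect_lt(abs(out$reduction - red_oracle), 1e-7)
    expect_equal(sum(out$EX_AF), sum(EX0), tolerance = 1e-9)
    expect_true(all(out$EX_AF <= AC + EX0 + 1e-9))
    expect_true(all(as.numeric(p$I %*% out$EX_AF) >= EX0 - 1e-9))
  }
})

test_that("production-side rates apply to the right base at the stated percentages", {
  idx <- data.frame(region = rep(c("A", "B"), each = 3),
                    sector = rep(c("c1", "l1", "o1"), 2),
                    category = rep(c("crop", "livestock", "other"), 2))
  em <- manual_emissions(idx, X = rep(1, 6),
                         emissions = c(100, 100, 0, 50, 200, 0))
  expect_equal(production_side_reduction(em, "manure_moderate")$reduction,
               0.35 * 300)
  expect_equal(production_side_reduction(em, "manure_drastic")$reduction,
               0.70 * 300)
  expect_equal(production_side_reduction(em, "fertilizer_overuse")$reduction,
               0.14 * 150)
  expect_equal(production_side_reduction(em, "deep_placement")$reduction,
               0.55 * 150)
  expect_equal(production_side_reduction(em, "deep_placement",
                                         grain_share = 0.6)$reduction,
               0.55 * 0.6 * 150)
  expect_equal(production_side_reduction(em, "enhanced_efficiency")$reduction,
               0.54 * 150)
  # reductions never exceed the category base
  for (s in c("fertilizer_overuse", "deep_placement", "enhanced_efficiency",
              "manure_moderate", "manure_drastic")) {
    out <- production_side_reduction(em, s)
    expect_true(all(out$by_region >= 0))
    expect_lte(out$reduction, 300)
  }
  expect_error(production_side_reduction(em, "cold_fusion"), "unknown")
})

test_that("food-waste and beef scenarios match hand arithmetic and bounds", {
  idx <- data.frame(region = "A", sector = c("c1", "l1", "o1"),
                    category = c("crop", "livestock", "other"))
  em <- manual_emissions(idx, X = rep(1, 3), emissions = c(100, 200, 0))
  wr <- data.frame(region = "A", waste_crop = 0.3, waste_meat = 0.2)
  expect_equal(food_waste_reduction(em, wr)$reduction, 70)
  wr0 <- data.frame(region = "A", waste_crop = 0, waste_meat = 0)
  expect_equal(food_waste_reduction(em, wr0)$reduction, 0)
  wr1 <- data.frame(region = "A", waste_crop = 1, waste_meat = 1)
  expect_equal(food_waste_reduction(em, wr1)$reduction, 300)
  expect_error(food_waste_reduction(em, transform(wr, waste_crop = 1.2)),
               "\\[0, 1\\]")

  em100 <- manual_emissions(idx, X = rep(1, 3), emissions = c(40, 100, 0))
  expect_equal(beef_substitution_reduction(em100, 0.3, 0.2)$reduction, 6)
  expect_equal(beef_substitution_reduction(em100, 0.3, 0.5)$reduction,
               2.5 * beef_substitution_reduction(em100, 0.3, 0.2)$reduction)
  expect_equal(beef_substitution_reduction(em100, 0.3, 0)$reduction, 0)
  expect_error(beef_substitution_reduction(em100, 0.3, 1.5), "cut_fraction")
})

test_that("community scenario pipeline keeps reductions within baselines", {
  cfg <- small_config(seed = 44, n_regions = 4)
  w <- synthetic_world(cfg, ensemble_size = 2)
  acc <- mrio_accounts(w)
  membership <- stats::setNames(c(1, 1, 2, 2), nh3trade:::region_labels(cfg))
  tot <- emission_totals(w$emissions)
  for (com in 1:2) {
    prob <- trade_problem(w, acc, membership, com)
    et <- export_transfer(prob)
    base <- sum(prob$EX0 * prob$EI)
    expect_gte(et$reduction, 0)
    expect_lte(et$reduction, base + 1e-9)
    for (r in prob$members) {
      is <- import_substitution(prob, r)
      expect_gte(is$reduction, 0)
    }
  }
  fw <- food_waste_reduction(w$emissions,
                             data.frame(region = w$climate$region,
                                        waste_crop = w$climate$waste_crop,
                                        waste_meat = w$climate$waste_meat))
  expect_true(all(fw$by_region <= tot$crop + tot$livestock + 1e-9))
})

test_that("avoided deaths vanish without reduction and rise monotonically", {
  cfg <- small_config(seed = 47, n_regions = 2)
  w <- synthetic_world(cfg, ensemble_size = 2)
  tot <- emission_totals(w$emissions)
  base <- stats::setNames(tot$crop + tot$livestock, tot$region)
  zero <- scenario_health_benefit(w, stats::setNames(rep(0, 2), tot$region))
  expect_equal(zero$avoided_deaths, 0, tolerance = 1e-9)
  fracs <- c(0.1, 0.3, 0.5, 0.8, 1)
  avoided <- vapply(fracs, function(f)
    scenario_health_benefit(w, base * f)$avoided_deaths, numeric(1))
  expect_true(all(diff(avoided) > 0))
  expect_true(all(avoided >= 0))
  # removing all agricultural NH3 removes its entire mortality contribution
  g <- w$grids
  bg_only <- grid_field(matrix(cfg$background_pm25,
                               nrow(g$pm25_total$values),
                               ncol(g$pm25_total$values)),
                        g$pm25_total$lat, g$pm25_total$lon, name = "pm25")
  mort_bg <- attributable_mortality(bg_only, g$population, g$mask_fine,
                                    g$y0, ier_default_params())
  full <- scenario_health_benefit(w, base)
  expect_equal(full$scenario_deaths, mort_bg$total, tolerance = 1e-8)
})
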