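land_df <- function(...) {
  rows <- list(...)
  structure(do.call(rbind, lapply(rows, function(r)
    data.frame(food_id = r[[1]], commodity_id = r[[2]], land_type = r[[3]],
               lb_yr = NA_real_, acres_pc = as.numeric(r[[4]]),
               stringsAsFactors = FALSE))),
    class = c("land_result", "data.frame"))
}
avail_obj <- function(ci = 1, cult = 1, all_uses = 1, graz = 1)
  structure(list(cropping_intensity = ci, productive_cropland = NA,
                 proportion_cultivated = NA,
                 available_cultivated_food_cropland = cult,
                 available_grazing_land = graz,
                 available_food_cropland_all_uses = all_uses),
            class = "land_availability")

test_that("land availability evaluates the five printed formulas", {
  base <- data.frame(area_harvested_field_veg_other = 120,
                     total_area_cultivated = 100,
                     cropland_harvested = 100,
                     cropland_pasture_grazing = 20,
                     total_cultivated_harvested_excl_forage = 96,
                     nonfood_cropland = 5,
                     permanent_pasture = 80, woodland_grazed = 20)
  av <- land_availability(base)
  expect_equal(av$cropping_intensity, 1.2)
  expect_equal(av$productive_cropland, 120)
  expect_equal(av$proportion_cultivated, 0.8)
  expect_equal(av$available_cultivated_food_cropland, 120 * 0.8 / 1.2 - 5)
  expect_equal(av$available_grazing_land, 100)
  expect_equal(av$available_food_cropland_all_uses, 115)

  # pathological base: negative availability floored at 0 with a warning
  base$nonfood_cropland <- 1e6
  suppressWarnings(expect_warning(av2 <- land_availability(base), "floored"))
  expect_equal(av2$available_cultivated_food_cropland, 0)
  base$total_area_cultivated <- 0
  expect_error(suppressWarnings(land_availability(base)), "cropping intensity")
})

test_that("grazing reallocation follows the piecewise rule", {
  av <- avail_obj(ci = 1, all_uses = 50, graz = 100)   # RA = 2
  # RR = 30/20 = 1.5 <= RA: no reallocation
  land1 <- land_df(list("w", "wheat", "cultivated_cropland", 20),
                   list("b", "grazed_forage", "permanent_pasture", 30))
  g1 <- grazing_adjustment(land1, av, MINI)
  expect_equal(g1$RR, 1.5)
  expect_equal(g1$cropland_used_for_grazing, 0)
  expect_equal(g1$grazing_land_offset, 0)

  # RR = 120/20 = 6 > RA = 2, RY = 2000/4000 = 0.5:
  # cropland used for grazing = (120 - 2*20)/(2 + 0.5) = 32; offset = 16
  land2 <- land_df(list("w", "wheat", "cultivated_cropland", 20),
                   list("b", "grazed_forage", "permanent_pasture", 120))
  g2 <- grazing_adjustment(land2, av, MINI)
  expect_equal(g2$RY, 0.5)
  expect_equal(g2$cropland_used_for_grazing, 32)
  expect_equal(g2$grazing_land_offset, 16)

  # zero grazing demand: all zeros
  g3 <- grazing_adjustment(land_df(list("w", "wheat", "cultivated_cropland",
                                        20)), av, MINI)
  expect_equal(g3$cropland_used_for_grazing, 0)
  expect_equal(g3$RR, 0)

  # positive grazing with zero required cropland: RR undefined
  expect_error(grazing_adjustment(
    land_df(list("b", "grazed_forage", "permanent_pasture", 10)), av, MINI),
    "undefined")
})

test_that("forage mass balance holds under the mass-balance RY convention", {
  av <- avail_obj(ci = 1, all_uses = 50, graz = 100)
  land <- land_df(list("w", "wheat", "cultivated_cropland", 20),
                  list("b", "grazed_forage", "permanent_pasture", 120))
  g <- grazing_adjustment(land, av, MINI, convention = "mass_balance")
  # forage harvested from reallocated cropland replaces exactly the
  # forage forgone on the released pasture
  expect_equal(g$cropland_used_for_grazing * g$yield_p,
               g$grazing_land_offset * g$yield_g, tolerance = 1e-9)
})

test_that("population fed and carrying capacity", {
  # availabilities 90 / 120 / (120+80) against denominators 1 / 1 / 2
  av <- avail_obj(ci = 1, cult = 90, all_uses = 120, graz = 80)
  land <- land_df(list("w", "wheat", "cultivated_cropland", 1),
                  list("b", "grazed_forage", "permanent_pasture", 1))
  adj <- structure(list(cropland_used_for_grazing = 0,
                        grazing_land_offset = 0),
                   class = "grazing_adjustment")
  pf <- population_fed(land, av, adj, 200)
  expect_equal(unname(pf$population_fed),
               c(90 / 1, 120 / 1, (120 + 80) / 2))
  expect_equal(pf$carrying_capacity, 90 / 200)
  expect_equal(pf$carrying_capacity,
               min(pf$population_fed) / 200)  # the defining invariant

  # zero per-capita requirement reports unbounded
  pf0 <- population_fed(land_df(list("w", "wheat", "cultivated_cropland", 0)),
                        av, adj, 200)
  expect_true(all(is.infinite(pf0$population_fed)))
})

test_that("total land use reduces to the plain sum without reallocation", {
  land <- land_df(list("w", "wheat", "cultivated_cropland", 0.12),
                  list("h", "hay", "cropland_pasture", 0.05),
                  list("b", "grazed_forage", "permanent_pasture", 0.4))
  adj0 <- structure(list(cropland_used_for_grazing = 0,
                         grazing_land_offset = 0),
                    class = "grazing_adjustment")
  lu <- total_land_use(land, adj0, 1.2, 1000)
  expect_equal(lu$per_capita_acres, 0.12 / 1.2 + 0.05 + 0.4)
  expect_equal(lu$total_acres, lu$per_capita_acres * 1000)
  # population doubled, per-capita inputs fixed: total doubles
  expect_equal(total_land_use(land, adj0, 1.2, 2000)$total_acres,
               2 * lu$total_acres)
  # reallocation moves 32 acres onto cropland and releases 16 of pasture
  adj <- structure(list(cropland_used_for_grazing = 32,
                        grazing_land_offset = 16),
                   class = "grazing_adjustment")
  lu2 <- total_land_use(land, adj, 1.2, 1)
  expect_equal(lu2$cropland, 0.05 + 32)
  expect_equal(lu2$grazing, max(0, 0.4 - 16))
})

test_that("amendment totals are the brute-force food x rate sum", {
  land <- land_df(list("a", "wheat", "cultivated_cropland", 2),
                  list("b", "lettuce", "cultivated_cropland", 3))
  p <- suppressMessages(make_mini_food_system())
  p$amendments <- data.frame(commodity_id = c("wheat", "lettuce"),
                             amendment = c("N", "N"), rate = c(10, 0))
  am <- suppressWarnings(amendment_use(land, p, population = 7))
  expect_equal(am$per_capita[["N"]], 20)
  expect_equal(am$total[["N"]], 140)
  expect_equal(sum(am$per_capita[names(am$per_capita) != "N"]), 0)
  # zero land gives zero amendments
  am0 <- amendment_use(land_df(list("a", "wheat", "cultivated_cropland", 0)),
                       p)
  expect_equal(unname(am0$per_capita), rep(0, 6))
  # uncovered commodity warns and contributes zero
  expect_warning(
    amendment_use(land_df(list("z", "quinoa", "cultivated_cropland", 1)), p),
    "quinoa")
  # MINI totals against the brute-force oracle grid
  res <- run_mini()
  o <- mini_oracle()
  expect_equal(res$amendments$per_capita[amendment_classes],
               o$output$amendments[amendment_classes], tolerance = 1e-9)
})

test_that("nutrient summary is the linear servings x composition sum", {
  d <- food_group_vector(c(grains = 2), groups = MINI_GROUPS)
  ns <- nutrient_summary(d, MINI)
  expect_equal(ns[["energy_kcal"]], 160)  # 2 servings x 80 kcal
  expect_equal(unname(nutrient_summary(
    food_group_vector(groups = MINI_GROUPS), MINI)),
    rep(0, 4))
  # missing composition: warn and skip
  p <- suppressMessages(make_mini_food_system())
  p$nutrients <- p$nutrients[p$nutrients$food_id != "bread", ]
  expect_warning(ns2 <- nutrient_summary(d, p), "bread")
  expect_equal(ns2[["energy_kcal"]], 0)
})
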