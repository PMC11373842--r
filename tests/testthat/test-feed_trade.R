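test_that("aquaculture 2x2 nutritional solve", {
  nut <- data.frame(feed_commodity_id = c("corn_grain", "soybean_meal"),
                    energy = c(1.6, 1.5), protein = c(0.09, 0.48))
  # requirements E = 3.1, P = 0.57 per edible lb solve to corn 1, soymeal 1
  sp <- data.frame(species_id = "salmon", farmed_share = 0.6, fcr = 1,
                   processing_efficiency = 0.5, ration_energy = 1.55,
                   ration_protein = 0.285)
  req <- aquaculture_requirements(sp, nut)
  expect_equal(req$energy_required, 3.1, tolerance = 1e-12)
  expect_equal(req$protein_required, 0.57, tolerance = 1e-12)
  expect_equal(req$corn_lb, 1, tolerance = 1e-9)
  expect_equal(req$soymeal_lb, 1, tolerance = 1e-9)
  # the blend meets both constraints exactly
  expect_equal(req$corn_lb * 1.6 + req$soymeal_lb * 1.5,
               req$energy_required, tolerance = 1e-9)
  expect_equal(req$corn_lb * 0.09 + req$soymeal_lb * 0.48,
               req$protein_required, tolerance = 1e-9)

  # strict-paper (multiplicative) mode scales requirements by efficiency^2
  req2 <- aquaculture_requirements(sp, nut, strict_paper = TRUE)
  expect_equal(req2$corn_lb, 0.25, tolerance = 1e-9)
  expect_equal(req2$soymeal_lb, 0.25, tolerance = 1e-9)

  # ration proportional to corn alone: soymeal exactly 0
  sp3 <- sp; sp3$ration_energy <- 0.8; sp3$ration_protein <- 0.045
  req3 <- aquaculture_requirements(sp3, nut)
  expect_equal(req3$soymeal_lb, 0, tolerance = 1e-9)
  expect_equal(req3$corn_lb, req3$energy_required / 1.6, tolerance = 1e-9)

  # infeasible exact blend clips to a nonnegative ration with a warning
  sp4 <- sp; sp4$ration_energy <- 2; sp4$ration_protein <- 0.01
  expect_warning(req4 <- aquaculture_requirements(sp4, nut), "infeasible")
  expect_true(req4$corn_lb >= 0 && req4$soymeal_lb >= 0)
  expect_true(req4$corn_lb * 1.6 + req4$soymeal_lb * 1.5 >=
                req4$energy_required - 1e-9)

  # singular nutrient matrix is fatal
  nut_sing <- data.frame(feed_commodity_id = c("corn_grain", "soybean_meal"),
                         energy = c(1.6, 3.2), protein = c(0.09, 0.18))
  expect_error(aquaculture_requirements(sp, nut_sing), "singular")
  expect_error(aquaculture_requirements(
    transform(sp, processing_efficiency = 0), nut), "processing_efficiency")
})

test_that("livestock feed demand scales linearly from coefficients", {
  dem <- structure(data.frame(
    food_id = "beef", food_group = "beef", commodity_id = "beef",
    kind = "animal", agricultural = TRUE, lb_yr = 50,
    stringsAsFactors = FALSE), class = c("commodity_demand", "data.frame"))
  p <- suppressMessages(make_mini_food_system())
  p$feed <- data.frame(animal_product_id = c("beef", "beef"),
                       feed_commodity_id = c("grazed_forage", "corn_grain"),
                       lb_feed_per_lb_product = c(6, 2))
  feed <- livestock_feed_demand(dem, p)
  expect_equal(feed$lb_yr[feed$feed_commodity_id == "grazed_forage"], 300)
  expect_equal(feed$lb_yr[feed$feed_commodity_id == "corn_grain"], 100)

  # missing coefficient is fatal; zero demand yields no feed rows
  dem$commodity_id <- "goat"
  expect_error(livestock_feed_demand(dem, p), "goat")
  dem$commodity_id <- "beef"; dem$lb_yr <- 0
  expect_equal(nrow(livestock_feed_demand(dem, p)), 0)
})

test_that("MINI feed totals equal a hand multiplication table", {
  dem <- food_requirements(MINI_DIET, MINI)
  feed <- livestock_feed_demand(dem, MINI)
  o <- mini_oracle()
  agg <- tapply(feed$lb_yr, feed$feed_commodity_id, sum)
  expect_equal(agg[["corn_grain"]], o$feed$corn, tolerance = 1e-9)
  expect_equal(agg[["soybean_meal"]], o$feed$soymeal, tolerance = 1e-9)
  expect_equal(agg[["hay"]], o$feed$hay, tolerance = 1e-9)
  expect_equal(agg[["grazed_forage"]], o$feed$forage, tolerance = 1e-9)
})

test_that("trade balances follow the narrative sign convention", {
  tr <- data.frame(food_id = c("a", "b", "c"),
                   beginning_stock = c(0, 10, 0),
                   imports = c(0, 5, 0),
                   exports = c(0, 8, 20))
  tb <- trade_balance(tr, mode = "open")
  expect_equal(tb$balance, c(0, 7, -20))
  # printed-equation mode adds exports instead
  expect_equal(trade_balance(tr, mode = "open", sign = "printed")$balance,
               c(0, 23, 20))
  # closed mode zeroes everything
  expect_equal(trade_balance(tr, mode = "closed")$balance, c(0, 0, 0))
})

test_that("an export-only food needs more land than without trade", {
  p <- suppressMessages(make_mini_food_system())
  pop <- 1000
  p$trade <- data.frame(food_id = "bread", beginning_stock = 0,
                        imports = 0, exports = 20 * pop)
  d <- food_group_vector(c(grains = 2), groups = MINI_GROUPS)
  closed <- suppressWarnings(run_single(d, p, scenario_config(
    population_size = pop, trade_mode = "closed")))
  open <- suppressWarnings(run_single(d, p, scenario_config(
    population_size = pop, trade_mode = "open")))
  wheat_land <- function(r) sum(r$land$acres_pc[r$land$commodity_id == "wheat"])
  expect_equal(wheat_land(open), wheat_land(closed) + 20 / 2700,
               tolerance = 1e-9)
})
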