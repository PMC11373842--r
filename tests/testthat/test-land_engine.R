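# bare commodity-demand builder for ledger unit tests
demand_rows <- function(...) {
  rows <- list(...)
  structure(do.call(rbind, lapply(rows, function(r)
    data.frame(food_id = r[[1]], food_group = r[[2]], commodity_id = r[[3]],
               kind = r[[4]], agricultural = TRUE,
               lb_yr = as.numeric(r[[5]]), stringsAsFactors = FALSE))),
    class = c("commodity_demand", "data.frame"))
}
empty_feed <- data.frame(food_id = character(0),
                         animal_product_id = character(0),
                         feed_commodity_id = character(0),
                         lb_yr = numeric(0))

test_that("corn oil spared is the lower of consumed and coproduced", {
  # sweetener corn 200 lb coproduces 8 lb corn oil; 5 lb consumed -> 5 spared
  dem <- demand_rows(
    list("hfcs", "sweeteners", "corn_grain", "sweetener", 200),
    list("cooking_oil", "plant_oils", "corn_oil", "oil", 5))
  adj <- multiuse_adjustment(dem, empty_feed, MINI)
  expect_equal(adj$corn_oil_coproduced, 8)
  expect_equal(adj$corn_oil_spared, 5)
  expect_equal(adj$corn_spared, 5 * 25)
  expect_equal(adj$corn_oil_surplus, 3)

  # consumed above coproduced: spared capped at coproduction
  dem2 <- demand_rows(
    list("hfcs", "sweeteners", "corn_grain", "sweetener", 100),
    list("cooking_oil", "plant_oils", "corn_oil", "oil", 9))
  adj2 <- multiuse_adjustment(dem2, empty_feed, MINI)
  expect_equal(adj2$corn_oil_spared, 4)
})

test_that("degenerate inputs produce an all-zero ledger", {
  dem <- demand_rows(list("bread", "grains", "wheat", "crop", 77.1))
  adj <- multiuse_adjustment(dem, empty_feed, MINI)
  for (f in c("corn_spared", "soybean_spared", "corn_oil_coproduced",
              "lard_tallow_coproduced", "lard_tallow_remaining"))
    expect_equal(adj[[f]], 0, label = f)
  expect_equal(sum(adj$oilseed_spared), 0)
})

test_that("MINI ledger matches the step-by-step hand computation", {
  dem <- food_requirements(MINI_DIET, MINI)
  feed <- livestock_feed_demand(dem, MINI)
  adj <- multiuse_adjustment(dem, feed, MINI)
  o <- mini_oracle()$ledger
  expect_equal(adj$corn_oil_coproduced, o$corn_oil_coproduced, tolerance = 1e-9)
  expect_equal(adj$gluten_protein_coproduced, o$gluten_protein, tolerance = 1e-9)
  expect_equal(adj$lard_tallow_coproduced, o$lard_tallow_coproduced,
               tolerance = 1e-9)
  expect_equal(adj$corn_oil_spared, o$corn_oil_spared, tolerance = 1e-9)
  expect_equal(adj$corn_spared, o$corn_spared, tolerance = 1e-9)
  expect_equal(adj$lard_tallow_remaining, o$lard_tallow_remaining,
               tolerance = 1e-9)
  expect_equal(adj$lard_tallow_surplus, o$lard_tallow_surplus,
               tolerance = 1e-9)
  expect_equal(unname(adj$oilseed_spared["soybeans"]), o$oilseed_spared,
               tolerance = 1e-9)
  expect_equal(adj$crush_feed_protein_coproduced, o$crush_protein,
               tolerance = 1e-9)
  expect_equal(adj$soybean_spared, o$soybean_spared, tolerance = 1e-9)
  # every spared quantity is nonnegative, spared oil within both caps
  expect_true(adj$corn_spared >= 0 && adj$soybean_spared >= 0)
  expect_lte(adj$corn_oil_spared,
             min(adj$corn_oil_consumed, adj$corn_oil_coproduced) + 1e-12)
})

test_that("required land divides net commodity mass by primary yield", {
  dem <- demand_rows(list("bread", "grains", "wheat", "crop", 77.1))
  land <- required_land(dem, empty_feed, NULL, 1000, NULL, MINI)
  expect_equal(land$acres_pc, 77.1 / 2700, tolerance = 1e-12)
  expect_equal(round(land$acres_pc, 5), 0.02856)
  expect_equal(land$land_type, "cultivated_cropland")

  # trade balance equal to total demand zeroes the land exactly
  tb <- data.frame(food_id = "bread", balance = 77.1 * 1000)
  land0 <- required_land(dem, empty_feed, tb, 1000, NULL, MINI)
  expect_equal(land0$acres_pc, 0)

  # a trade surplus beyond demand cannot go negative
  tb$balance <- 2 * 77.1 * 1000
  expect_gte(min(required_land(dem, empty_feed, tb, 1000, NULL,
                               MINI)$acres_pc), 0)

  # missing yield for demanded commodity is fatal, not silently dropped
  dem2 <- demand_rows(list("x", "grains", "quinoa", "crop", 10))
  expect_error(required_land(dem2, empty_feed, NULL, 1000, NULL, MINI),
               "quinoa")
})

test_that("multiuse adjustment never increases any commodity's land", {
  dem <- food_requirements(MINI_DIET, MINI)
  feed <- livestock_feed_demand(dem, MINI)
  adj <- multiuse_adjustment(dem, feed, MINI)
  with_adj <- required_land(dem, feed, NULL, 1e5, adj, MINI)
  without <- required_land(dem, feed, NULL, 1e5, NULL, MINI)
  a <- tapply(with_adj$acres_pc, with_adj$commodity_id, sum)
  b <- tapply(without$acres_pc, without$commodity_id, sum)
  expect_true(all(a[names(b)] <= b + 1e-12))
  expect_lt(sum(with_adj$acres_pc), sum(without$acres_pc))
})
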