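test_that("preference reapportionment: proportional renormalization", {
  gf <- data.frame(food_group = "g", food_id = c("A", "B", "C"),
                   producible = c(TRUE, TRUE, FALSE),
                   preference_share = c(0.6, 0.3, 0.1))
  out <- reapportion_preferences(gf)
  expect_equal(out$preference_share, c(2 / 3, 1 / 3, 0))

  # all producible: identity
  gf$producible <- TRUE
  expect_equal(reapportion_preferences(gf)$preference_share, gf$preference_share)

  # single producible food absorbs the whole group
  gf$producible <- c(FALSE, FALSE, TRUE)
  gf$preference_share <- c(0.5, 0.3, 0.2)
  expect_equal(reapportion_preferences(gf)$preference_share, c(0, 0, 1))

  # no producible food: fatal
  gf$producible <- FALSE
  expect_error(reapportion_preferences(gf), "no producible")
})

test_that("fluid-milk equivalent: identity, limiting fraction, degenerate", {
  comp <- data.frame(food_id = c("fluid_milk", "cheese"),
                     fat_solids = c(0.037, 0.30),
                     nonfat_solids = c(0.086, 0.25))
  # a pure fluid-milk diet maps to itself: FM = intake
  fm <- fluid_milk_equivalent(c(fluid_milk = 100), comp)
  expect_equal(fm$fm_fat, 100)
  expect_equal(fm$fm_nonfat, 100)
  expect_equal(fm$fm, 100)

  # cheese: fat-limited (hand arithmetic of the two equations)
  fm <- fluid_milk_equivalent(c(cheese = 10), comp)
  expect_equal(fm$fm_fat, 10 * 0.30 / 0.037, tolerance = 1e-12)
  expect_equal(fm$fm_fat, 81.081, tolerance = 1e-4)
  expect_equal(fm$fm_nonfat, 10 * 0.25 / 0.086, tolerance = 1e-12)
  expect_equal(fm$fm_nonfat, 29.070, tolerance = 1e-4)
  expect_equal(fm$fm, fm$fm_fat)
  expect_equal(fm$limiting, "fat")

  # FM is the max of the two components, and per-food parts sum to it
  fm <- fluid_milk_equivalent(c(fluid_milk = 50, cheese = 10), comp)
  expect_equal(fm$fm, max(fm$fm_fat, fm$fm_nonfat))
  expect_equal(sum(fm$per_food_fm), fm$fm)

  expect_equal(fluid_milk_equivalent(numeric(0), comp)$fm, 0)
  expect_error(fluid_milk_equivalent(c(butter = 1), comp),
               "missing dairy composition")
})

test_that("the mass equation converts bread to 77.10 lb wheat", {
  d <- food_group_vector(c(grains = 2), groups = MINI_GROUPS)
  dem <- food_requirements(d, MINI)
  wheat <- dem$lb_yr[dem$commodity_id == "wheat"]
  expect_equal(wheat, 2 * 28 / 454 * 1.25 * 1.37 * 365, tolerance = 1e-12)
  expect_equal(wheat, 77.10, tolerance = 1e-4)
})

test_that("zero diet gives all-zero demand; uncovered groups error", {
  d <- food_group_vector(groups = MINI_GROUPS)
  dem <- food_requirements(d, MINI)
  expect_true(all(dem$lb_yr == 0))
  # positive intake in a group with no producible food
  p <- suppressMessages(make_mini_food_system())
  d2 <- food_group_vector(c(pork = 1), groups = c(MINI_GROUPS, "pork"))
  expect_error(food_requirements(d2, p), "no producible")
})

test_that("demand is linear and monotone in the diet", {
  base <- food_requirements(MINI_DIET, MINI)
  agg <- function(dem) {
    s <- tapply(dem$lb_yr, dem$commodity_id, sum)
    stats::setNames(as.numeric(s), names(s))
  }
  b <- agg(base)
  # linearity under scaling
  for (alpha in c(0.25, 2, 7)) {
    sc <- agg(food_requirements(MINI_DIET * alpha, MINI))
    expect_equal(sc[names(b)], b * alpha, tolerance = 1e-12)
  }
  # monotonicity: bump each group, no commodity demand decreases
  for (g in MINI_GROUPS) {
    d2 <- unclass(MINI_DIET); d2[g] <- d2[g] + 1
    up <- agg(food_requirements(
      food_group_vector(d2, groups = MINI_GROUPS), MINI))
    expect_true(all(up[names(b)] >= b - 1e-12), label = g)
  }
})

test_that("fat/oil decomposition conserves mass", {
  shares <- data.frame(product_id = "shortening",
                       oil_id = c("soybean_oil", "palm_oil"),
                       share = c(0.7, 0.3))
  oils <- decompose_fats_oils(c(shortening = 10), shares)
  expect_equal(oils[["soybean_oil"]], 7)
  expect_equal(oils[["palm_oil"]], 3)
  expect_equal(sum(oils), 10)
  expect_length(decompose_fats_oils(c(shortening = 0), shares), 0)
  expect_error(decompose_fats_oils(c(margarine = 1), shares),
               "no oil shares")
  # MINI blend conserves mass through food_requirements
  dem <- food_requirements(MINI_DIET, MINI)
  oil_rows <- dem[dem$kind == "oil", ]
  expect_equal(sum(oil_rows$lb_yr), sum(attr(dem, "product_lb")),
               tolerance = 1e-9)
})

test_that("aquatic demand splits into farmed and wild fractions", {
  dem <- food_requirements(MINI_DIET, MINI)
  farmed <- dem$lb_yr[dem$kind == "aquaculture"]
  wild <- dem$lb_yr[dem$kind == "wild_aquatic"]
  expect_equal(farmed / (farmed + wild), 0.6, tolerance = 1e-12)
  expect_false(any(dem$agricultural[dem$kind == "wild_aquatic"]))
  # toggling aquatic food off sends everything to the wild fraction
  dem0 <- food_requirements(MINI_DIET, MINI, include_aquatic = FALSE)
  expect_equal(sum(dem0$lb_yr[dem0$kind == "aquaculture"]), 0)
  expect_equal(sum(dem0$lb_yr[dem0$kind == "wild_aquatic"]), farmed + wild)
})
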