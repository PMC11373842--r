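#' The MINI toy food system
#'
#' A deterministic ~13-food parameter set that exercises every mechanism
#' of the model with numbers chosen for hand arithmetic: a grain (bread /
#' wheat at the 2700 lb/acre yield), a vegetable group with a
#' non-producible member (preference reapportionment), fruit, fluid milk
#' plus cheese (limiting dairy fraction), beef (grazing + feed + tallow
#' coproduct), chicken, farmed salmon with a wild share (the aquaculture
#' 2x2 solve lands exactly on 1 lb corn + 1 lb soybean meal per edible
#' lb), a cooking-oil blend of soybean and corn oil, a corn sweetener
#' (wet-milling coproducts), and lard (coproduct ledger). Grazing yields
#' are 2000 lb/acre on pasture and 4000 lb/acre on cropland, so the
#' printed yield ratio RY is exactly 0.5.
#'
#' @return a validated `food_system_parameters` object (identical on
#'   every call).
#' @export
make_mini_food_system <- function() {
  groups <- data.frame(
    food_group = c("grains", "other_vegetables", "fruit",
                   "fluid_milk_yogurt", "cheese_other_dairy", "beef",
                   "chicken", "aquatic_food", "plant_oils", "sweeteners",
                   "lard_tallow"),
    serving_unit = c("oz_eq", "cup_eq", "cup_eq", "cup_eq", "cup_eq",
                     "oz_eq", "oz_eq", "oz_eq", "tsp", "tsp", "tsp"),
    stringsAsFactors = FALSE)

  foods <- data.frame(
    food_id = c("bread", "lettuce", "carrot", "import_veg", "apple",
                "fluid_milk", "cheese", "beef", "chicken", "salmon",
                "cooking_oil", "hfcs", "lard"),
    food_group = c("grains", "other_vegetables", "other_vegetables",
                   "other_vegetables", "fruit", "fluid_milk_yogurt",
                   "cheese_other_dairy", "beef", "chicken", "aquatic_food",
                   "plant_oils", "sweeteners", "lard_tallow"),
    category = c("grains", "vegetables", "vegetables", "vegetables",
                 "fruit", "dairy", "dairy", "meat", "meat", "aquatic",
                 "fats_oils", "sweeteners", "fats_oils"),
    serving_size = c(28, 113.5, 113.5, 113.5, 113.5, 244, 45.4, 113.5,
                     113.5, 113.5, 4.54, 4.54, 4.54),
    producible = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, TRUE),
    preference_share = c(1, 0.6, 0.3, 0.1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    loss_waste_factor = c(1.25, 1.2, 1.25, 1, 1.4, 1.1, 1.1, 1.4, 1.3,
                          1.2, 1.1, 1.05, 1.1),
    processing_conversion = c(1.37, 1, 1, 1, 1, 1, 1, 1.5, 1.4, 1, 1, 2, 1),
    commodity_id = c("wheat", "lettuce", "carrot", "import_veg", "apple",
                     "milk", "milk", "beef", "chicken", "salmon",
                     "cooking_oil", "corn_grain", "lard_tallow"),
    stringsAsFactors = FALSE)

  dairy <- data.frame(
    food_id = c("fluid_milk", "cheese"),
    fat_solids = c(0.037, 0.30),
    nonfat_solids = c(0.086, 0.25),
    stringsAsFactors = FALSE)

  fats_oils <- data.frame(
    product_id = c("cooking_oil", "cooking_oil"),
    oil_id = c("soybean_oil", "corn_oil"),
    share = c(0.6, 0.4),
    stringsAsFactors = FALSE)

  oil_crops <- data.frame(
    oil_id = c("soybean_oil", "corn_oil"),
    commodity_id = c("soybeans", "corn_grain"),
    meal_commodity_id = c("soybean_meal", NA),
    seed_per_oil = c(5, 25),
    meal_yield = c(0.8, 0),
    meal_protein = c(0.5, 0),
    stringsAsFactors = FALSE)

  feed <- data.frame(
    animal_product_id = c("beef", "beef", "beef", "chicken", "chicken",
                          "milk", "milk", "milk"),
    feed_commodity_id = c("grazed_forage", "corn_grain", "hay",
                          "corn_grain", "soybean_meal", "corn_grain",
                          "hay", "grazed_forage"),
    lb_feed_per_lb_product = c(6, 2, 1, 2, 1, 0.1, 0.2, 0.3),
    stringsAsFactors = FALSE)

  animal_fats <- data.frame(
    animal_product_id = "beef", lb_fat_per_lb_product = 0.05,
    stringsAsFactors = FALSE)

  aquaculture <- data.frame(
    species_id = "salmon", farmed_share = 0.6, fcr = 1,
    processing_efficiency = 0.5, ration_energy = 1.55,
    ration_protein = 0.285, stringsAsFactors = FALSE)

  feed_nutrients <- data.frame(
    feed_commodity_id = c("corn_grain", "soybean_meal"),
    energy = c(1.6, 1.5), protein = c(0.09, 0.48),
    stringsAsFactors = FALSE)

  trade <- data.frame(
    food_id = c("bread", "apple"),
    beginning_stock = c(0, 0), imports = c(0, 0), exports = c(0, 0),
    stringsAsFactors = FALSE)

  yields <- data.frame(
    commodity_id = c("wheat", "lettuce", "carrot", "apple", "corn_grain",
                     "soybeans", "hay", "grazed_forage", "grazed_forage"),
    land_type = c(rep("cultivated_cropland", 6), "cropland_pasture",
                  "permanent_pasture", "cropland_pasture"),
    yield = c(2700, 30000, 30000, 20000, 10000, 3000, 5000, 2000, 4000),
    primary = c(rep(TRUE, 8), FALSE),
    stringsAsFactors = FALSE)

  amendments <- do.call(rbind, lapply(
    list(
      list("wheat",      c(60, 25, 20, 5, 1, 0.2)),
      list("corn_grain", c(120, 50, 60, 10, 2, 0.5)),
      list("soybeans",   c(10, 20, 30, 5, 1.5, 0.3)),
      list("lettuce",    c(100, 40, 50, 5, 3, 1.5)),
      list("carrot",     c(80, 30, 40, 5, 2, 1)),
      list("apple",      c(50, 20, 40, 5, 4, 1.2)),
      list("hay",        c(30, 15, 25, 3, 0.3, 0.1))),
    function(x) data.frame(commodity_id = x[[1]],
                           amendment = amendment_classes,
                           rate = x[[2]], stringsAsFactors = FALSE)))

  land_base <- data.frame(
    area_harvested_field_veg_other = 60000,
    total_area_cultivated = 50000,
    cropland_harvested = 50000,
    cropland_pasture_grazing = 10000,
    total_cultivated_harvested_excl_forage = 48000,
    nonfood_cropland = 2000,
    permanent_pasture = 200000,
    woodland_grazed = 40000,
    stringsAsFactors = FALSE)

  nutrients <- data.frame(
    food_id = foods$food_id,
    energy_kcal = c(80, 10, 25, 20, 60, 103, 45, 180, 140, 130, 40, 16, 37),
    protein_g = c(3, 1, 1, 1, 0, 8, 3, 22, 26, 22, 0, 0, 0),
    fat_g = c(1, 0, 0, 0, 0, 2.4, 3.5, 10, 3, 4, 4.5, 0, 4.1),
    carbohydrate_g = c(15, 2, 6, 4, 15, 12, 0.5, 0, 0, 0, 0, 4, 0),
    stringsAsFactors = FALSE)

  system <- data.frame(
    corn_commodity_id = "corn_grain",
    soymeal_commodity_id = "soybean_meal",
    corn_oil_per_lb_corn = 0.04,
    gluten_feed_per_lb_corn = 0.25,
    gluten_feed_protein = 0.2,
    milk_commodity_id = "milk",
    milk_processing_conversion = 1,
    lard_commodity_id = "lard_tallow",
    stringsAsFactors = FALSE)

  suppressMessages(food_system_parameters(
    groups, foods, dairy, fats_oils, oil_crops, feed, animal_fats,
    aquaculture, feed_nutrients, trade, yields, amendments, land_base,
    nutrients, system))
}

#' Reference per-capita diet for the MINI system
#'
#' The documented diet against which the hand-computed oracle worksheet
#' (see the package tests and methods vignette) is evaluated.
#'
#' @return a `food_group_vector` over the MINI groups.
#' @export
mini_reference_diet <- function() {
  food_group_vector(
    c(grains = 2, other_vegetables = 1.5, fruit = 1,
      fluid_milk_yogurt = 1.5, cheese_other_dairy = 1, beef = 0.5,
      chicken = 0.6, aquatic_food = 0.2, plant_oils = 2, sweeteners = 5,
      lard_tallow = 0.5),
    groups = make_mini_food_system()$groups$food_group)
}

# run expr under a temporary integer seed, restoring RNG state afterwards
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for a synthetic diet survey
#'
#' Individual-level one-day recalls are emulated as zero-inflated
#' log-normal draws per food group — dietary intake data are typically
#' right-skewed, and many respondents report zero intake of a given group
#' on any one day. A small fraction of extreme beef consumers is included
#' so that individual diets can trigger the grazing-land reallocation
#' (RR > RA) that the population-mean diet does not.
#'
#' @param seed integer seed.
#' @param n number of respondents.
#' @param mean_servings named numeric: target mean servings/day per group
#'   (defaults to the MINI reference diet).
#' @param sdlog log-scale SD of the log-normal component (default 0.5).
#' @param zero_prevalence named numeric in \[0, 1\]: probability of zero
#'   intake per group.
#' @param extreme_fraction fraction of respondents drawn as extreme beef
#'   consumers (default 0.05).
#' @param extreme_beef_servings beef servings/day assigned to extreme
#'   consumers (default 5, about 1.25 lb cooked beef per day).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n = 100,
                         mean_servings = NULL, sdlog = 0.5,
                         zero_prevalence = NULL,
                         extreme_fraction = 0.05,
                         extreme_beef_servings = 5) {
  if (is.null(mean_servings)) {
    d <- mini_reference_diet()
    mean_servings <- stats::setNames(as.numeric(d), names(d))
  }
  if (is.null(zero_prevalence)) {
    zero_prevalence <- stats::setNames(
      rep(0.2, length(mean_servings)), names(mean_servings))
    zero_prevalence[intersect(c("aquatic_food", "lard_tallow"),
                              names(zero_prevalence))] <- 0.7
    zero_prevalence[intersect(c("grains", "sweeteners"),
                              names(zero_prevalence))] <- 0.05
  }
  stopifnot(n >= 1, all(is.finite(mean_servings)), all(mean_servings >= 0),
            all(zero_prevalence >= 0 & zero_prevalence <= 1),
            extreme_fraction >= 0, extreme_fraction <= 1)
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 mean_servings = mean_servings, sdlog = sdlog,
                 zero_prevalence = zero_prevalence,
                 extreme_fraction = extreme_fraction,
                 extreme_beef_servings = extreme_beef_servings),
            class = "fixture_spec")
}

#' Generate a seeded synthetic diet survey
#'
#' Draws `n` respondents per [fixture_spec()]: per-group intake is zero
#' with the stated prevalence and otherwise log-normal with the stated
#' mean (the log-normal meanlog is set so the nonzero-component mean times
#' the nonzero probability equals the target group mean). Ages are uniform
#' on 1–85, survey weights log-normal around 1, and recalls reliable;
#' records engineered to trigger specific exclusion rules are the tests'
#' business, built by perturbing the returned frame.
#'
#' @param spec a `fixture_spec` (or arguments forwarded to one).
#' @param ... forwarded to [fixture_spec()] when `spec` is missing.
#' @return a `diet_survey` data.frame of `spec$n` records; identical on
#'   repeated calls with the same spec; leaves the caller's RNG state
#'   untouched.
#' @export
make_synthetic_survey <- function(spec = fixture_spec(...), ...) {
  stopifnot(inherits(spec, "fixture_spec"))
  gr <- names(spec$mean_servings)
  .with_seed(spec$seed, {
    n <- spec$n
    out <- data.frame(
      participant_id = sprintf("P%05d", seq_len(n)),
      age_years = floor(stats::runif(n, 1, 86)),
      survey_weight = stats::rlnorm(n, 0, 0.5),
      recall_reliable = TRUE,
      stringsAsFactors = FALSE)
    for (g in gr) {
      mu <- spec$mean_servings[[g]]
      p0 <- spec$zero_prevalence[[g]]
      x <- numeric(n)
      nz <- stats::runif(n) >= p0
      if (mu > 0 && any(nz)) {
        # mean of lognormal component = mu / (1 - p0) so E[x] = mu
        target <- mu / max(1 - p0, 1e-12)
        meanlog <- log(target) - spec$sdlog^2 / 2
        x[nz] <- stats::rlnorm(sum(nz), meanlog, spec$sdlog)
      }
      out[[g]] <- x
    }
    if (spec$extreme_fraction > 0 && "beef" %in% gr) {
      k <- max(1, round(spec$extreme_fraction * n))
      idx <- sample.int(n, k)
      out$beef[idx] <- spec$extreme_beef_servings
    }
    structure(out, groups = gr, class = c("diet_survey", "data.frame"))
  })
}
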