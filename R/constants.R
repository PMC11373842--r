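#' Canonical 22 food groups
#'
#' The diet input is expressed as daily servings of 22 food groups. Serving
#' units differ by group (cup-equivalents for vegetables, fruit and dairy,
#' ounce-equivalents for grains and protein foods, teaspoons for oils, fats
#' and sweeteners); per-food serving sizes in the parameter set encode grams
#' per that unit so downstream mass conversion is uniform.
#'
#' Any parameter set may define its own (sub)set of groups; this constant is
#' the national-survey default schema.
#'
#' @format Character vector of 22 group codes.
#' @export
food_groups_22 <- c(
  "grains", "dark_green_vegetables", "red_orange_vegetables",
  "dry_beans_lentils_peas", "starchy_vegetables", "other_vegetables",
  "fruit", "fluid_milk_yogurt", "cheese_other_dairy", "soy_milk",
  "nuts", "tofu", "beef", "pork", "chicken", "turkey", "eggs",
  "aquatic_food", "plant_oils", "dairy_fats", "lard_tallow", "sweeteners"
)

#' Amendment classes tracked by the model
#' @format Character vector: four fertilizer nutrients, pesticides,
#'   irrigation water.
#' @export
amendment_classes <- c("N", "P2O5", "K2O", "S", "pesticides", "irrigation")

#' Land types tracked by the model
#' @format Character vector: cultivated cropland (annual crops), cropland
#'   pasture (perennial forage on cropland), permanent pasture (grazing
#'   land including grazed woodland).
#' @export
land_types <- c("cultivated_cropland", "cropland_pasture", "permanent_pasture")

# Model unit constants. Internal units are imperial (lb, acres,
# servings/day); SI conversion is a reporting-layer concern only.
model_constants <- function() {
  list(
    g_per_lb       = 454,      # grams per pound, as used in the mass equation
    days_per_year  = 365,
    milk_fat       = 0.037,    # fat solids as proportion of fluid-milk mass
    milk_nonfat    = 0.086,    # non-fat solids as proportion of fluid-milk mass
    acre_to_ha     = 0.404686,
    lb_to_kg       = 0.453592,
    acreft_to_m3   = 1233.48
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
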