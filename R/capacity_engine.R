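#' Land availability from a census land base
#'
#' Evaluates, in order: cropping intensity (harvested area over cultivated
#' area; > 1 under double cropping), productive cropland (harvested plus
#' cropland pasture), the proportion of productive land cultivated,
#' available cultivated food cropland (productive x proportion cultivated
#' / cropping intensity, minus non-food cropland), and available grazing
#' land (permanent pasture plus grazed woodland). Formulas can go negative
#' on inconsistent bases; such values are floored at zero with a warning.
#'
#' @param base one-row land-base data.frame (see
#'   [food_system_parameters()]).
#' @return list of class `land_availability`: `cropping_intensity`,
#'   `productive_cropland`, `proportion_cultivated`,
#'   `available_cultivated_food_cropland`, `available_grazing_land`,
#'   `available_food_cropland_all_uses` (acres).
#' @export
land_availability <- function(base) {
  b <- as.list(base[1, ])
  if (b$total_area_cultivated <= 0)
    stop("total_area_cultivated must be > 0 (cropping intensity undefined)")
  ci <- b$area_harvested_field_veg_other / b$total_area_cultivated
  productive <- b$cropland_harvested + b$cropland_pasture_grazing
  prop_cult <- if (productive > 0)
    b$total_cultivated_harvested_excl_forage / productive else 0
  avail_cult <- productive * prop_cult / ci - b$nonfood_cropland
  if (avail_cult < 0) {
    warning("available cultivated food cropland is negative (non-food ",
            "cropland exceeds cultivated area); floored at 0", call. = FALSE)
    avail_cult <- 0
  }
  all_uses <- productive - b$nonfood_cropland
  if (all_uses < 0) {
    warning("available food cropland (all uses) is negative; floored at 0",
            call. = FALSE)
    all_uses <- 0
  }
  structure(list(
    cropping_intensity = ci,
    productive_cropland = productive,
    proportion_cultivated = prop_cult,
    available_cultivated_food_cropland = avail_cult,
    available_grazing_land = b$permanent_pasture + b$woodland_grazed,
    available_food_cropland_all_uses = all_uses
  ), class = "land_availability")
}

#' Grazing-land reallocation onto cropland
#'
#' When a diet demands more grazing land, relative to cropland, than the
#' land base offers, part of the grazing burden is moved onto cropland.
#' With `RA` the availability ratio (available grazing land over available
#' cropland), `RR` the requirement ratio (required grazing land over
#' required cropland-plus-forage land, cropland divided by cropping
#' intensity), and `RY` the yield equivalence ratio between the two land
#' classes, the reallocated cropland is
#' `(sum grazing - RA * sum(cropland/CI + forage)) / (RA + RY)` when
#' `RR > RA` and zero otherwise; the grazing land it releases is
#' `cropland_used_for_grazing * RY`.
#'
#' Two conventions for `RY` are supported. `"as_printed"` (default) uses
#' the grazing-land yield over the cropland grazing yield, exactly as the
#' source prints it. `"mass_balance"` uses the inverse, which is the
#' convention under which the forage mass harvested from the reallocated
#' cropland exactly replaces the forage forgone on the released pasture.
#'
#' @param land a `land_result` data.frame (per-capita acres).
#' @param avail a `land_availability` object.
#' @param params a `food_system_parameters` object (yield table supplies
#'   the two grazing yields).
#' @param convention `"as_printed"` or `"mass_balance"`.
#' @param ra_cropland which availability enters RA's denominator:
#'   `"all_uses"` (default) or `"cultivated"`.
#' @return list of class `grazing_adjustment`: `RA`, `RR`, `RY`,
#'   `cropland_used_for_grazing`, `grazing_land_offset` (per-capita
#'   acres), `yield_g`, `yield_p`.
#' @export
grazing_adjustment <- function(land, avail, params,
                               convention = c("as_printed", "mass_balance"),
                               ra_cropland = c("all_uses", "cultivated")) {
  convention <- match.arg(convention)
  ra_cropland <- match.arg(ra_cropland)
  tot <- land_totals(land)
  G <- tot[["permanent_pasture"]]
  Ccult <- tot[["cultivated_cropland"]]
  For <- tot[["cropland_pasture"]]
  ci <- avail$cropping_intensity

  avail_crop <- switch(ra_cropland,
                       all_uses = avail$available_food_cropland_all_uses,
                       cultivated = avail$available_cultivated_food_cropland)
  RA <- avail$available_grazing_land / avail_crop

  # grazing yields on the two land classes, from the grazing commodity
  y <- params$yields
  gcomm <- unique(y$commodity_id[y$primary & y$land_type == "permanent_pasture"])
  yield_g <- yield_p <- NA_real_
  if (length(gcomm)) {
    gc1 <- gcomm[1]
    yield_g <- y$yield[y$commodity_id == gc1 & y$land_type == "permanent_pasture"][1]
    yp <- y$yield[y$commodity_id == gc1 & y$land_type == "cropland_pasture" &
                    !y$primary]
    yield_p <- if (length(yp)) yp[1] else yield_g
  }

  if (G <= 0)
    return(structure(list(RA = RA, RR = 0, RY = NA_real_,
                          cropland_used_for_grazing = 0,
                          grazing_land_offset = 0,
                          yield_g = yield_g, yield_p = yield_p),
                     class = "grazing_adjustment"))

  denom <- Ccult / ci + For
  if (denom <= 0)
    stop("required cropland is zero with positive grazing demand; ",
         "RR is undefined")
  RR <- G / denom
  RY <- switch(convention,
               as_printed = yield_g / yield_p,
               mass_balance = yield_p / yield_g)
  if (!is.finite(RY))
    stop("grazing yields unavailable; cannot form the yield ratio RY")

  cug <- if (RR > RA) (G - RA * denom) / (RA + RY) else 0
  structure(list(RA = RA, RR = RR, RY = RY,
                 cropland_used_for_grazing = cug,
                 grazing_land_offset = cug * RY,
                 yield_g = yield_g, yield_p = yield_p),
            class = "grazing_adjustment")
}

#' Population fed and carrying capacity
#'
#' Three land constraints each bound the number of people the land base
#' can feed the given diet: cultivated cropland alone, all cropland
#' (cultivated divided by cropping intensity, plus perennial forage, plus
#' cropland reallocated to grazing), and all productive land (adding
#' grazing demand net of the grazing-land offset against cropland-plus-
#' grazing availability). The carrying capacity is the smallest of the
#' three divided by the population size. A zero per-capita requirement
#' with positive availability reports `Inf` (unbounded). The estimate is
#' meaningful for a closed system; in an open system it is still computed
#' but rests on a fixed domestic land base.
#'
#' @param land a `land_result` data.frame (per-capita acres).
#' @param avail a `land_availability` object.
#' @param adj a `grazing_adjustment` object.
#' @param population population size (> 0).
#' @return list: `population_fed` (named length-3: `cultivated_cropland`,
#'   `all_cropland`, `all_productive_land`), `carrying_capacity`.
#' @export
population_fed <- function(land, avail, adj, population) {
  stopifnot(population > 0)
  tot <- land_totals(land)
  ci <- avail$cropping_intensity
  cult <- tot[["cultivated_cropland"]]
  forage <- tot[["cropland_pasture"]]
  graz <- tot[["permanent_pasture"]]
  cug <- adj$cropland_used_for_grazing
  off <- adj$grazing_land_offset

  ratio <- function(a, b) if (b <= 0) Inf else a / b
  pf <- c(
    cultivated_cropland = ratio(avail$available_cultivated_food_cropland, cult),
    all_cropland = ratio(avail$available_food_cropland_all_uses,
                         cult / ci + forage + cug),
    all_productive_land = ratio(
      avail$available_food_cropland_all_uses + avail$available_grazing_land,
      cult / ci + forage + graz + cug - off)
  )
  list(population_fed = pf, carrying_capacity = min(pf) / population)
}

#' Total annual land use
#'
#' `[(cultivated / cropping_intensity) + (forage +
#' cropland_used_for_grazing) + (grazing - grazing_land_offset)] x
#' population`. With a zero grazing adjustment this reduces to the plain
#' sum of the three per-capita land types (cultivated discounted by
#' cropping intensity).
#'
#' @param land a `land_result` data.frame (per-capita acres).
#' @param adj a `grazing_adjustment` object.
#' @param cropping_intensity from [land_availability()].
#' @param population population size.
#' @return list: `total_acres`, `per_capita_acres`, and the three
#'   per-capita components (`cultivated`, `cropland` forage+reallocated,
#'   `grazing` net of offset).
#' @export
total_land_use <- function(land, adj, cropping_intensity, population) {
  tot <- land_totals(land)
  cult <- tot[["cultivated_cropland"]] / cropping_intensity
  crop <- tot[["cropland_pasture"]] + adj$cropland_used_for_grazing
  graz <- max(0, tot[["permanent_pasture"]] - adj$grazing_land_offset)
  pc <- cult + crop + graz
  list(total_acres = pc * population, per_capita_acres = pc,
       cultivated = cult, cropland = crop, grazing = graz)
}

#' Amendment use implied by a land result
#'
#' Fertilizer nutrients (N, P2O5, K2O, S), pesticides, and irrigation
#' water: each food's acres are multiplied by the per-acre application
#' rate of its commodity. Commodities without a rate record contribute
#' zero (grazing land is conventionally unamended), with a single
#' warning, so totals are conservative.
#'
#' @param land a `land_result` data.frame (per-capita acres).
#' @param params a `food_system_parameters` object.
#' @param population population size for system totals.
#' @return list: `per_capita` (named over [amendment_classes]), `total`
#'   (scaled by population), `per_food` (long data.frame `food_id`,
#'   `commodity_id`, `amendment`, `amount_pc`).
#' @export
amendment_use <- function(land, params, population = 1) {
  am <- params$amendments
  if (nrow(am) && any(am$rate < 0)) stop("negative amendment rate")
  per_capita <- stats::setNames(numeric(length(amendment_classes)),
                                amendment_classes)
  per_food <- data.frame(food_id = character(0), commodity_id = character(0),
                         amendment = character(0), amount_pc = numeric(0),
                         stringsAsFactors = FALSE)
  if (nrow(land)) {
    uncovered <- setdiff(unique(land$commodity_id[land$acres_pc > 0]),
                         unique(am$commodity_id))
    if (length(uncovered))
      warning("no amendment rates for commodity(ies) ",
              paste(uncovered, collapse = ", "),
              "; contributing 0 (conservative)", call. = FALSE)
    mg <- merge(land[, c("food_id", "commodity_id", "acres_pc")], am,
                by = "commodity_id")
    if (nrow(mg)) {
      mg$amount_pc <- mg$acres_pc * mg$rate
      per_food <- mg[, c("food_id", "commodity_id", "amendment", "amount_pc")]
      s <- tapply(mg$amount_pc, mg$amendment, sum)
      per_capita[names(s)] <- as.numeric(s)
    }
  }
  list(per_capita = per_capita, total = per_capita * population,
       per_food = per_food)
}

#' Per-capita energy and macronutrient content of a diet
#'
#' Linear sum over foods of daily servings (group servings times
#' preference share) times per-serving composition. Foods missing a
#' composition are skipped with a warning.
#'
#' @param diet a `food_group_vector`.
#' @param params a `food_system_parameters` object.
#' @return named numeric: `energy_kcal`, `protein_g`, `fat_g`,
#'   `carbohydrate_g` per capita per day.
#' @export
nutrient_summary <- function(diet, params) {
  f <- params$foods
  nu <- params$nutrients
  m <- match(f$food_group, names(diet))
  servings <- ifelse(is.na(m), 0, as.numeric(diet)[m]) * f$preference_share
  k <- match(f$food_id, nu$food_id)
  if (any(is.na(k) & servings > 0))
    warning("no nutrient composition for: ",
            paste(f$food_id[is.na(k) & servings > 0], collapse = ", "),
            "; skipped", call. = FALSE)
  ok <- !is.na(k)
  c(energy_kcal = sum(servings[ok] * nu$energy_kcal[k[ok]]),
    protein_g = sum(servings[ok] * nu$protein_g[k[ok]]),
    fat_g = sum(servings[ok] * nu$fat_g[k[ok]]),
    carbohydrate_g = sum(servings[ok] * nu$carbohydrate_g[k[ok]]))
}
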