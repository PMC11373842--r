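#' @title Food-system parameter sets
#'
#' @description
#' A `food_system_parameters` object holds every coefficient the simulation
#' consumes: per-food preference, serving-size, loss/waste and processing
#' records; dairy solids compositions; fat/oil product blends and oilseed
#' crush coefficients; livestock and aquaculture feed coefficients; trade
#' stocks; crop and grazing yields by land type; amendment application
#' rates; the land-availability base; and per-serving nutrient
#' compositions. All invariants are machine-checked at construction, so a
#' parameter set that exists is a parameter set every downstream stage can
#' trust.
#'
#' Internal units are those of the source accounting: pounds, acres,
#' servings per day, lb/acre. SI conversion happens only at reporting.
#'
#' @name food_system_parameters
NULL

.fsp_tables <- c("groups", "foods", "dairy", "fats_oils", "oil_crops",
                 "feed", "animal_fats", "aquaculture", "feed_nutrients",
                 "trade", "yields", "amendments", "land_base", "nutrients",
                 "system")

.land_base_fields <- c("area_harvested_field_veg_other", "total_area_cultivated",
                       "cropland_harvested", "cropland_pasture_grazing",
                       "total_cultivated_harvested_excl_forage",
                       "nonfood_cropland", "permanent_pasture", "woodland_grazed")

#' Construct and validate a food-system parameter set
#'
#' All component tables are plain data frames (column contracts below).
#' Construction runs the full validation battery and reapportions
#' preference shares of non-producible foods onto producible foods within
#' the same group, in proportion to their stated shares. The raw shares are
#' retained in `foods$preference_share_raw` for provenance.
#'
#' @param groups data.frame: `food_group`, `serving_unit`.
#' @param foods data.frame: `food_id`, `food_group`, `category`,
#'   `serving_size` (g/serving), `producible` (logical),
#'   `preference_share`, `loss_waste_factor` (>= 1),
#'   `processing_conversion` (lb commodity / lb food), `commodity_id`.
#' @param dairy data.frame: `food_id`, `fat_solids`, `nonfat_solids`
#'   (proportions of food mass).
#' @param fats_oils data.frame: `product_id`, `oil_id`, `share`
#'   (shares sum to 1 per product).
#' @param oil_crops data.frame: `oil_id`, `commodity_id` (seed crop),
#'   `meal_commodity_id` (or NA), `seed_per_oil` (lb seed / lb oil),
#'   `meal_yield` (lb meal / lb seed), `meal_protein` (protein fraction).
#' @param feed data.frame: `animal_product_id`, `feed_commodity_id`,
#'   `lb_feed_per_lb_product`.
#' @param animal_fats data.frame: `animal_product_id`,
#'   `lb_fat_per_lb_product` (lard/tallow coproduced per lb product).
#' @param aquaculture data.frame: `species_id`, `farmed_share`, `fcr`,
#'   `processing_efficiency`, `ration_energy` (energy units / lb feed),
#'   `ration_protein` (protein lb / lb feed).
#' @param feed_nutrients data.frame: `feed_commodity_id`, `energy`,
#'   `protein` (per lb as-fed); must cover corn and soybean meal for the
#'   aquaculture solve.
#' @param trade data.frame: `food_id`, `beginning_stock`, `imports`,
#'   `exports` (system-level lb/yr).
#' @param yields data.frame: `commodity_id`, `land_type`, `yield`
#'   (lb/acre), `primary` (logical; the land type on which demand for the
#'   commodity is grown — non-primary rows carry auxiliary yields such as
#'   the grazing yield of cropland used by the reallocation step).
#' @param amendments data.frame: `commodity_id`, `amendment`, `rate`
#'   (quantity/acre/yr, already scaled by proportion of area treated).
#' @param land_base one-row data.frame with acre fields
#'   `area_harvested_field_veg_other`, `total_area_cultivated`,
#'   `cropland_harvested`, `cropland_pasture_grazing`,
#'   `total_cultivated_harvested_excl_forage`, `nonfood_cropland`,
#'   `permanent_pasture`, `woodland_grazed`.
#' @param nutrients data.frame: `food_id`, `energy_kcal`, `protein_g`,
#'   `fat_g`, `carbohydrate_g` per serving.
#' @param system one-row data.frame of system-level coefficients:
#'   `corn_commodity_id`, `soymeal_commodity_id`, `corn_oil_per_lb_corn`,
#'   `gluten_feed_per_lb_corn`, `gluten_feed_protein`, `milk_commodity_id`,
#'   `milk_processing_conversion`, `lard_commodity_id`.
#' @param validate logical; skip validation only when reconstructing a set
#'   already known valid.
#'
#' @return An object of class `food_system_parameters`.
#' @export
food_system_parameters <- function(groups, foods, dairy, fats_oils, oil_crops,
                                   feed, animal_fats, aquaculture,
                                   feed_nutrients, trade, yields, amendments,
                                   land_base, nutrients, system,
                                   validate = TRUE) {
  params <- structure(
    list(groups = groups, foods = foods, dairy = dairy,
         fats_oils = fats_oils, oil_crops = oil_crops, feed = feed,
         animal_fats = animal_fats, aquaculture = aquaculture,
         feed_nutrients = feed_nutrients, trade = trade, yields = yields,
         amendments = amendments, land_base = land_base,
         nutrients = nutrients, system = system,
         constants = model_constants()),
    class = "food_system_parameters")
  if (validate) {
    validate_parameters(params)
    params <- .reapportion_all(params)
  }
  params
}

#' @export
print.food_system_parameters <- function(x, ...) {
  cat("<food_system_parameters>\n")
  cat(sprintf("  %d foods in %d groups; %d commodities with yields\n",
              nrow(x$foods), length(unique(x$foods$food_group)),
              length(unique(x$yields$commodity_id))))
  cat(sprintf("  %d feed coefficients, %d aquaculture species, %d trade records\n",
              nrow(x$feed), nrow(x$aquaculture), nrow(x$trade)))
  invisible(x)
}

# Reapportion preference shares of non-producible foods within each group.
# Retains raw shares; errors if a group with positive raw share has no
# producible member (its demand could never be served).
.reapportion_all <- function(params) {
  foods <- params$foods
  if (is.null(foods$preference_share_raw))
    foods$preference_share_raw <- foods$preference_share
  for (g in unique(foods$food_group)) {
    idx <- which(foods$food_group == g)
    foods$preference_share[idx] <-
      reapportion_preferences(foods[idx, , drop = FALSE])$preference_share
  }
  params$foods <- foods
  params
}

#' Validate a food-system parameter set
#'
#' Checks every declared invariant: positivity and range constraints on all
#' tables, per-group preference-share closure, per-product fat/oil share
#' closure, dairy solids bounds, cross-references between tables, and the
#' presence of a primary yield for every commodity that can demand land.
#' Violations are collected and reported together.
#'
#' @param params a `food_system_parameters` object (or compatible list).
#' @param quiet logical; suppress the validation report message.
#' @return `params`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_parameters <- function(params, quiet = FALSE) {
  bad <- character(0)
  note <- function(fmt, ...) bad <<- c(bad, sprintf(fmt, ...))

  need_cols <- function(tab, name, cols) {
    miss <- setdiff(cols, names(tab))
    if (length(miss)) {
      note("table '%s': missing column(s) %s", name,
           paste(sQuote(miss), collapse = ", "))
      return(FALSE)
    }
    TRUE
  }

  f <- params$foods
  if (need_cols(f, "foods", c("food_id", "food_group", "serving_size",
                              "producible", "preference_share",
                              "loss_waste_factor", "processing_conversion",
                              "commodity_id"))) {
    if (anyDuplicated(f$food_id))
      note("foods: duplicated food_id %s",
           paste(unique(f$food_id[duplicated(f$food_id)]), collapse = ", "))
    chk <- function(cond, msg) if (any(!cond))
      note("foods: %s for %s", msg, paste(f$food_id[!cond], collapse = ", "))
    chk(f$serving_size > 0, "serving_size must be > 0")
    chk(f$loss_waste_factor >= 1, "loss_waste_factor must be >= 1")
    chk(f$processing_conversion > 0, "processing_conversion must be > 0")
    chk(f$preference_share >= 0 & f$preference_share <= 1,
        "preference_share must lie in [0, 1]")
    shares <- f$preference_share_raw %||% f$preference_share
    for (g in unique(f$food_group)) {
      s <- sum(shares[f$food_group == g])
      if (abs(s - 1) > 1e-9)
        note("foods: preference shares in group '%s' sum to %.12g, not 1", g, s)
    }
    if (!is.null(params$groups) &&
        length(miss <- setdiff(f$food_group, params$groups$food_group)))
      note("foods: food_group(s) %s absent from groups table",
           paste(sQuote(miss), collapse = ", "))
  }

  d <- params$dairy
  if (nrow(d) && need_cols(d, "dairy", c("food_id", "fat_solids", "nonfat_solids"))) {
    if (any(d$fat_solids < 0 | d$nonfat_solids < 0))
      note("dairy: negative solids proportions")
    if (any(d$fat_solids + d$nonfat_solids > 1 + 1e-12))
      note("dairy: fat_solids + nonfat_solids exceeds 1 for %s",
           paste(d$food_id[d$fat_solids + d$nonfat_solids > 1 + 1e-12],
                 collapse = ", "))
    if (length(miss <- setdiff(d$food_id, f$food_id)))
      note("dairy: unknown food_id %s", paste(miss, collapse = ", "))
  }

  fo <- params$fats_oils
  if (nrow(fo) && need_cols(fo, "fats_oils", c("product_id", "oil_id", "share"))) {
    for (p in unique(fo$product_id)) {
      s <- sum(fo$share[fo$product_id == p])
      if (abs(s - 1) > 1e-9)
        note("fats_oils: shares for product '%s' sum to %.12g, not 1", p, s)
    }
  }

  oc <- params$oil_crops
  if (nrow(oc) && need_cols(oc, "oil_crops",
                            c("oil_id", "commodity_id", "seed_per_oil",
                              "meal_yield", "meal_protein"))) {
    if (any(oc$seed_per_oil <= 0)) note("oil_crops: seed_per_oil must be > 0")
    if (any(oc$meal_yield < 0 | oc$meal_yield > 1) ||
        any(oc$meal_protein < 0 | oc$meal_protein > 1))
      note("oil_crops: meal_yield and meal_protein must lie in [0, 1]")
    if (length(miss <- setdiff(fo$oil_id, oc$oil_id)))
      note("oil_crops: no crush coefficients for oil(s) %s",
           paste(miss, collapse = ", "))
  }

  fe <- params$feed
  if (nrow(fe) && need_cols(fe, "feed", c("animal_product_id",
                                          "feed_commodity_id",
                                          "lb_feed_per_lb_product"))) {
    if (any(fe$lb_feed_per_lb_product < 0))
      note("feed: negative feed coefficient")
  }

  aq <- params$aquaculture
  if (nrow(aq) && need_cols(aq, "aquaculture",
                            c("species_id", "farmed_share", "fcr",
                              "processing_efficiency", "ration_energy",
                              "ration_protein"))) {
    if (any(aq$farmed_share < 0 | aq$farmed_share > 1))
      note("aquaculture: farmed_share must lie in [0, 1]")
    if (any(aq$fcr <= 0)) note("aquaculture: fcr must be > 0")
    if (any(aq$processing_efficiency <= 0 | aq$processing_efficiency > 1))
      note("aquaculture: processing_efficiency must lie in (0, 1]")
  }

  tr <- params$trade
  if (nrow(tr) && need_cols(tr, "trade", c("food_id", "beginning_stock",
                                           "imports", "exports"))) {
    if (any(tr$beginning_stock < 0 | tr$imports < 0 | tr$exports < 0))
      note("trade: stocks, imports and exports must be >= 0")
  }

  y <- params$yields
  if (need_cols(y, "yields", c("commodity_id", "land_type", "yield", "primary"))) {
    if (length(miss <- setdiff(y$land_type, land_types)))
      note("yields: unknown land_type %s", paste(sQuote(miss), collapse = ", "))
    if (any(y$yield <= 0)) note("yields: yield must be > 0")
    # every commodity that can demand land must have exactly one primary yield
    land_comm <- .land_commodities(params)
    np <- vapply(land_comm, function(cm) sum(y$primary[y$commodity_id == cm]),
                 numeric(1))
    if (any(np != 1))
      note("yields: commodity(ies) %s need exactly one primary yield record",
           paste(land_comm[np != 1], collapse = ", "))
  }

  am <- params$amendments
  if (nrow(am) && need_cols(am, "amendments", c("commodity_id", "amendment", "rate"))) {
    if (length(miss <- setdiff(am$amendment, amendment_classes)))
      note("amendments: unknown amendment %s", paste(sQuote(miss), collapse = ", "))
    if (any(am$rate < 0)) note("amendments: negative application rate")
  }

  lb <- params$land_base
  if (need_cols(lb, "land_base", .land_base_fields)) {
    v <- unlist(lb[1, .land_base_fields])
    if (any(v < 0)) note("land_base: all areas must be >= 0")
  }

  nu <- params$nutrients
  if (nrow(nu) && need_cols(nu, "nutrients", c("food_id", "energy_kcal",
                                               "protein_g", "fat_g",
                                               "carbohydrate_g"))) {
    if (length(miss <- setdiff(nu$food_id, f$food_id)))
      note("nutrients: unknown food_id %s", paste(miss, collapse = ", "))
  }

  sy <- params$system
  need_cols(sy, "system", c("corn_commodity_id", "soymeal_commodity_id",
                            "corn_oil_per_lb_corn",
                            "gluten_feed_per_lb_corn", "gluten_feed_protein",
                            "milk_commodity_id", "milk_processing_conversion",
                            "lard_commodity_id"))

  if (length(bad))
    stop("invalid food-system parameters:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  if (!quiet)
    message(sprintf(
      "parameter set valid: %d foods, %d yield records, %d amendment rates",
      nrow(f), nrow(y), nrow(am)))
  invisible(params)
}

# Commodities whose demand is served by land directly (crops): everything
# referenced as a demand target that is not an animal product, aquaculture
# species, dairy milk, fat/oil product, oil, meal, or lard/tallow pool.
.land_commodities <- function(params) {
  f <- params$foods; sy <- params$system
  non_land <- unique(c(params$feed$animal_product_id,
                       params$aquaculture$species_id,
                       sy$milk_commodity_id, sy$lard_commodity_id,
                       params$fats_oils$product_id,
                       params$oil_crops$oil_id,
                       params$oil_crops$meal_commodity_id))
  direct <- setdiff(unique(f$commodity_id[f$producible]), non_land)
  feed_land <- setdiff(unique(params$feed$feed_commodity_id),
                       c(params$oil_crops$meal_commodity_id))
  seed <- unique(params$oil_crops$commodity_id)
  unique(c(direct, feed_land, seed))
}

# ---- serialization ---------------------------------------------------------

.fsp_files <- function() paste0(.fsp_tables, ".tsv")

# write a data.frame as TSV with round-trip-exact numeric formatting
.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

.read_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  # numeric columns serialize without decimal points when integer-valued;
  # keep them double so round-trips are type-identical
  for (j in seq_along(df))
    if (is.integer(df[[j]])) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Write a parameter set to a directory of delimited tables
#'
#' One UTF-8 tab-separated table per component plus a `manifest.yaml`
#' naming each table. `load_parameters()` on the result reproduces the
#' parameter set field-for-field (numeric values are serialized with 17
#' significant digits).
#'
#' @param params a `food_system_parameters` object.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "food_system_parameters"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  manifest <- list(format = "foodprintr-parameters", version = 1L,
                   tables = stats::setNames(as.list(.fsp_files()), .fsp_tables))
  for (tab in .fsp_tables)
    .write_tsv(params[[tab]], file.path(path, paste0(tab, ".tsv")))
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Load and validate a parameter set from a directory of delimited tables
#'
#' Reads the `manifest.yaml` (falling back to default table filenames when
#' absent), loads every table, and runs the full validation battery.
#' Missing tables, invariant violations, and dangling cross-references are
#' all fatal.
#'
#' @param path directory containing the parameter tables.
#' @param quiet logical; suppress the validation report.
#' @return A validated `food_system_parameters` object.
#' @export
load_parameters <- function(path, quiet = FALSE) {
  if (!dir.exists(path)) stop("parameter directory not found: ", path)
  mf <- file.path(path, "manifest.yaml")
  files <- if (file.exists(mf)) {
    m <- yaml::read_yaml(mf)
    stats::setNames(as.character(unlist(m$tables[.fsp_tables])),
                    .fsp_tables)
  } else stats::setNames(.fsp_files(), .fsp_tables)
  tabs <- list()
  for (tab in .fsp_tables) {
    fp <- file.path(path, files[[tab]])
    if (is.na(files[[tab]]) || !file.exists(fp))
      stop("missing table '", tab, "' (expected file ",
           files[[tab]] %||% paste0(tab, ".tsv"), ") in ", path)
    tabs[[tab]] <- .read_tsv(fp)
  }
  params <- do.call(food_system_parameters, c(tabs, list(validate = FALSE)))
  validate_parameters(params, quiet = quiet)
  # shares on disk may be raw (pre-reapportionment) or already processed;
  # reapportionment is idempotent so always reapply from the raw column
  if (!is.null(params$foods$preference_share_raw))
    params$foods$preference_share <- params$foods$preference_share_raw
  .reapportion_all(params)
}
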