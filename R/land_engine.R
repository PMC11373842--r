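#' Multiuse-crop coproduct ledger
#'
#' Corn milled for sweeteners coproduces corn oil and corn gluten feed;
#' soybeans and other oilseeds crushed for oil coproduce protein meal;
#' animal foods coproduce lard and tallow. Summing land over end uses
#' would count these crops more than once, so an eight-step ledger derives
#' spared commodity masses that are credited against demand before land is
#' computed. Every intermediate is exposed for audit.
#'
#' The steps, in order (each a sum, min, or zero-floored difference):
#' \enumerate{
#' \item corn oil and corn-gluten-feed protein coproduced from milling
#'   corn for sweetener demand;
#' \item oil demand per oilseed and crush coefficients (seed per oil);
#' \item protein-meal coproduction from crushing for oil demand, and
#'   lard/tallow coproduced from animal-food demand;
#' \item corn oil spared = min(corn oil consumed, corn oil coproduced);
#'   corn spared = spared oil converted to corn mass;
#' \item lard/tallow remaining = demand minus coproduced, floored at 0
#'   (remaining demand is itself a coproduct of animal foods and claims
#'   no extra land); surplus = coproduced minus demand, floored at 0;
#' \item oilseed oil demand offset by the surplus fat pool (surplus corn
#'   oil + surplus lard/tallow), allocated proportionally; spared seed
#'   mass credited per oilseed;
#' \item feed protein coproduced from the remaining (actually crushed)
#'   oilseed mass;
#' \item soybeans spared from feed: coproduced protein (gluten + crush)
#'   divided by protein per pound of soybean processed into meal, capped
#'   at the soybean mass the feed ration actually demands.
#' }
#'
#' @param demand a `commodity_demand` data.frame.
#' @param feed feed-demand data.frame from [livestock_feed_demand()].
#' @param params a `food_system_parameters` object.
#' @return list of class `multiuse_adjustment` with the full intermediate
#'   ledger and the offsets `corn_spared` (lb corn), `oilseed_spared`
#'   (named lb per seed commodity), `soybean_spared` (lb soybeans).
#' @export
multiuse_adjustment <- function(demand, feed, params) {
  sy <- params$system
  oc <- params$oil_crops
  corn_id <- sy$corn_commodity_id

  corn_for_sweetener <- sum(demand$lb_yr[demand$kind == "sweetener" &
                                           demand$commodity_id == corn_id])
  oil_dem <- demand[demand$kind == "oil", ]
  oil_demand <- if (nrow(oil_dem))
    vapply(split(oil_dem$lb_yr, oil_dem$commodity_id), sum, numeric(1))
  else stats::setNames(numeric(0), character(0))
  lard_demand <- sum(demand$lb_yr[demand$kind == "lard"])

  # Step 1: wet-milling coproducts of sweetener corn
  corn_oil_coproduced <- corn_for_sweetener * sy$corn_oil_per_lb_corn
  gluten_protein <- corn_for_sweetener * sy$gluten_feed_per_lb_corn *
    sy$gluten_feed_protein

  # Step 2: split oil demand into the corn-oil stream and oilseed streams
  oc_corn <- oc[oc$commodity_id == corn_id, , drop = FALSE]
  corn_oil_ids <- oc_corn$oil_id
  seed_oils <- setdiff(names(oil_demand), corn_oil_ids)
  oilseed_oil_demand <- oil_demand[seed_oils]
  spo <- stats::setNames(oc$seed_per_oil, oc$oil_id)

  # Step 3: coproduction from crushing for oil, and animal-fat coproducts
  meal_protein_coproduced <- sum(oilseed_oil_demand * spo[seed_oils] *
    oc$meal_yield[match(seed_oils, oc$oil_id)] *
    oc$meal_protein[match(seed_oils, oc$oil_id)])
  ani <- demand[demand$kind %in% c("animal", "dairy"), ]
  lt_coproduced <- 0
  if (nrow(ani) && nrow(params$animal_fats)) {
    m <- match(ani$commodity_id, params$animal_fats$animal_product_id)
    lt_coproduced <- sum(ani$lb_yr *
      ifelse(is.na(m), 0, params$animal_fats$lb_fat_per_lb_product[m]))
  }

  # Step 4: corn spared via corn-oil matching
  corn_oil_consumed <- sum(oil_demand[corn_oil_ids], na.rm = TRUE)
  corn_oil_spared <- min(corn_oil_consumed, corn_oil_coproduced)
  corn_spared <- if (length(corn_oil_ids))
    corn_oil_spared * spo[corn_oil_ids[1]] else 0
  corn_oil_surplus <- corn_oil_coproduced - corn_oil_spared

  # Step 5: lard/tallow balance
  lt_remaining <- max(0, lard_demand - lt_coproduced)
  lt_surplus <- max(0, lt_coproduced - lard_demand)

  # Step 6: oilseed offset from the surplus fat pool
  fat_pool <- corn_oil_surplus + lt_surplus
  tot_seed_oil <- sum(oilseed_oil_demand)
  offset_total <- min(tot_seed_oil, fat_pool)
  oil_offset <- if (tot_seed_oil > 0)
    oilseed_oil_demand * offset_total / tot_seed_oil
  else oilseed_oil_demand
  oilseed_spared <- stats::setNames(numeric(0), character(0))
  if (length(seed_oils)) {
    seed_of <- stats::setNames(oc$commodity_id, oc$oil_id)
    spared_seed <- oil_offset * spo[seed_oils]
    oilseed_spared <- vapply(split(spared_seed, seed_of[seed_oils]), sum,
                             numeric(1))
  }

  # Step 7: feed protein from oilseed mass actually crushed
  remaining_oil <- oilseed_oil_demand - oil_offset
  crush_protein <- sum(remaining_oil * spo[seed_oils] *
    oc$meal_yield[match(seed_oils, oc$oil_id)] *
    oc$meal_protein[match(seed_oils, oc$oil_id)])

  # Step 8: soybeans spared from the feed ration
  soy_row <- oc[!is.na(oc$meal_commodity_id) &
                  oc$meal_commodity_id == sy$soymeal_commodity_id, ,
                drop = FALSE]
  soymeal_feed <- sum(feed$lb_yr[feed$feed_commodity_id ==
                                   sy$soymeal_commodity_id])
  soybean_spared <- 0
  soybeans_for_feed <- 0
  if (nrow(soy_row)) {
    soybeans_for_feed <- soymeal_feed / soy_row$meal_yield[1]
    prot_per_lb_soy <- soy_row$meal_yield[1] * soy_row$meal_protein[1]
    if (prot_per_lb_soy > 0)
      soybean_spared <- min(soybeans_for_feed,
                            (gluten_protein + crush_protein) /
                              prot_per_lb_soy)
  }

  structure(list(
    corn_for_sweetener = corn_for_sweetener,
    corn_oil_coproduced = corn_oil_coproduced,
    gluten_protein_coproduced = gluten_protein,
    oilseed_oil_demand = oilseed_oil_demand,
    meal_protein_coproduced = meal_protein_coproduced,
    lard_tallow_coproduced = lt_coproduced,
    corn_oil_consumed = corn_oil_consumed,
    corn_oil_spared = corn_oil_spared,
    corn_oil_surplus = corn_oil_surplus,
    lard_tallow_remaining = lt_remaining,
    lard_tallow_surplus = lt_surplus,
    oilseed_oil_offset = oil_offset,
    crush_feed_protein_coproduced = crush_protein,
    soybeans_for_feed = soybeans_for_feed,
    corn_spared = unname(corn_spared),
    oilseed_spared = oilseed_spared,
    soybean_spared = soybean_spared
  ), class = "multiuse_adjustment")
}

# zero-offset adjustment (used when the ledger is disabled)
.null_adjustment <- function() {
  structure(list(corn_spared = 0,
                 oilseed_spared = stats::setNames(numeric(0), character(0)),
                 soybean_spared = 0),
            class = "multiuse_adjustment")
}

#' Per-food land requirements by land type
#'
#' Converts commodity and feed demand into acres per person per year:
#' `required_land = (commodity - trade_balance / population) / yield`,
#' evaluated on each commodity's primary land type. Fat and oil demand is
#' first converted from oil mass to oilseed mass by the crush
#' coefficients; soybean-meal feed demand is converted to whole soybeans;
#' multiuse-crop offsets are credited as commodity-mass reductions before
#' the division by yield (equivalent to a land offset at fixed yield).
#' Results are floored at zero: a trade surplus cannot create negative
#' land.
#'
#' @param demand a `commodity_demand` data.frame.
#' @param feed feed-demand data.frame from [livestock_feed_demand()].
#' @param trade trade balances from [trade_balance()].
#' @param population persons in the study area (> 0).
#' @param adjustment a `multiuse_adjustment` (or `NULL` for no offsets).
#' @param params a `food_system_parameters` object.
#' @return data.frame of class `land_result`: `food_id`, `commodity_id`,
#'   `land_type`, `lb_yr` (net commodity mass), `acres_pc`
#'   (acres/person/yr).
#' @export
required_land <- function(demand, feed, trade, population,
                          adjustment = NULL, params) {
  stopifnot(population > 0)
  if (is.null(adjustment)) adjustment <- .null_adjustment()
  sy <- params$system
  oc <- params$oil_crops

  rows <- list()
  add <- function(food_id, commodity_id, lb)
    rows[[length(rows) + 1]] <<- data.frame(
      food_id = food_id, commodity_id = commodity_id, lb_yr = lb,
      stringsAsFactors = FALSE)

  crop <- demand[demand$kind %in% c("crop", "sweetener") &
                   demand$agricultural & demand$lb_yr > 0, ]
  if (nrow(crop)) add(crop$food_id, crop$commodity_id, crop$lb_yr)

  oil <- demand[demand$kind == "oil" & demand$lb_yr > 0, ]
  if (nrow(oil)) {
    m <- match(oil$commodity_id, oc$oil_id)
    if (anyNA(m))
      stop("no crush coefficients for oil(s): ",
           paste(unique(oil$commodity_id[is.na(m)]), collapse = ", "))
    add(oil$food_id, oc$commodity_id[m], oil$lb_yr * oc$seed_per_oil[m])
  }

  if (nrow(feed)) {
    fc <- feed$feed_commodity_id
    lb <- feed$lb_yr
    meal <- match(fc, oc$meal_commodity_id)
    seed_lb <- ifelse(is.na(meal), lb, lb / oc$meal_yield[meal])
    seed_cm <- ifelse(is.na(meal), fc, oc$commodity_id[meal])
    add(feed$food_id, seed_cm, seed_lb)
  }

  land <- do.call(rbind, rows)
  if (is.null(land) || !nrow(land))
    land <- data.frame(food_id = character(0), commodity_id = character(0),
                       lb_yr = numeric(0), stringsAsFactors = FALSE)

  # trade: per-capita balance credited proportionally across a food's rows
  if (!is.null(trade) && nrow(trade) && nrow(land)) {
    for (k in which(trade$balance != 0)) {
      idx <- which(land$food_id == trade$food_id[k])
      tot <- sum(land$lb_yr[idx])
      if (!length(idx) || tot <= 0) next
      fac <- max(0, 1 - (trade$balance[k] / population) / tot)
      land$lb_yr[idx] <- land$lb_yr[idx] * fac
    }
  }

  # multiuse offsets: proportional reduction within each commodity
  spared <- c(stats::setNames(adjustment$corn_spared, sy$corn_commodity_id),
              adjustment$oilseed_spared)
  soy_row <- oc[!is.na(oc$meal_commodity_id) &
                  oc$meal_commodity_id == sy$soymeal_commodity_id, ,
                drop = FALSE]
  if (nrow(soy_row)) {
    soy_cm <- soy_row$commodity_id[1]
    spared[soy_cm] <- (if (soy_cm %in% names(spared)) spared[soy_cm] else 0) +
      adjustment$soybean_spared
  }
  for (cm in names(spared)) {
    if (spared[cm] <= 0) next
    idx <- which(land$commodity_id == cm)
    tot <- sum(land$lb_yr[idx])
    if (!length(idx) || tot <= 0) next
    land$lb_yr[idx] <- land$lb_yr[idx] * max(0, 1 - spared[cm] / tot)
  }

  # yields: each commodity grows on its primary land type
  y <- params$yields[params$yields$primary, ]
  m <- match(land$commodity_id, y$commodity_id)
  if (anyNA(m)) {
    miss <- unique(land$commodity_id[is.na(m) & land$lb_yr > 0])
    if (length(miss))
      stop("demand with no primary yield record for commodity(ies): ",
           paste(miss, collapse = ", "))
    land <- land[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  land$land_type <- y$land_type[m]
  land$acres_pc <- land$lb_yr / y$yield[m]
  rownames(land) <- NULL
  structure(land, class = c("land_result", "data.frame"))
}

#' Total acres per person by land type
#' @param land a `land_result` data.frame.
#' @return named numeric over the three land types.
#' @export
land_totals <- function(land) {
  out <- stats::setNames(numeric(length(land_types)), land_types)
  if (nrow(land)) {
    s <- tapply(land$acres_pc, land$land_type, sum)
    out[names(s)] <- as.numeric(s)
  }
  out
}
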