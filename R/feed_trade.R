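#' Aquaculture feed requirements via a two-ingredient nutritional solve
#'
#' For each farmed species, lifetime feed mass per pound of edible fish is
#' the feed conversion ratio (feed per live-weight gain) divided by the
#' processing efficiency (edible mass per live mass). Multiplying by the
#' ration's energy and crude-protein densities gives the per-edible-pound
#' nutritional requirement, which is then met exactly with a corn /
#' soybean-meal blend by solving the 2x2 linear system. If the exact
#' solution has a negative component the blend is clipped to the
#' nonnegative single-ingredient mix that meets both constraints with the
#' least total feed mass, with a warning.
#'
#' A strict-paper mode multiplies by processing efficiency instead of
#' dividing, reproducing the printed product form for comparison (it
#' understates feed whenever processing efficiency < 1).
#'
#' @param species data.frame of aquaculture species records.
#' @param feed_nutrients data.frame: `feed_commodity_id`, `energy`,
#'   `protein` per lb as-fed.
#' @param corn_id,soymeal_id commodity ids of the two ingredients.
#' @param strict_paper logical; use the multiplicative dimensional form.
#' @return data.frame: `species_id`, `energy_required`,
#'   `protein_required` (per lb edible), `corn_lb`, `soymeal_lb`.
#' @export
aquaculture_requirements <- function(species, feed_nutrients,
                                     corn_id = "corn_grain",
                                     soymeal_id = "soybean_meal",
                                     strict_paper = FALSE) {
  nut <- function(id) {
    k <- match(id, feed_nutrients$feed_commodity_id)
    if (is.na(k)) stop("feed nutrient content missing for '", id, "'")
    c(E = feed_nutrients$energy[k], P = feed_nutrients$protein[k])
  }
  corn <- nut(corn_id); soy <- nut(soymeal_id)
  A <- matrix(c(corn["E"], corn["P"], soy["E"], soy["P"]), nrow = 2)
  if (abs(det(A)) < 1e-12)
    stop("corn / soybean-meal nutrient matrix is singular; ",
         "the two-ingredient blend cannot be solved")

  out <- species[, "species_id", drop = FALSE]
  out$energy_required <- out$protein_required <- out$corn_lb <-
    out$soymeal_lb <- NA_real_
  for (i in seq_len(nrow(species))) {
    s <- species[i, ]
    if (s$processing_efficiency <= 0)
      stop("processing_efficiency must be > 0 for ", s$species_id)
    feed_per_edible <- if (strict_paper) s$fcr * s$processing_efficiency
                       else s$fcr / s$processing_efficiency
    req <- c(feed_per_edible * s$ration_energy,
             feed_per_edible * s$ration_protein)
    x <- solve(A, req)
    if (any(x < -1e-12)) {
      corn_only <- max(req[1] / corn["E"], req[2] / corn["P"])
      soy_only <- max(req[1] / soy["E"], req[2] / soy["P"])
      x <- if (corn_only <= soy_only) c(corn_only, 0) else c(0, soy_only)
      warning("exact blend for ", s$species_id, " is infeasible with ",
              "nonnegative ingredients; using least-excess single-",
              "ingredient ration", call. = FALSE)
    }
    x <- pmax(x, 0)
    out$energy_required[i] <- req[1]
    out$protein_required[i] <- req[2]
    out$corn_lb[i] <- x[1]
    out$soymeal_lb[i] <- x[2]
  }
  out
}

#' Expand animal-product demand into feed-commodity demand
#'
#' Livestock feed coefficients (lb of corn grain, corn silage, soybean
#' meal, hay, haylage, or grazed forage per lb of animal product) scale
#' linearly with animal-product demand. Dairy demand enters as the
#' fluid-milk commodity; farmed aquatic demand is expanded through the
#' two-ingredient nutritional solve scaled by edible pounds.
#'
#' @param demand a `commodity_demand` data.frame from
#'   [food_requirements()].
#' @param params a `food_system_parameters` object.
#' @param strict_paper_aquaculture logical, see
#'   [aquaculture_requirements()].
#' @return data.frame: `food_id`, `animal_product_id`,
#'   `feed_commodity_id`, `lb_yr` (lb/person/yr).
#' @export
livestock_feed_demand <- function(demand, params,
                                  strict_paper_aquaculture = FALSE) {
  fe <- params$feed
  sy <- params$system
  rows <- list()

  animal <- demand[demand$kind %in% c("animal", "dairy") & demand$lb_yr > 0, ]
  if (nrow(animal)) {
    if (length(miss <- setdiff(unique(animal$commodity_id),
                               fe$animal_product_id)))
      stop("no feed coefficients for animal product(s): ",
           paste(miss, collapse = ", "))
    for (i in seq_len(nrow(animal))) {
      co <- fe[fe$animal_product_id == animal$commodity_id[i], ]
      rows[[length(rows) + 1]] <- data.frame(
        food_id = animal$food_id[i],
        animal_product_id = animal$commodity_id[i],
        feed_commodity_id = co$feed_commodity_id,
        lb_yr = animal$lb_yr[i] * co$lb_feed_per_lb_product,
        stringsAsFactors = FALSE)
    }
  }

  aqua <- demand[demand$kind == "aquaculture" & demand$lb_yr > 0, ]
  if (nrow(aqua)) {
    req <- aquaculture_requirements(
      params$aquaculture[params$aquaculture$species_id %in%
                           aqua$commodity_id, , drop = FALSE],
      params$feed_nutrients, corn_id = sy$corn_commodity_id,
      soymeal_id = sy$soymeal_commodity_id,
      strict_paper = strict_paper_aquaculture)
    m <- match(aqua$commodity_id, req$species_id)
    for (i in seq_len(nrow(aqua))) {
      rows[[length(rows) + 1]] <- data.frame(
        food_id = aqua$food_id[i],
        animal_product_id = aqua$commodity_id[i],
        feed_commodity_id = c(sy$corn_commodity_id, sy$soymeal_commodity_id),
        lb_yr = aqua$lb_yr[i] * c(req$corn_lb[m[i]], req$soymeal_lb[m[i]]),
        stringsAsFactors = FALSE)
    }
  }

  if (!length(rows))
    return(data.frame(food_id = character(0),
                      animal_product_id = character(0),
                      feed_commodity_id = character(0), lb_yr = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-food trade balances
#'
#' In an open trade system each food's balance is beginning stock plus
#' imports minus exports (system-level lb/yr): a positive balance means
#' that much less domestic production is needed, a negative balance that
#' much more. The printed source equation sums exports with a plus sign,
#' contradicting its own narrative; the narrative convention (exports
#' subtracted) is the default and the printed form is available as
#' `sign = "printed"`. A closed system ignores trade entirely: all
#' balances are zero.
#'
#' @param params a `food_system_parameters` object (or its `trade` table).
#' @param mode `"open"` or `"closed"`.
#' @param sign `"narrative"` (default; exports subtracted) or
#'   `"printed"` (exports added).
#' @return data.frame: `food_id`, `balance` (lb/yr, system-level).
#' @export
trade_balance <- function(params, mode = c("open", "closed"),
                          sign = c("narrative", "printed")) {
  mode <- match.arg(mode)
  sign <- match.arg(sign)
  tr <- if (inherits(params, "food_system_parameters")) params$trade
        else params
  if (!nrow(tr))
    return(data.frame(food_id = character(0), balance = numeric(0),
                      stringsAsFactors = FALSE))
  bal <- if (mode == "closed") rep(0, nrow(tr))
         else tr$beginning_stock + tr$imports +
              if (sign == "printed") tr$exports else -tr$exports
  data.frame(food_id = tr$food_id, balance = bal, stringsAsFactors = FALSE)
}
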