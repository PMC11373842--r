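#' Reapportion preference shares within one food group
#'
#' Foods flagged non-producible cannot be grown in the study area; their
#' stated preference share is reapportioned to the producible foods of the
#' same group in proportion to those foods' own shares (equivalently, the
#' producible shares are renormalized to sum to 1). Non-producible foods
#' end with share 0.
#'
#' @param group_foods data.frame of food records for a single group
#'   (columns `producible`, `preference_share`).
#' @return the data.frame with updated `preference_share`.
#' @export
reapportion_preferences <- function(group_foods) {
  p <- group_foods$producible
  s <- group_foods$preference_share
  tot <- sum(s[p])
  if (!any(p) || tot <= 0)
    stop("food group '", group_foods$food_group[1],
         "' has no producible food with positive preference share; ",
         "its demand cannot be served")
  s[!p] <- 0
  s[p] <- s[p] / tot
  group_foods$preference_share <- s
  group_foods
}

#' Fluid-milk equivalent of a set of dairy intakes
#'
#' Two estimates of the fluid milk needed to supply a diet's dairy demand
#' are computed — one from fat solids, one from non-fat solids — and the
#' larger governs (the limiting dairy fraction):
#' `FM_fat = sum_i intake_i * fat_i / 0.037` and
#' `FM_nonfat = sum_i intake_i * nonfat_i / 0.086`, where 0.037 and 0.086
#' are the fat and non-fat solids proportions of fluid milk itself. The
#' non-limiting fraction's surplus is discarded, mirroring the max()
#' semantics of the source accounting.
#'
#' @param intake_lb named numeric: annual lb of each dairy food
#'   (as-consumed mass, losses and waste included).
#' @param compositions data.frame: `food_id`, `fat_solids`,
#'   `nonfat_solids`.
#' @param constants model constants list (provides the 0.037/0.086 pair).
#' @return list: `fm_fat`, `fm_nonfat`, `fm` (the max), `limiting`
#'   (`"fat"` or `"nonfat"`), and `per_food_fm` (each food's contribution
#'   under the limiting fraction; sums to `fm`).
#' @export
fluid_milk_equivalent <- function(intake_lb, compositions,
                                  constants = model_constants()) {
  intake_lb <- intake_lb[intake_lb > 0]
  if (!length(intake_lb))
    return(list(fm_fat = 0, fm_nonfat = 0, fm = 0, limiting = "fat",
                per_food_fm = numeric(0)))
  m <- match(names(intake_lb), compositions$food_id)
  if (anyNA(m))
    stop("missing dairy composition for: ",
         paste(names(intake_lb)[is.na(m)], collapse = ", "))
  fat <- compositions$fat_solids[m]
  nonfat <- compositions$nonfat_solids[m]
  fm_fat_i <- intake_lb * fat / constants$milk_fat
  fm_nonfat_i <- intake_lb * nonfat / constants$milk_nonfat
  fm_fat <- sum(fm_fat_i); fm_nonfat <- sum(fm_nonfat_i)
  limiting <- if (fm_fat >= fm_nonfat) "fat" else "nonfat"
  per_food <- if (limiting == "fat") fm_fat_i else fm_nonfat_i
  list(fm_fat = fm_fat, fm_nonfat = fm_nonfat,
       fm = max(fm_fat, fm_nonfat), limiting = limiting,
       per_food_fm = per_food)
}

#' Decompose fat-product demand into individual oils
#'
#' Processed fat products (salad dressing, cooking oil, margarine,
#' shortening, other) are blends of individual fats and oils; demand for a
#' product is split across its constituent oils by mass share. Mass is
#' conserved exactly.
#'
#' @param product_lb named numeric: annual lb demand per product.
#' @param fats_oils data.frame: `product_id`, `oil_id`, `share`.
#' @return named numeric: annual lb per oil.
#' @export
decompose_fats_oils <- function(product_lb, fats_oils) {
  product_lb <- product_lb[product_lb > 0]
  if (!length(product_lb)) return(stats::setNames(numeric(0), character(0)))
  if (length(miss <- setdiff(names(product_lb), fats_oils$product_id)))
    stop("no oil shares defined for product(s): ",
         paste(miss, collapse = ", "))
  sub <- fats_oils[fats_oils$product_id %in% names(product_lb), ]
  oil <- sub$share * product_lb[sub$product_id]
  tapply_num <- tapply(oil, sub$oil_id, sum)
  stats::setNames(as.numeric(tapply_num), names(tapply_num))
}

#' Convert a diet pattern to annual agricultural commodity demand
#'
#' The core mass conversion: daily food-group servings are disaggregated
#' to foods by preference share, converted to pounds via per-food serving
#' sizes, inflated for retail/inedible/cooking/consumer losses, and
#' converted to raw-commodity mass by processing coefficients:
#' `commodity_i = intake_i * serving_size_i / 454 * preference_i *
#' loss_waste_i * processing_i * 365`.
#'
#' Special routings:
#' \itemize{
#' \item dairy foods are pooled through the fluid-milk-equivalent
#'   limiting-fraction calculation, then converted to farm milk;
#' \item fat products are decomposed into individual oils (commodity rows
#'   carry the oil id; oilseed mass conversion happens at the land stage);
#' \item aquatic foods are split into a farmed share (agricultural) and a
#'   wild-caught share, carried but flagged non-agricultural;
#' \item animal foods become animal-product demand to be expanded into
#'   feed; lard/tallow demand enters the coproduct ledger.
#' }
#'
#' @param diet a `food_group_vector` (or named numeric of servings/day).
#' @param params a `food_system_parameters` object.
#' @param include_aquatic logical; when `FALSE`, all aquatic-food demand is
#'   treated as wild-caught (no agricultural resources).
#' @return data.frame of class `commodity_demand`: `food_id`,
#'   `food_group`, `commodity_id`, `kind` (crop, sweetener, dairy, animal,
#'   aquaculture, oil, lard), `agricultural` (logical), `lb_yr`
#'   (lb/person/yr). Attributes: `fm` (fluid-milk ledger), `product_lb`
#'   (fat-product demand), `diet`.
#' @export
food_requirements <- function(diet, params, include_aquatic = TRUE) {
  f <- params$foods
  cn <- params$constants
  sy <- params$system
  diet <- food_group_vector(stats::setNames(as.numeric(diet), names(diet)),
                            groups = names(diet))

  # groups with positive intake must be servable
  for (g in names(diet)[unclass(diet) > 0]) {
    idx <- f$food_group == g
    if (!any(idx) || !any(f$producible[idx]))
      stop("group '", g, "' has positive intake but no producible food")
  }

  m <- match(f$food_group, names(diet))
  group_serv <- ifelse(is.na(m), 0, unclass(diet)[m])
  servings <- group_serv * f$preference_share
  # annual as-consumed-equivalent pounds, losses and waste included
  base_lb <- servings * f$serving_size / cn$g_per_lb *
    f$loss_waste_factor * cn$days_per_year

  is_dairy <- f$food_id %in% params$dairy$food_id
  is_product <- f$commodity_id %in% params$fats_oils$product_id
  is_aqua <- f$commodity_id %in% params$aquaculture$species_id
  is_animal <- f$commodity_id %in% params$feed$animal_product_id & !is_aqua
  is_lard <- f$commodity_id == sy$lard_commodity_id
  is_sweet <- !is_dairy & !is_product & !is_aqua & !is_animal & !is_lard &
    f$commodity_id == sy$corn_commodity_id & f$food_group == "sweeteners"

  rows <- list()
  add <- function(food_id, food_group, commodity_id, kind, agricultural, lb)
    rows[[length(rows) + 1]] <<- data.frame(
      food_id = food_id, food_group = food_group,
      commodity_id = commodity_id, kind = kind,
      agricultural = agricultural, lb_yr = lb,
      stringsAsFactors = FALSE)

  # dairy pool -> fluid milk equivalent -> farm milk commodity
  dairy_intake <- stats::setNames(base_lb[is_dairy], f$food_id[is_dairy])
  fm <- fluid_milk_equivalent(dairy_intake, params$dairy, cn)
  if (length(fm$per_food_fm)) {
    dm <- match(names(fm$per_food_fm), f$food_id)
    add(names(fm$per_food_fm), f$food_group[dm],
        rep(sy$milk_commodity_id, length(dm)), "dairy", TRUE,
        fm$per_food_fm * sy$milk_processing_conversion)
  }

  # fat products -> oils
  prod_lb <- stats::setNames(base_lb[is_product] *
                               f$processing_conversion[is_product],
                             f$commodity_id[is_product])
  prod_lb <- tapply(prod_lb, names(prod_lb), sum)
  prod_lb <- stats::setNames(as.numeric(prod_lb), names(prod_lb))
  oil_lb <- decompose_fats_oils(prod_lb, params$fats_oils)
  if (length(oil_lb)) {
    # attribute oil rows to the products' foods proportionally
    for (oid in names(oil_lb)) {
      sub <- params$fats_oils[params$fats_oils$oil_id == oid, ]
      for (k in seq_len(nrow(sub))) {
        pfoods <- which(is_product & f$commodity_id == sub$product_id[k])
        pl <- base_lb[pfoods] * f$processing_conversion[pfoods]
        if (sum(pl) <= 0) next
        add(f$food_id[pfoods], f$food_group[pfoods], rep(oid, length(pfoods)),
            "oil", TRUE, pl * sub$share[k])
      }
    }
  }

  # aquatic: farmed vs wild split
  if (any(is_aqua)) {
    am <- match(f$commodity_id[is_aqua], params$aquaculture$species_id)
    fs <- params$aquaculture$farmed_share[am]
    if (!include_aquatic) fs <- rep(0, length(fs))
    edible <- base_lb[is_aqua] * f$processing_conversion[is_aqua]
    add(f$food_id[is_aqua], f$food_group[is_aqua], f$commodity_id[is_aqua],
        "aquaculture", TRUE, edible * fs)
    add(f$food_id[is_aqua], f$food_group[is_aqua], f$commodity_id[is_aqua],
        "wild_aquatic", FALSE, edible * (1 - fs))
  }

  plain <- !(is_dairy | is_product | is_aqua)
  kind <- ifelse(is_animal, "animal",
                 ifelse(is_lard, "lard",
                        ifelse(is_sweet, "sweetener", "crop")))
  if (any(plain))
    add(f$food_id[plain], f$food_group[plain], f$commodity_id[plain],
        kind[plain], TRUE, base_lb[plain] * f$processing_conversion[plain])

  out <- do.call(rbind, rows)
  out <- out[out$lb_yr > 0 | out$kind %in% c("crop", "sweetener"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, fm = fm, product_lb = prod_lb, diet = diet,
            class = c("commodity_demand", "data.frame"))
}
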