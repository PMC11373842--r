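#' Scenario configuration
#'
#' Bundles the run-level choices: population size, open vs closed trade,
#' whether farmed aquatic food counts as agricultural demand, the
#' trade-sign and aquaculture dimensional conventions (see
#' [trade_balance()] and [aquaculture_requirements()]), the RY convention
#' of the grazing adjustment, and whether the multiuse-crop ledger is
#' applied.
#'
#' @param population_size persons in the study area (> 0).
#' @param trade_mode `"closed"` (default) or `"open"`.
#' @param include_aquatic_food logical; `FALSE` routes all aquatic demand
#'   to the wild (non-agricultural) fraction.
#' @param strict_paper_aquaculture logical; multiplicative feed form.
#' @param trade_sign `"narrative"` or `"printed"`.
#' @param ry_convention `"as_printed"` or `"mass_balance"`.
#' @param ra_cropland `"all_uses"` or `"cultivated"`.
#' @param multiuse logical; apply the coproduct ledger.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(population_size = 1e5,
                            trade_mode = c("closed", "open"),
                            include_aquatic_food = TRUE,
                            strict_paper_aquaculture = FALSE,
                            trade_sign = c("narrative", "printed"),
                            ry_convention = c("as_printed", "mass_balance"),
                            ra_cropland = c("all_uses", "cultivated"),
                            multiuse = TRUE) {
  stopifnot(population_size > 0)
  structure(list(population_size = population_size,
                 trade_mode = match.arg(trade_mode),
                 include_aquatic_food = include_aquatic_food,
                 strict_paper_aquaculture = strict_paper_aquaculture,
                 trade_sign = match.arg(trade_sign),
                 ry_convention = match.arg(ry_convention),
                 ra_cropland = match.arg(ra_cropland),
                 multiuse = multiuse),
            class = "scenario_config")
}

#' Run the full model for one diet pattern
#'
#' Executes the stage chain: servings to commodity demand, feed expansion,
#' trade balances, multiuse-crop ledger, land requirements, land
#' availability, grazing reallocation, population fed / carrying
#' capacity, total land use, amendment use, and the nutrient summary.
#' Errors from a stage are rethrown with the stage name attached.
#'
#' @param diet a `food_group_vector` (servings/day).
#' @param params a `food_system_parameters` object.
#' @param config a `scenario_config`.
#' @return list of class `footprint_result` holding every intermediate:
#'   `demand`, `feed`, `trade`, `adjustment`, `land`, `availability`,
#'   `grazing`, `population_fed`, `carrying_capacity`, `land_use`,
#'   `amendments`, `nutrients`, `config`.
#' @export
run_single <- function(diet, params, config = scenario_config()) {
  stopifnot(inherits(params, "food_system_parameters"),
            inherits(config, "scenario_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  demand <- stage("commodity_flow",
                  food_requirements(diet, params,
                                    include_aquatic = config$include_aquatic_food))
  feed <- stage("feed_trade",
                livestock_feed_demand(demand, params,
                                      config$strict_paper_aquaculture))
  trade <- stage("feed_trade",
                 trade_balance(params, mode = config$trade_mode,
                               sign = config$trade_sign))
  adj <- if (config$multiuse)
    stage("land_engine", multiuse_adjustment(demand, feed, params))
  else .null_adjustment()
  land <- stage("land_engine",
                required_land(demand, feed, trade,
                              config$population_size, adj, params))
  avail <- stage("capacity_engine", land_availability(params$land_base))
  grazing <- stage("capacity_engine",
                   grazing_adjustment(land, avail, params,
                                      convention = config$ry_convention,
                                      ra_cropland = config$ra_cropland))
  pf <- stage("capacity_engine",
              population_fed(land, avail, grazing, config$population_size))
  lu <- stage("capacity_engine",
              total_land_use(land, grazing, avail$cropping_intensity,
                             config$population_size))
  amd <- stage("capacity_engine",
               amendment_use(land, params, config$population_size))
  nut <- stage("capacity_engine", nutrient_summary(diet, params))

  structure(list(diet = diet, demand = demand, feed = feed, trade = trade,
                 adjustment = adj, land = land, availability = avail,
                 grazing = grazing, population_fed = pf$population_fed,
                 carrying_capacity = pf$carrying_capacity, land_use = lu,
                 amendments = amd, nutrients = nut, config = config),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cn <- model_constants()
  cat("<footprint_result>\n")
  cat(sprintf("  trade: %s; population: %g\n", x$config$trade_mode,
              x$config$population_size))
  cat(sprintf("  land use: %.4f acres/person/yr (%.4f ha) | total %.0f acres\n",
              x$land_use$per_capita_acres,
              x$land_use$per_capita_acres * cn$acre_to_ha,
              x$land_use$total_acres))
  tot <- land_totals(x$land)
  cat(sprintf("    cultivated %.4f, forage %.4f, grazing %.4f acres/person\n",
              tot[["cultivated_cropland"]], tot[["cropland_pasture"]],
              tot[["permanent_pasture"]]))
  cat(sprintf("  population fed: %s\n",
              paste(sprintf("%s %.0f", names(x$population_fed),
                            x$population_fed), collapse = ", ")))
  cat(sprintf("  carrying capacity: %.3f%s\n", x$carrying_capacity,
              if (x$config$trade_mode == "open")
                " (open trade: interpret with caution)" else ""))
  amd <- x$amendments$per_capita
  cat(sprintf("  amendments/person: %s\n",
              paste(sprintf("%s %.3g", names(amd), amd), collapse = ", ")))
  cat(sprintf("  diet energy: %.0f kcal/day\n", x$nutrients[["energy_kcal"]]))
  invisible(x)
}

#' Per-capita resource totals of a result
#'
#' The four screened resources: total land (per-capita acres), fertilizer
#' nutrients (sum of N, P2O5, K2O, S), pesticides, and irrigation water.
#'
#' @param result a `footprint_result`.
#' @return named numeric: `land`, `fertilizer`, `pesticides`,
#'   `irrigation`.
#' @export
resource_totals <- function(result) {
  a <- result$amendments$per_capita
  c(land = result$land_use$per_capita_acres,
    fertilizer = sum(a[c("N", "P2O5", "K2O", "S")]),
    pesticides = a[["pesticides"]],
    irrigation = a[["irrigation"]])
}

#' Run the model over an individual-level survey
#'
#' Two-pass batch: every record that survives the age, reliability, and
#' zero-intake screens is run through the full model independently; the
#' 3-SD resource outlier screen is then applied to the per-record land,
#' fertilizer, and pesticide totals; survey-weighted summary statistics
#' are computed over the final sample. Records are independent (one
#' shared parameter set, no cross-record state), so output order follows
#' input order.
#'
#' @param records a `diet_survey` data.frame.
#' @param params a `food_system_parameters` object.
#' @param config a `scenario_config`.
#' @param outlier_sd SD multiple for the resource screen (default 3);
#'   `NA` disables the screen.
#' @return list of class `batch_result`: `totals` (one row per modelled
#'   record: resources, land components, amendments, energy), `kept`
#'   (participant ids of the final sample), `exclusions` (tally by
#'   reason), `excluded` (records with reasons), `summary`
#'   (weighted mean and quartiles per resource over the final sample).
#' @export
run_batch <- function(records, params, config = scenario_config(),
                      outlier_sd = 3) {
  groups <- attr(records, "groups") %||%
    setdiff(names(records), .diet_meta_cols)
  pre <- apply_exclusions(records)
  cand <- pre$kept
  if (!nrow(cand)) stop("no records survive the pre-model exclusions")

  seen <- new.env(parent = emptyenv())
  run_quiet <- function(diet) withCallingHandlers(
    run_single(diet, params, config),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (!is.null(seen[[msg]])) invokeRestart("muffleWarning")
      seen[[msg]] <- TRUE
    })

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    diet <- food_group_vector(
      stats::setNames(as.numeric(cand[i, groups]), groups), groups = groups)
    res <- run_quiet(diet)
    rt <- resource_totals(res)
    tot <- land_totals(res$land)
    rows[[i]] <- data.frame(
      participant_id = cand$participant_id[i],
      survey_weight = cand$survey_weight[i],
      land = rt[["land"]], fertilizer = rt[["fertilizer"]],
      pesticides = rt[["pesticides"]], irrigation = rt[["irrigation"]],
      cultivated_cropland = tot[["cultivated_cropland"]],
      cropland_pasture = tot[["cropland_pasture"]],
      permanent_pasture = tot[["permanent_pasture"]],
      grazing_net = res$land_use$grazing,
      rr_exceeds_ra = res$grazing$RR > res$grazing$RA,
      energy_kcal = res$nutrients[["energy_kcal"]],
      stringsAsFactors = FALSE)
  }
  totals <- do.call(rbind, rows)

  if (is.na(outlier_sd)) {
    ex <- pre
  } else {
    ex <- apply_exclusions(records, resources = totals,
                           sd_threshold = outlier_sd)
  }
  kept_ids <- ex$kept$participant_id
  kept_tot <- totals[totals$participant_id %in% kept_ids, , drop = FALSE]

  wmean <- function(x, w) sum(x * w) / sum(w)
  vars <- c("land", "fertilizer", "pesticides", "irrigation")
  summary <- do.call(rbind, lapply(vars, function(v) {
    x <- kept_tot[[v]]; w <- kept_tot$survey_weight
    data.frame(resource = v, weighted_mean = wmean(x, w), mean = mean(x),
               q25 = unname(stats::quantile(x, 0.25)),
               median = unname(stats::median(x)),
               q75 = unname(stats::quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))

  structure(list(totals = totals, kept = kept_ids, exclusions = ex$tally,
                 excluded = ex$excluded, summary = summary,
                 config = config),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat("<batch_result>\n")
  cat(sprintf("  %d records modelled; %d kept after exclusions\n",
              nrow(x$totals), length(x$kept)))
  tl <- x$exclusions[x$exclusions > 0 | names(x$exclusions) == "kept"]
  cat("  exclusions:", paste(sprintf("%s=%d", names(tl), tl),
                             collapse = ", "), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ---- report writers --------------------------------------------------------

.si_factor <- function(units) {
  cn <- model_constants()
  if (units == "si") c(area = cn$acre_to_ha, mass = cn$lb_to_kg,
                       water = cn$acreft_to_m3)
  else c(area = 1, mass = 1, water = 1)
}

#' Write single-run outputs to a directory
#'
#' Emits `summary.tsv` (totals: land by type, amendments, population fed,
#' carrying capacity, nutrients) and `expanded.tsv` (per-food,
#' per-land-type acres with amendment detail). Units are imperial (acres,
#' lb) or SI (ha, kg; irrigation acre-feet to cubic metres).
#'
#' @param result a `footprint_result`.
#' @param dir output directory (created if needed).
#' @param units `"imperial"` or `"si"`.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, units = c("imperial", "si")) {
  units <- match.arg(units)
  f <- .si_factor(units)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tot <- land_totals(result$land) * f[["area"]]
  amd <- result$amendments$per_capita
  amd[c("N", "P2O5", "K2O", "S", "pesticides")] <-
    amd[c("N", "P2O5", "K2O", "S", "pesticides")] * f[["mass"]]
  amd["irrigation"] <- amd[["irrigation"]] * f[["water"]]
  summ <- data.frame(
    quantity = c(paste0("land_", names(tot)), "land_use_per_capita",
                 "land_use_total",
                 paste0("amendment_", names(amd)),
                 paste0("population_fed_", names(result$population_fed)),
                 "carrying_capacity", names(result$nutrients)),
    value = c(tot, result$land_use$per_capita_acres * f[["area"]],
              result$land_use$total_acres * f[["area"]], amd,
              result$population_fed, result$carrying_capacity,
              result$nutrients),
    stringsAsFactors = FALSE)
  .write_tsv(summ, file.path(dir, "summary.tsv"))
  exp <- result$land
  exp$acres_pc <- exp$acres_pc * f[["area"]]
  .write_tsv(exp, file.path(dir, "expanded.tsv"))
  invisible(dir)
}

#' Write batch outputs to a directory
#'
#' Emits `totals.tsv` (per-participant resources), `summary.tsv`
#' (weighted summary over the final sample), and `exclusions.tsv`
#' (tally by reason).
#'
#' @param batch a `batch_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_batch <- function(batch, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(batch$totals, file.path(dir, "totals.tsv"))
  .write_tsv(batch$summary, file.path(dir, "summary.tsv"))
  .write_tsv(data.frame(reason = names(batch$exclusions),
                        n = as.integer(batch$exclusions),
                        stringsAsFactors = FALSE),
             file.path(dir, "exclusions.tsv"))
  invisible(dir)
}
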