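# Shared fixtures for the test suite. The MINI system is deterministic,
# so build it once; perturbation helpers derive randomized variants for
# the property suite.

MINI <- suppressMessages(make_mini_food_system())
MINI_DIET <- mini_reference_diet()
MINI_GROUPS <- MINI$groups$food_group

run_mini <- function(diet = MINI_DIET, params = MINI, ...) {
  suppressWarnings(run_single(diet, params, scenario_config(...)))
}

# Randomized MINI variant: jitter yields, loss/waste, serving sizes,
# feed coefficients and amendment rates; optionally randomize trade.
perturb_mini <- function(seed, trade = FALSE) {
  set.seed(seed)
  p <- suppressMessages(make_mini_food_system())
  jitter <- function(x, lo = 0.7, hi = 1.3) x * runif(length(x), lo, hi)
  p$yields$yield <- jitter(p$yields$yield)
  p$foods$loss_waste_factor <- 1 + jitter(p$foods$loss_waste_factor - 1)
  p$foods$serving_size <- jitter(p$foods$serving_size)
  p$feed$lb_feed_per_lb_product <- jitter(p$feed$lb_feed_per_lb_product)
  p$amendments$rate <- jitter(p$amendments$rate)
  if (trade) {
    p$trade <- data.frame(
      food_id = c("bread", "apple", "beef"),
      beginning_stock = runif(3, 0, 2e6),
      imports = runif(3, 0, 5e6),
      exports = runif(3, 0, 5e6),
      stringsAsFactors = FALSE)
  }
  validate_parameters(p, quiet = TRUE)
}

random_diet <- function(seed) {
  set.seed(seed)
  food_group_vector(
    stats::setNames(rexp(length(MINI_GROUPS), rate = 1), MINI_GROUPS),
    groups = MINI_GROUPS)
}

# quick survey data.frame builder for exclusion tests
make_records <- function(..., groups = MINI_GROUPS) {
  recs <- list(...)
  out <- do.call(rbind, lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    row <- data.frame(
      participant_id = r$id %||% sprintf("R%02d", i),
      age_years = r$age %||% 30,
      survey_weight = r$weight %||% 1,
      recall_reliable = r$reliable %||% TRUE,
      stringsAsFactors = FALSE)
    intake <- stats::setNames(rep(0, length(groups)), groups)
    if (!is.null(r$intake)) intake[names(r$intake)] <- r$intake
    cbind(row, as.data.frame(as.list(intake), check.names = FALSE))
  }))
  structure(out, groups = groups, class = c("diet_survey", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
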