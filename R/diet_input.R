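#' Construct a food-group intake vector
#'
#' Daily per-capita servings over a set of food groups. Groups absent from
#' `x` are filled with zero; entries must be nonnegative and finite.
#'
#' @param x named numeric vector of servings/day.
#' @param groups character vector of group codes defining the schema
#'   (default the canonical 22-group list).
#' @return named numeric vector of class `food_group_vector`.
#' @export
food_group_vector <- function(x = numeric(0), groups = food_groups_22) {
  if (length(extra <- setdiff(names(x), groups)))
    stop("unknown food group(s): ", paste(extra, collapse = ", "))
  v <- stats::setNames(numeric(length(groups)), groups)
  v[names(x)] <- as.numeric(x)
  if (any(!is.finite(v)) || any(v < 0))
    stop("food-group servings must be finite and >= 0")
  structure(v, class = c("food_group_vector", "numeric"))
}

.diet_meta_cols <- c("participant_id", "age_years", "survey_weight",
                     "recall_reliable")

#' Read an individual-level diet survey
#'
#' Reads a delimited table of one-day dietary recalls: one row per
#' participant with id, age, survey weight, a recall-reliability flag, and
#' one column of daily servings per food group. Unit conversion from raw
#' recall foods to food-group servings is an upstream contract (food
#' pattern equivalents); values here are taken at face value.
#'
#' @param path delimited file (TSV or CSV by extension).
#' @param groups food-group schema the file must cover.
#' @param schema optional named character vector mapping canonical column
#'   names (`participant_id`, `age_years`, `survey_weight`,
#'   `recall_reliable`, and group codes) to the file's column names.
#' @return data.frame of class `diet_survey`: metadata columns plus one
#'   numeric column per group.
#' @export
read_diet_survey <- function(path, groups = food_groups_22, schema = NULL) {
  if (!file.exists(path)) stop("diet survey file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  wanted <- c(.diet_meta_cols, groups)
  src <- stats::setNames(wanted, wanted)
  if (!is.null(schema)) src[names(schema)] <- schema
  if (length(miss <- setdiff(unname(src), names(raw))))
    stop("diet survey is missing required column(s): ",
         paste(miss, collapse = ", "))
  out <- stats::setNames(raw[, unname(src), drop = FALSE], wanted)
  for (g in groups) {
    out[[g]] <- as.numeric(out[[g]])
    if (any(is.na(out[[g]])))
      stop("non-numeric intake in column '", g, "'")
    if (any(out[[g]] < 0))
      stop("negative intake for group '", g, "' at row(s) ",
           paste(which(out[[g]] < 0), collapse = ", "))
  }
  out$age_years <- as.numeric(out$age_years)
  out$survey_weight <- as.numeric(out$survey_weight)
  out$recall_reliable <- as.logical(out$recall_reliable)
  if (any(out$survey_weight <= 0, na.rm = TRUE))
    stop("survey_weight must be > 0")
  structure(out, groups = groups, class = c("diet_survey", "data.frame"))
}

#' Write a diet survey to a delimited file
#' @param records a `diet_survey` data.frame.
#' @param path output path (TSV or CSV by extension).
#' @return `path`, invisibly.
#' @export
write_diet_survey <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(records), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply the analytic exclusion rules to a diet survey
#'
#' Applies, in order: (1) age under 1 year; (2) unreliable dietary recall;
#' (3) zero intake of every modelled food group; (4) optionally, any
#' agricultural resource use (land, summed fertilizer nutrients, or
#' pesticides — irrigation deliberately not screened) more than
#' `sd_threshold` standard deviations above or below the post-(1)-(3)
#' sample mean. The outlier screen is a single pass with unweighted mean
#' and SD; it requires per-record resource totals from a first model pass.
#'
#' @param records a `diet_survey` data.frame.
#' @param resources optional data.frame with `participant_id`, `land`,
#'   `fertilizer`, `pesticides` (one row per kept candidate); required for
#'   the outlier screen.
#' @param sd_threshold numeric, default 3.
#' @return list with `kept` (the surviving records), `excluded`
#'   (records plus `exclusion_reason`), and `tally` (named integer vector
#'   by reason, including `kept`).
#' @export
apply_exclusions <- function(records, resources = NULL, sd_threshold = 3) {
  groups <- attr(records, "groups") %||%
    setdiff(names(records), .diet_meta_cols)
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  reason[is.na(reason) & records$age_years < 1] <- "age<1"
  reason[is.na(reason) & !records$recall_reliable] <- "unreliable recall"
  intake <- as.matrix(records[, groups, drop = FALSE])
  reason[is.na(reason) & rowSums(intake) == 0] <- "no model food groups"

  if (!is.null(resources)) {
    need <- c("participant_id", "land", "fertilizer", "pesticides")
    if (length(miss <- setdiff(need, names(resources))))
      stop("resource totals for the outlier screen must include: ",
           paste(miss, collapse = ", "))
    cand <- which(is.na(reason))
    m <- match(records$participant_id[cand], resources$participant_id)
    if (anyNA(m))
      stop("outlier screen requested but resource totals are missing for ",
           sum(is.na(m)), " record(s)")
    out <- rep(FALSE, length(cand))
    for (v in c("land", "fertilizer", "pesticides")) {
      x <- resources[[v]][m]
      mu <- mean(x); sdv <- stats::sd(x)
      if (is.finite(sdv) && sdv > 0)
        out <- out | abs(x - mu) > sd_threshold * sdv
    }
    reason[cand[out]] <- "resource outlier"
  }

  keep <- is.na(reason)
  tally <- c(table(factor(reason[!keep],
                          levels = c("age<1", "unreliable recall",
                                     "no model food groups",
                                     "resource outlier"))),
             kept = sum(keep))
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], excluded = excluded,
       tally = tally)
}

#' Population-mean diet of a survey
#'
#' Arithmetic or survey-weighted mean servings per food group, giving the
#' population-level intake vector used for population-vs-individual
#' comparisons.
#'
#' @param records a `diet_survey` data.frame (nonempty).
#' @param weighted logical; use `survey_weight` as weights.
#' @return a `food_group_vector`.
#' @export
population_mean_diet <- function(records, weighted = FALSE) {
  if (nrow(records) == 0) stop("cannot average an empty record list")
  groups <- attr(records, "groups") %||%
    setdiff(names(records), .diet_meta_cols)
  intake <- as.matrix(records[, groups, drop = FALSE])
  w <- if (weighted) records$survey_weight else rep(1, nrow(records))
  food_group_vector(colSums(intake * w) / sum(w), groups = groups)
}
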