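# Food-log ingestion, validation, per-day aggregation and quality-control
# filtering. A food log is a long table of eating events; the per-day table
# derived from it feeds every diet metric in the package.

#' Nutrient columns carried by a food log
#'
#' Names of the per-event nutrient columns recognized by [aggregate_daily()].
#' Macronutrients and food groups are tracked in g/day; micronutrients in
#' mg/day or ug/day as conventional for dietary reference values.
#'
#' @return Character vector of column names.
#' @export
nutrient_columns <- function() {
  c("fiber", "protein", "fat", "carbohydrate", "sfa", "mufa", "pufa",
    "sodium", "added_sugar", "potassium", "magnesium", "folate", "iron",
    "calcium", "phosphorus", "zinc", "vitamin_c", "niacin", "alcohol")
}

#' Default food-group vocabulary
#'
#' The closed set of food-group labels used by the synthetic generator and the
#' shipped diet-quality configuration: vegetables, fruits, meat, dairy,
#' grains/cereals, oils/nuts, sugary foods, fast food, coffee and a catch-all.
#'
#' @return Character vector of group labels.
#' @export
food_group_vocabulary <- function() {
  c("vegetables", "fruits", "meat", "dairy", "grains_cereals", "oils_nuts",
    "sugary_foods", "fast_food", "coffee", "others")
}

#' Read a food log from TSV/CSV
#'
#' Expects long-format eating events with at least `participant_id`, `date`,
#' `item_id`, `food_group`, `grams` and `kcal` columns; any of the
#' [nutrient_columns()] present are carried along. The separator is sniffed by
#' [data.table::fread()].
#'
#' @param path Path to a delimited text file.
#' @param groups Allowed food-group labels.
#' @return A validated `data.table` food log.
#' @export
read_food_log <- function(path, groups = food_group_vocabulary()) {
  log <- data.table::fread(path)
  validate_food_log(log, groups = groups)
}

#' Validate a food log
#'
#' Checks required columns, non-negative grams and kcal, parseable ISO dates,
#' and that every `food_group` label belongs to the declared vocabulary
#' (unknown labels are reported verbatim).
#'
#' @param log A data.frame/data.table of eating events.
#' @param groups Allowed food-group labels.
#' @return The log as a `data.table` with `date` normalized to `Date`.
#' @export
validate_food_log <- function(log, groups = food_group_vocabulary()) {
  log <- data.table::as.data.table(log)
  required <- c("participant_id", "date", "item_id", "food_group", "grams", "kcal")
  missing_cols <- setdiff(required, names(log))
  if (length(missing_cols)) {
    stop("food log is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(log)) {
    if (!inherits(log$date, "Date")) {
      dates <- as.Date(as.character(log$date))
      if (anyNA(dates)) stop("food log contains unparseable dates", call. = FALSE)
      data.table::set(log, j = "date", value = dates)
    }
    if (any(log$grams < 0, na.rm = TRUE) || any(log$kcal < 0, na.rm = TRUE)) {
      stop("grams and kcal must be non-negative", call. = FALSE)
    }
    bad <- setdiff(unique(log$food_group), groups)
    if (length(bad)) {
      stop("unknown food_group label(s): ", paste(sort(bad), collapse = ", "),
           call. = FALSE)
    }
  }
  log[]
}

#' Aggregate a food log to per participant-day intakes
#'
#' Sums grams, energy and nutrients over all eating events of a participant-day
#' and spreads food-group intakes into `<group>` (grams) and `kcal_<group>`
#' (energy) columns. A tracked day is any day with at least one logged event;
#' groups not eaten that day contribute 0 g, so day-to-day series are complete
#' over tracking days. Missing nutrient cells are treated as 0 and their count
#' reported via a message.
#'
#' @param log A validated food log (see [validate_food_log()]).
#' @param groups Food-group vocabulary defining the wide columns.
#' @return A `data.table` with one row per participant-day: `participant_id`,
#'   `date`, `energy_kcal`, `eaten_g`, per-group gram and kcal columns, and
#'   summed nutrient columns.
#' @export
aggregate_daily <- function(log, groups = food_group_vocabulary()) {
  log <- validate_food_log(log, groups = groups)
  nut <- intersect(nutrient_columns(), names(log))
  empty <- data.table::data.table(
    participant_id = character(), date = as.Date(character()),
    energy_kcal = numeric(), eaten_g = numeric()
  )
  for (g in groups) data.table::set(empty, j = g, value = numeric())
  for (g in groups) data.table::set(empty, j = paste0("kcal_", g), value = numeric())
  for (nm in nut) data.table::set(empty, j = nm, value = numeric())
  if (!nrow(log)) return(empty[])

  n_missing <- sum(vapply(log[, c("grams", "kcal", nut), with = FALSE],
                          function(x) sum(is.na(x)), integer(1)))
  if (n_missing > 0) {
    message(sprintf("aggregate_daily: %d missing cells treated as 0", n_missing))
    log <- data.table::copy(log)
    for (cl in c("grams", "kcal", nut)) {
      v <- log[[cl]]
      v[is.na(v)] <- 0
      data.table::set(log, j = cl, value = as.double(v))
    }
  }
  totals <- log[, c(list(energy_kcal = sum(kcal), eaten_g = sum(grams)),
                    lapply(.SD, sum)),
                by = .(participant_id, date), .SDcols = nut]
  byg <- log[, .(g = sum(grams), k = sum(kcal)),
             by = .(participant_id, date, food_group)]
  wide_g <- data.table::dcast(byg, participant_id + date ~ food_group,
                              value.var = "g", fill = 0)
  wide_k <- data.table::dcast(byg, participant_id + date ~ food_group,
                              value.var = "k", fill = 0)
  for (g in setdiff(groups, names(wide_g))) {
    data.table::set(wide_g, j = g, value = 0)
    data.table::set(wide_k, j = g, value = 0)
  }
  data.table::setnames(wide_k, groups, paste0("kcal_", groups))
  out <- Reduce(function(a, b) merge(a, b, by = c("participant_id", "date")),
                list(totals, wide_g[, c("participant_id", "date", groups), with = FALSE],
                     wide_k))
  data.table::setcolorder(out, c("participant_id", "date", "energy_kcal",
                                 "eaten_g", groups, paste0("kcal_", groups), nut))
  data.table::setkey(out, participant_id, date)
  out[]
}

#' Quality-control filter for per-day intakes
#'
#' Drops tracking days whose total energy is below `min_kcal` (default
#' 1000 kcal), then drops participants left with fewer than `min_days` days
#' (default 6, i.e. participants with 5 or fewer remaining days are excluded
#' entirely). The exclusion report is attached as the `"exclusions"` attribute
#' and retrievable with [qc_exclusions()]; it reconciles exactly
#' (`days_total == days_kept + days_low_energy`).
#'
#' @param daily Output of [aggregate_daily()].
#' @param min_kcal Minimum energy for a day to count as tracked.
#' @param min_days Minimum number of remaining days to keep a participant.
#' @return Filtered `data.table` with an `"exclusions"` attribute.
#' @export
qc_filter <- function(daily, min_kcal = 1000, min_days = 6) {
  daily <- data.table::as.data.table(daily)
  if (!nrow(daily)) {
    warning("qc_filter: empty input")
    report <- data.table::data.table(participant_id = character(),
                                     days_total = integer(),
                                     days_low_energy = integer(),
                                     days_kept = integer(),
                                     excluded = logical(), reason = character())
    data.table::setattr(daily, "exclusions", report)
    return(daily)
  }
  report <- daily[, .(days_total = .N,
                      days_low_energy = sum(energy_kcal < min_kcal)),
                  by = participant_id]
  report[, days_kept := days_total - days_low_energy]
  report[, excluded := days_kept < min_days]
  report[, reason := data.table::fifelse(
    excluded, sprintf("fewer than %d days with >= %g kcal", min_days, min_kcal), "")]
  kept_ids <- report[excluded == FALSE, participant_id]
  out <- daily[energy_kcal >= min_kcal & participant_id %in% kept_ids]
  if (!nrow(out)) warning("qc_filter: no participant-days remain after filtering")
  data.table::setattr(out, "exclusions", report[])
  out[]
}

#' Exclusion report of a QC-filtered table
#'
#' @param daily A table returned by [qc_filter()].
#' @return Per-participant exclusion report (`data.table`).
#' @export
qc_exclusions <- function(daily) {
  rep <- attr(daily, "exclusions", exact = TRUE)
  if (is.null(rep)) stop("no exclusion report attached; was qc_filter() applied?")
  rep
}
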