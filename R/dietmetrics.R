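# Diet-quality scoring (Healthy Eating Index), dietary-regularity CV metrics
# and dietary diversity indices, computed per participant from the QC'd
# per-day intake table.
#
# The scoring engine is standard-agnostic: a component set is a list of
# adequacy/moderation components with density cut-points, loaded from a YAML
# config. HEI-2020 ships as the default set; alternative indices (aMED, DASH)
# can be expressed in the same config format without code changes.

#' Load a diet-index component configuration
#'
#' Reads a YAML component set (see `inst/extdata/hei2020.yaml`) and validates
#' it: adequacy components need `full_score_at > zero_score_at`, moderation
#' components the reverse, and the HEI-2020 set must total 100 points.
#'
#' @param path YAML file; defaults to the shipped HEI-2020 standard.
#' @return A list of component specs, class `diet_components`.
#' @export
read_component_specs <- function(path = system.file("extdata", "hei2020.yaml",
                                                    package = "dietrhythm")) {
  cfg <- yaml::read_yaml(path)
  specs <- cfg$components
  if (!length(specs)) stop("component config contains no components")
  for (sp in specs) {
    for (fld in c("name", "direction", "max_points", "density_basis",
                  "numerator", "full_score_at", "zero_score_at")) {
      if (is.null(sp[[fld]])) stop("component missing field: ", fld)
    }
    validate_component_spec(sp)
  }
  total <- sum(vapply(specs, `[[`, numeric(1), "max_points"))
  if (identical(cfg$version, "HEI-2020") && total != 100) {
    stop("HEI-2020 component points must sum to 100, got ", total)
  }
  structure(specs, class = "diet_components",
            version = cfg$version %||% "custom", total_points = total)
}

validate_component_spec <- function(spec) {
  if (!spec$direction %in% c("adequacy", "moderation")) {
    stop("component direction must be adequacy or moderation: ", spec$name)
  }
  if (spec$direction == "adequacy" && spec$full_score_at <= spec$zero_score_at) {
    stop("adequacy component needs full_score_at > zero_score_at: ", spec$name)
  }
  if (spec$direction == "moderation" && spec$full_score_at >= spec$zero_score_at) {
    stop("moderation component needs full_score_at < zero_score_at: ", spec$name)
  }
  if (spec$max_points <= 0) stop("max_points must be positive: ", spec$name)
  invisible(spec)
}

#' Score one component from a density
#'
#' Linear interpolation between the zero-score and full-score thresholds,
#' clamped to `[0, max_points]`. Adequacy components increase with density,
#' moderation components decrease. Infinite densities (e.g. a fatty-acid ratio
#' with zero saturated fat but positive unsaturated fat) saturate an adequacy
#' component; an undefined 0/0 ratio scores 0.
#'
#' @param density Density value(s) on the component's basis.
#' @param spec A single component spec.
#' @return Numeric score(s) in `[0, max_points]`.
#' @export
score_component <- function(density, spec) {
  validate_component_spec(spec)
  d <- as.double(density)
  d[is.nan(d)] <- spec$zero_score_at # 0/0 ratio degeneracy scores 0 points
  frac <- if (spec$direction == "adequacy") {
    (d - spec$zero_score_at) / (spec$full_score_at - spec$zero_score_at)
  } else {
    (spec$zero_score_at - d) / (spec$zero_score_at - spec$full_score_at)
  }
  frac[is.nan(frac)] <- 0 # Inf - Inf style degeneracies
  spec$max_points * pmin(pmax(frac, 0), 1)
}

# Evaluate a component's density for each row of a per-day (or per-mean)
# intake table. The numerator is an arithmetic expression over columns.
component_density <- function(intake, spec) {
  num <- eval(parse(text = spec$numerator), envir = intake)
  switch(spec$density_basis,
    "per-1000-kcal" = num / (intake$energy_kcal / 1000),
    "percent-of-energy" = 100 * num / intake$energy_kcal,
    "ratio" = num,
    stop("unknown density_basis: ", spec$density_basis)
  )
}

# Total index score for each row of an intake table.
score_intake_rows <- function(intake, specs) {
  if (any(intake$energy_kcal <= 0)) stop("cannot score rows with zero energy")
  total <- numeric(nrow(intake))
  for (sp in specs) total <- total + score_component(component_density(intake, sp), sp)
  total
}

#' Standard HEI: one score from across-day mean intakes
#'
#' Each participant's intakes (including energy) are averaged across their
#' QC'd tracking days first; densities and component scores are then computed
#' once from those means.
#'
#' @param daily QC'd per-day intake table ([qc_filter()]).
#' @param specs Component set from [read_component_specs()].
#' @return `data.table` with `participant_id` and `hei`.
#' @export
hei_standard <- function(daily, specs = read_component_specs()) {
  daily <- data.table::as.data.table(daily)
  num_cols <- setdiff(names(daily)[vapply(daily, is.numeric, logical(1))], NULL)
  # base mean (long-double accumulation) so a constant diet's across-day mean
  # reproduces the daily values exactly, keeping the day-wise == standard
  # identity bit-exact on constant diets
  means <- daily[, lapply(.SD, function(x) mean(x)),
                 by = participant_id, .SDcols = num_cols]
  means[, .(participant_id, hei = score_intake_rows(.SD, specs)),
        .SDcols = num_cols][]
}

#' Day-wise HEI: mean of per-day scores
#'
#' Scores every QC'd tracking day separately on that day's densities and
#' averages the day scores per participant; the per-day series is returned
#' alongside. With a perfectly constant diet this equals [hei_standard()]
#' exactly; with variable diets it additionally penalizes irregular quality.
#'
#' @inheritParams hei_standard
#' @return List with `score` (`participant_id`, `hei_daily`) and `days`
#'   (`participant_id`, `date`, `hei_day`).
#' @export
hei_daily <- function(daily, specs = read_component_specs()) {
  daily <- data.table::as.data.table(daily)
  days <- daily[, .(participant_id, date)]
  days[, hei_day := score_intake_rows(daily, specs)]
  score <- days[, .(hei_daily = (function(x) mean(x))(hei_day)),
                by = participant_id]
  list(score = score[], days = days[])
}

#' Coefficient of variation of a per-day series
#'
#' `CV = sample SD / mean * 100` (n-1 denominator), the day-to-day regularity
#' metric: higher CV means more irregular consumption. Undefined (returned as
#' `NA`) when the mean is 0 or fewer than 2 days are available.
#'
#' @param series Numeric vector of per-day amounts over tracking days
#'   (zero-intake days included).
#' @return CV in percent, or `NA_real_`.
#' @export
compute_cv <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) < 2) return(NA_real_)
  m <- mean(series)
  if (m == 0) return(NA_real_)
  100 * stats::sd(series) / m
}

#' Per-participant CV table
#'
#' Computes [compute_cv()] for each listed per-day variable of the intake
#' table, one column `cv_<variable>` per variable.
#'
#' @param daily QC'd per-day intake table.
#' @param variables Column names to compute CVs for.
#' @return `data.table` keyed by `participant_id`.
#' @export
cv_table <- function(daily, variables) {
  daily <- data.table::as.data.table(daily)
  missing_v <- setdiff(variables, names(daily))
  if (length(missing_v)) stop("unknown variables: ", paste(missing_v, collapse = ", "))
  out <- daily[, lapply(.SD, compute_cv), by = participant_id, .SDcols = variables]
  data.table::setnames(out, variables, paste0("cv_", variables))
  out[]
}

#' Daily dietary diversity indices
#'
#' Per tracking day, food-group kilocalorie shares `p_g` yield the dietary
#' diversity score (number of groups above an intake threshold, default
#' any positive grams), Shannon diversity `-sum(p log p)` in nats and the
#' Gini-Simpson index `1 - sum(p^2)`; participant values are across-day means.
#'
#' @param daily QC'd per-day intake table with `kcal_<group>` columns.
#' @param groups Food-group names.
#' @param dds_threshold Grams above which a group counts towards the DDS.
#' @return `data.table` with `participant_id`, `dds_mean`,
#'   `diet_shannon_mean`, `gini_simpson_mean`.
#' @export
diet_diversity_daily <- function(daily, groups = food_group_vocabulary(),
                                 dds_threshold = 0) {
  daily <- data.table::as.data.table(daily)
  kc <- paste0("kcal_", groups)
  if (!all(kc %in% names(daily))) stop("missing kcal_<group> columns")
  kmat <- as.matrix(daily[, kc, with = FALSE])
  gmat <- as.matrix(daily[, groups, with = FALSE])
  tot <- rowSums(kmat)
  if (any(tot <= 0)) stop("day with zero kcal cannot be scored (apply qc_filter first)")
  p <- kmat / tot
  shannon <- -rowSums(ifelse(p > 0, p * log(p), 0))
  gini <- 1 - rowSums(p^2)
  dds <- rowSums(gmat > dds_threshold)
  per_day <- data.table::data.table(participant_id = daily$participant_id,
                                    dds = dds, shannon = shannon, gini = gini)
  per_day[, .(dds_mean = mean(dds), diet_shannon_mean = mean(shannon),
              gini_simpson_mean = mean(gini)), by = participant_id][]
}

#' Full per-participant diet profile
#'
#' Orchestrates the module: standard and day-wise HEI, dietary diversity
#' means, mean intakes, and CVs for the requested variables plus the CV of the
#' per-day HEI series (`cv_hei`, day-to-day diet-quality regularity).
#'
#' @param daily QC'd per-day intake table.
#' @param specs Component set.
#' @param cv_variables Per-day columns to compute CVs for; defaults to all
#'   food groups, energy and the logged nutrients.
#' @param groups Food-group vocabulary.
#' @return One-row-per-participant `data.table` (the diet profile).
#' @export
diet_profile <- function(daily, specs = read_component_specs(),
                         cv_variables = NULL,
                         groups = food_group_vocabulary()) {
  daily <- data.table::as.data.table(daily)
  if (is.null(cv_variables)) {
    cv_variables <- intersect(c(groups, "energy_kcal", nutrient_columns()),
                              names(daily))
  }
  hs <- hei_standard(daily, specs)
  hd <- hei_daily(daily, specs)
  dd <- diet_diversity_daily(daily, groups = groups)
  cvs <- cv_table(daily, cv_variables)
  cv_hei <- hd$days[, .(cv_hei = compute_cv(hei_day)), by = participant_id]
  mean_cols <- intersect(c("energy_kcal", "eaten_g", groups, nutrient_columns()),
                         names(daily))
  means <- daily[, lapply(.SD, mean), by = participant_id, .SDcols = mean_cols]
  out <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                list(hs, hd$score, dd, cv_hei, cvs, means))
  data.table::setattr(out, "hei_days", hd$days)
  out[]
}
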