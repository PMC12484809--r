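# Stool-quality features from daily self-reports: per-participant category
# proportions, top-k classification, and correlations against diet,
# microbiome and lifestyle variables.

stool_categories <- function() c("great", "normal", "constipated", "diarrhea")

#' Validate stool reports
#'
#' Requires `participant_id`, `date`, `category` columns, categories from the
#' closed vocabulary, and at most one report per participant-day.
#'
#' @param reports A data.frame/data.table of daily stool reports.
#' @return `data.table` of validated reports.
#' @export
validate_stool_reports <- function(reports) {
  reports <- data.table::as.data.table(reports)
  need <- c("participant_id", "date", "category")
  if (!all(need %in% names(reports))) {
    stop("stool reports need columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(reports$category), stool_categories())
  if (length(bad)) stop("unknown stool categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(reports[, .(participant_id, date)])) {
    stop("more than one stool report for some participant-day")
  }
  reports[]
}

#' Per-participant stool-quality proportions
#'
#' Participants with fewer than `min_days` reported days are excluded; for the
#' rest, each category's proportion is its reported-day count over all
#' reported days (so the four proportions always sum to 1).
#'
#' @param reports Validated stool reports.
#' @param min_days Minimum reported days (default 5).
#' @return `data.table`: `participant_id`, `n_reported_days`,
#'   `great_proportion`, `normal_proportion`, `constipated_proportion`,
#'   `diarrhea_proportion`.
#' @export
stool_proportions <- function(reports, min_days = 5) {
  reports <- validate_stool_reports(reports)
  out <- reports[, .(
    n_reported_days = .N,
    great_proportion = mean(category == "great"),
    normal_proportion = mean(category == "normal"),
    constipated_proportion = mean(category == "constipated"),
    diarrhea_proportion = mean(category == "diarrhea")
  ), by = participant_id]
  out[n_reported_days >= min_days][]
}

#' Classify participants by stool quality
#'
#' Ranks participants by category proportions and labels the top `k_extreme`
#' by diarrhea proportion as "diarrhea", the top `k_extreme` of the remainder
#' by constipated proportion as "constipated", the top `k_great` of the
#' remainder by great proportion as "great", and everyone else "normal".
#' Extreme/great labels require a strictly positive proportion; ties at the
#' k-th rank break by participant ID. The precedence (diarrhea over
#' constipated over great) resolves multi-category overlaps in favour of the
#' clinically salient signal.
#'
#' @param profiles Output of [stool_proportions()].
#' @param k_great,k_extreme Label quotas (defaults 50 and 20).
#' @return `profiles` with a `label` column added.
#' @export
classify_stool_users <- function(profiles, k_great = 50, k_extreme = 20) {
  profiles <- data.table::as.data.table(data.table::copy(profiles))
  if (nrow(profiles) < k_great + 2 * k_extreme) {
    warning("fewer participants than k_great + 2 * k_extreme; labels will be sparse")
  }
  profiles[, label := NA_character_]
  take_top <- function(prop_col, k, lab) {
    pool <- profiles[is.na(label) & profiles[[prop_col]] > 0]
    if (!nrow(pool)) return(invisible(NULL))
    data.table::setorderv(pool, c(prop_col, "participant_id"), c(-1, 1))
    chosen <- head(pool$participant_id, k)
    profiles[participant_id %in% chosen, label := lab]
    invisible(NULL)
  }
  take_top("diarrhea_proportion", k_extreme, "diarrhea")
  take_top("constipated_proportion", k_extreme, "constipated")
  take_top("great_proportion", k_great, "great")
  profiles[is.na(label), label := "normal"]
  profiles[]
}

#' Correlate stool features with cohort variables
#'
#' Spearman correlations of `great_proportion` and `diarrhea_proportion`
#' against every numeric column of the analysis frame, reported in full plus
#' filtered at `|r| >= min_abs_r`.
#'
#' @param profiles Stool profiles.
#' @param frame Analysis frame keyed by `participant_id`.
#' @param min_abs_r Report filter (default 0.15).
#' @return List with `full` and `filtered` correlation tables.
#' @export
stool_associations <- function(profiles, frame, min_abs_r = 0.15) {
  profiles <- data.table::as.data.table(profiles)
  frame <- data.table::as.data.table(frame)
  merged <- merge(profiles, frame, by = "participant_id")
  if (nrow(merged) < 10) warning("fewer than 10 merged participants")
  feats <- setdiff(names(frame)[vapply(frame, is.numeric, logical(1))],
                   "participant_id")
  rows <- list()
  for (target in c("great_proportion", "diarrhea_proportion")) {
    for (f in feats) {
      ok <- stats::complete.cases(merged[[target]], merged[[f]])
      if (sum(ok) < 3 || stats::sd(merged[[f]][ok]) == 0) next
      ct <- suppressWarnings(stats::cor.test(merged[[target]][ok],
                                             merged[[f]][ok],
                                             method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        target = target, feature = f, rho = unname(ct$estimate),
        p = ct$p.value, n = sum(ok))
    }
  }
  full <- data.table::rbindlist(rows)
  list(full = full[], filtered = full[abs(full$rho) >= min_abs_r][])
}
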