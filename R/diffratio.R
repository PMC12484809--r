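# Per-taxon differential effects against a dietary variable, credible-taxon
# reference-frame selection, and sign-grouped log ratios.
#
# The effect estimator is a bootstrap surrogate for a Bayesian negative
# binomial mixed model: per taxon, the OLS slope of CLR abundance on the
# z-scored variable, with a 95% percentile interval over sample-level
# bootstrap resamples. With one sample per subject the random-effects
# structure of the original model is not identifiable anyway, and externally
# computed effect tables can be ingested via read_effect_table(), after which
# the log-ratio stage is identical.

#' Estimate per-taxon differential effects
#'
#' For each taxon, the slope of its CLR-transformed abundance on the
#' standardized variable (effect per 1 SD, CLR units). `mean_effect` is the
#' mean over `n_boot` sample-level bootstrap resamples; `interval_low`/
#' `interval_high` are the 2.5/97.5 bootstrap percentiles, and a taxon is
#' `credible` when that interval excludes zero.
#'
#' @param table Prevalence-filtered samples x taxa count matrix (raw counts).
#' @param variable Numeric per-sample values, aligned with rows; must vary.
#' @param n_boot Bootstrap resamples (default 500; < 100 warns).
#' @param seed Integer seed.
#' @param pseudocount CLR pseudocount.
#' @return `data.table`: `taxon`, `mean_effect`, `interval_low`,
#'   `interval_high`, `credible`.
#' @export
estimate_effects <- function(table, variable, n_boot = 500, seed = 1,
                             pseudocount = 1) {
  table <- validate_feature_table(table)
  n <- nrow(table)
  if (length(variable) != n) stop("variable length must match sample count")
  keep <- !is.na(variable)
  table <- table[keep, , drop = FALSE]
  variable <- variable[keep]
  n <- nrow(table)
  if (stats::sd(variable) == 0) stop("variable is constant")
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals")
  Z <- clr_transform(table, pseudocount)
  slope <- function(idx) {
    v <- variable[idx]
    vc <- v - mean(v)
    # population-SD standardization: exactly invariant under sample duplication
    s <- sqrt(mean(vc^2))
    if (s == 0) return(rep(NA_real_, ncol(Z)))
    vc <- vc / s
    as.numeric(crossprod(Z[idx, , drop = FALSE], vc) / sum(vc^2))
  }
  boots <- with_rng(substream_seed(seed, "effects"), {
    vapply(seq_len(n_boot), function(b) slope(sample.int(n, n, replace = TRUE)),
           numeric(ncol(Z)))
  })
  qs <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.table::data.table(
    taxon = colnames(Z),
    mean_effect = rowMeans(boots, na.rm = TRUE),
    interval_low = qs[1, ],
    interval_high = qs[2, ]
  )
  out[, credible := interval_low > 0 | interval_high < 0]
  out[]
}

#' Read an externally computed effect table
#'
#' TSV with columns `taxon`, `mean_effect`, `interval_low`, `interval_high`
#' (and optionally `credible`, recomputed if absent), e.g. posterior summaries
#' from a Bayesian differential-abundance model.
#'
#' @param path TSV path.
#' @return Effect `data.table` as from [estimate_effects()].
#' @export
read_effect_table <- function(path) {
  out <- data.table::fread(path)
  need <- c("taxon", "mean_effect", "interval_low", "interval_high")
  if (!all(need %in% names(out))) {
    stop("effect table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(out$interval_low > out$mean_effect | out$mean_effect > out$interval_high)) {
    stop("effect table violates interval_low <= mean_effect <= interval_high")
  }
  if (!"credible" %in% names(out)) {
    out[, credible := interval_low > 0 | interval_high < 0]
  }
  out[]
}

#' Select numerator/denominator reference frames
#'
#' Among credible taxa, takes the `top_k` by absolute mean effect (ties broken
#' by taxon ID) and splits them by effect sign: positive associations form the
#' numerator group, negative the denominator group.
#'
#' @param effects Effect table.
#' @param top_k Number of credible taxa to retain (default 100).
#' @param variable_name Used in error messages.
#' @return List with `numerator` and `denominator` taxon ID vectors.
#' @export
select_reference_frames <- function(effects, top_k = 100,
                                    variable_name = "variable") {
  effects <- data.table::as.data.table(effects)
  cred <- effects[credible == TRUE]
  if (nrow(cred) < 2) {
    stop("fewer than 2 credible taxa for ", variable_name)
  }
  cred[, abs_effect := abs(mean_effect)]
  data.table::setorder(cred, -abs_effect, taxon)
  top <- head(cred, top_k)
  num <- sort(top[mean_effect > 0, taxon])
  den <- sort(top[mean_effect < 0, taxon])
  if (!length(num) || !length(den)) {
    stop("empty ", if (!length(num)) "numerator" else "denominator",
         " reference frame for ", variable_name)
  }
  list(numerator = num, denominator = den)
}

#' Per-sample reference-frame log ratio
#'
#' For each sample, the base-10 logarithm of the ratio between the summed
#' counts of numerator taxa and denominator taxa. Samples with zero counts in
#' either group, or with null metadata in `meta_var`, are removed and listed
#' in the dropped-sample report.
#'
#' @param table Samples x taxa count matrix.
#' @param numerator,denominator Disjoint, non-empty taxon ID sets.
#' @param metadata Optional per-sample table with `sample_id` column.
#' @param meta_var Optional metadata column whose missingness drops a sample.
#' @return List: `series` (`sample_id`, `log_ratio`), `numerator`,
#'   `denominator`, `dropped` (`sample_id`, `reason`).
#' @export
compute_log_ratio <- function(table, numerator, denominator,
                              metadata = NULL, meta_var = NULL) {
  table <- validate_feature_table(table)
  if (!length(numerator) || !length(denominator)) {
    stop("numerator and denominator must be non-empty")
  }
  if (length(intersect(numerator, denominator))) {
    stop("numerator and denominator must be disjoint")
  }
  missing_t <- setdiff(c(numerator, denominator), colnames(table))
  if (length(missing_t)) {
    stop("taxa absent from table: ", paste(head(missing_t, 5), collapse = ", "))
  }
  s_num <- rowSums(table[, numerator, drop = FALSE])
  s_den <- rowSums(table[, denominator, drop = FALSE])
  reason <- rep(NA_character_, nrow(table))
  reason[s_num == 0] <- "zero_numerator"
  reason[s_den == 0] <- "zero_denominator"
  if (!is.null(metadata) && !is.null(meta_var)) {
    md <- data.table::as.data.table(metadata)
    v <- md[[meta_var]][match(rownames(table), md$sample_id)]
    reason[is.na(v) & is.na(reason)] <- "null_metadata"
  }
  keep <- is.na(reason)
  list(
    series = data.table::data.table(sample_id = rownames(table)[keep],
                                    log_ratio = log10(s_num[keep] / s_den[keep])),
    numerator = numerator, denominator = denominator,
    dropped = data.table::data.table(sample_id = rownames(table)[!keep],
                                     reason = reason[!keep])
  )
}

#' Pearson correlation of a log-ratio series with a variable
#'
#' @param series Output of [compute_log_ratio()] (or its `series` table).
#' @param variable Named numeric vector (names = sample IDs) or a vector
#'   aligned with the retained samples.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_log_ratio <- function(series, variable) {
  s <- if (is.list(series) && !is.data.frame(series)) series$series else series
  s <- data.table::as.data.table(s)
  v <- if (!is.null(names(variable))) variable[s$sample_id] else variable
  if (length(v) != nrow(s)) stop("variable does not align with retained samples")
  ok <- !is.na(v)
  if (sum(ok) < 3) stop("need at least 3 retained samples")
  ct <- stats::cor.test(s$log_ratio[ok], v[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
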