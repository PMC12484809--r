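# Covariate-adjusted association testing, the diversity-on-diet regression,
# variance partitioning, and Cohen effect sizes on the merged per-participant
# analysis table.

#' Build the per-participant analysis frame
#'
#' Merges the diet profile, alpha diversity table (sample IDs are participant
#' IDs) and participant metadata on `participant_id`. Unmatched IDs on either
#' side are reported via a message and recorded in the `"unmatched"`
#' attribute — rows are never dropped silently.
#'
#' @param profile Diet profile ([diet_profile()]).
#' @param alpha Alpha diversity table ([alpha_metrics()]).
#' @param metadata Participant metadata.
#' @return Merged `data.table`, one row per participant present in all inputs.
#' @export
build_cohort_frame <- function(profile, alpha, metadata) {
  profile <- data.table::as.data.table(profile)
  alpha <- data.table::as.data.table(alpha)
  metadata <- data.table::as.data.table(metadata)
  if ("sample_id" %in% names(alpha) && !"participant_id" %in% names(alpha)) {
    data.table::setnames(alpha, "sample_id", "participant_id")
  }
  ids <- list(profile = profile$participant_id, alpha = alpha$participant_id,
              metadata = metadata$participant_id)
  common <- Reduce(intersect, ids)
  unmatched <- lapply(ids, function(x) setdiff(x, common))
  n_un <- sum(lengths(unmatched))
  if (n_un > 0) {
    message(sprintf("build_cohort_frame: %d unmatched participant IDs (see attr 'unmatched')",
                    n_un))
  }
  out <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                list(profile, alpha, metadata))
  if (anyDuplicated(out$participant_id)) stop("duplicate participant IDs after merge")
  data.table::setattr(out, "unmatched", unmatched)
  out[]
}

#' Partial Spearman correlation
#'
#' Ranks `x` and `y` (average ranks for ties), residualizes both ranks on the
#' covariates by least squares (with intercept), and correlates the residuals;
#' the p-value is t-based with `n - 2 - k` degrees of freedom. With no
#' covariates this reduces exactly to the plain Spearman correlation.
#' Incomplete cases are dropped listwise (count reflected in `n`).
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @return List with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(data.table::as.data.table(covariates))
    cc <- stats::complete.cases(x, y, covariates)
    covariates <- covariates[cc, , drop = FALSE]
  } else {
    cc <- stats::complete.cases(x, y)
  }
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < k + 3) stop("need at least covariates + 3 complete cases")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("x or y constant after ranking")
  }
  if (k > 0) {
    X <- cbind(1, covariates)
    rx <- stats::lm.fit(X, rx)$residuals
    ry <- stats::lm.fit(X, ry)$residuals
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values with discoveries flagged at `q_values <= q`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q Discovery threshold (default 0.1).
#' @return List with `q_values` and logical `discoveries`.
#' @export
fdr_adjust <- function(p_values, q = 0.1) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  qv <- stats::p.adjust(p_values, method = "BH")
  list(q_values = qv, discoveries = qv <= q)
}

#' Association table with covariate adjustment and FDR
#'
#' Runs [partial_spearman()] for every (feature, target) pair and adjusts the
#' pooled p-values with Benjamini-Hochberg.
#'
#' @param frame Analysis frame.
#' @param features,targets Column names.
#' @param covariates Covariate column names (default age and BMI).
#' @param q FDR threshold.
#' @return `data.table`: `feature`, `target`, `partial_rho`, `p_raw`, `q_fdr`,
#'   `discovery`, `n`.
#' @export
associate <- function(frame, features, targets, covariates = c("age", "bmi"),
                      q = 0.1) {
  frame <- data.table::as.data.table(frame)
  cov_m <- if (length(covariates)) frame[, covariates, with = FALSE] else NULL
  grid <- data.table::CJ(feature = features, target = targets)
  res <- grid[, {
    ps <- partial_spearman(frame[[feature]], frame[[target]], cov_m)
    list(partial_rho = ps$rho, p_raw = ps$p, n = ps$n)
  }, by = .(feature, target)]
  adj <- fdr_adjust(res$p_raw, q)
  res[, q_fdr := adj$q_values]
  res[, "discovery" := adj$discoveries]
  res[]
}

#' Diversity-on-diet multiple regression
#'
#' Ordinary least squares of an alpha-diversity outcome on diet-quality and
#' covariate terms, with categorical covariates dummy-coded against declared
#' reference levels (BMI category "normal", smoking "non-smoker"). The
#' canonical no-interaction specification regresses Shannon on the day-wise
#' HEI with age and BMI continuous; interaction formulas are supported via
#' standard R formula syntax.
#'
#' @param frame Analysis frame.
#' @param formula Model formula.
#' @param reference_levels Named character vector of factor reference levels.
#' @return List with `coefficients` (`term`, `estimate`, `se`, `t`, `p`,
#'   `ci_low`, `ci_high`), the fitted `model`, and `n`.
#' @export
fit_diversity_regression <- function(frame, formula,
                                     reference_levels = c(bmi_category = "normal",
                                                          smoking = "non-smoker")) {
  frame <- data.table::as.data.table(data.table::copy(frame))
  for (v in names(reference_levels)) {
    if (v %in% names(frame)) {
      data.table::set(frame, j = v,
                      value = stats::relevel(factor(frame[[v]]), ref = reference_levels[[v]]))
    }
  }
  fit <- stats::lm(formula, data = frame)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  list(
    coefficients = data.table::data.table(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      t = sm[, 3], p = sm[, 4], ci_low = ci[, 1], ci_high = ci[, 2]
    ),
    model = fit,
    n = length(fit$residuals)
  )
}

#' Predicted diversity change for a diet-quality improvement
#'
#' Linear-model prediction: a regression slope (diversity units per index
#' point) times an index-point improvement.
#'
#' @param beta_per_point Slope of diversity on the diet index.
#' @param delta_points Index improvement in points.
#' @return Predicted diversity change.
#' @export
predict_diversity_change <- function(beta_per_point, delta_points) {
  beta_per_point * delta_points
}

#' Variance explained by feature blocks
#'
#' OLS R-squared of the outcome on each named block of features and on the
#' union of all blocks (complete cases of the union).
#'
#' @param frame Analysis frame.
#' @param outcome Outcome column name.
#' @param blocks Named list of feature-column vectors (e.g. macronutrients,
#'   micronutrients, diet indices, food groups).
#' @return `data.table` with `block`, `r_squared`, `n_features`.
#' @export
variance_explained <- function(frame, outcome, blocks) {
  frame <- data.table::as.data.table(frame)
  if (any(lengths(blocks) == 0)) stop("empty feature block")
  all_feats <- unique(unlist(blocks))
  cc <- stats::complete.cases(frame[, unique(c(outcome, all_feats)), with = FALSE])
  sub <- frame[cc]
  yv <- sub[[outcome]]
  tss <- sum((yv - mean(yv))^2)
  r2 <- function(feats) {
    X <- cbind(1, as.matrix(sub[, feats, with = FALSE]))
    res <- stats::lm.fit(X, yv)$residuals
    1 - sum(res^2) / tss
  }
  out <- data.table::data.table(
    block = c(names(blocks), "all"),
    r_squared = c(vapply(blocks, r2, numeric(1)), r2(all_feats)),
    n_features = c(lengths(blocks), length(all_feats))
  )
  out[]
}

#' Cohen's d or f effect size
#'
#' Binary grouping: `d = (m1 - m2) / pooled SD`. Three or more groups:
#' `f = sqrt(eta^2 / (1 - eta^2))` from one-way ANOVA.
#'
#' @param values Numeric outcome.
#' @param grouping Factor-like grouping with >= 2 groups of >= 2 observations.
#' @return List with `statistic` (`"cohen_d"` or `"cohen_f"`) and `value`.
#' @export
effect_size <- function(values, grouping) {
  cc <- stats::complete.cases(values, grouping)
  values <- values[cc]
  grouping <- factor(grouping[cc])
  sizes <- table(grouping)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  if (length(sizes) == 2) {
    g <- levels(grouping)
    x1 <- values[grouping == g[1]]; x2 <- values[grouping == g[2]]
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                 (length(x1) + length(x2) - 2))
    list(statistic = "cohen_d", value = (mean(x1) - mean(x2)) / sp)
  } else {
    fit <- stats::aov(values ~ grouping)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    eta2 <- ss[1] / sum(ss)
    list(statistic = "cohen_f", value = sqrt(eta2 / (1 - eta2)))
  }
}
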