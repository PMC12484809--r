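# Bidirectional prediction harness: classify extreme quartiles (Q1 vs Q4) of
# a variable from features (or regress the full range), over repeated seeded
# 80:20 train-test splits, aggregating held-out AUROC/AUPRC or Spearman rho
# and gain-based feature importances. The boosted-tree learner itself lives
# in src/ (no gradient-boosting dependency exists in this stack).

#' Harness configuration
#'
#' Defaults follow the study setup: 100 iterations of 80:20 splits;
#' classifier trees = 1000, max_depth = 6, column subsample 0.8, row
#' subsample 0.4, L1 alpha 0.1, learning rate 0.005; regressor trees = 1000,
#' learning rate 0.05; variables with mean below 0.001 are
#' log10(x + 1e-6)-transformed.
#'
#' @param task `"classify"` or `"regress"`.
#' @param n_iterations Number of repeated splits.
#' @param test_fraction Held-out fraction per split.
#' @param trees,max_depth,colsample,subsample,l1_alpha,learning_rate
#'   Classifier hyperparameters.
#' @param reg_trees,reg_learning_rate Regressor hyperparameters.
#' @param log_transform_threshold,log_transform_offset Low-mean transform rule.
#' @param seed_base Base seed; iteration i uses `seed_base + i`.
#' @return A `harness_config` list.
#' @export
harness_config <- function(task = c("classify", "regress"),
                           n_iterations = 100, test_fraction = 0.2,
                           trees = 1000, max_depth = 6, colsample = 0.8,
                           subsample = 0.4, l1_alpha = 0.1,
                           learning_rate = 0.005,
                           reg_trees = 1000, reg_learning_rate = 0.05,
                           log_transform_threshold = 0.001,
                           log_transform_offset = 1e-6,
                           seed_base = 1) {
  task <- match.arg(task)
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must be in (0, 1)")
  assert_scalar_count(n_iterations, "n_iterations")
  structure(list(task = task, n_iterations = as.integer(n_iterations),
                 test_fraction = test_fraction, trees = as.integer(trees),
                 max_depth = as.integer(max_depth), colsample = colsample,
                 subsample = subsample, l1_alpha = l1_alpha,
                 learning_rate = learning_rate,
                 reg_trees = as.integer(reg_trees),
                 reg_learning_rate = reg_learning_rate,
                 log_transform_threshold = log_transform_threshold,
                 log_transform_offset = log_transform_offset,
                 seed_base = as.integer(seed_base)),
            class = "harness_config")
}

#' Extreme-quartile labels
#'
#' Binary labels distinguishing the bottom (Q1) and top (Q4) quartiles of a
#' variable by its 25th/75th linear-interpolation percentiles; the middle half
#' gets `NA`. Q4 is the positive class.
#'
#' @param values Numeric vector with >= 8 non-missing values.
#' @return List with `labels` (factor Q1/Q4 with NA middle) and `report`
#'   (cut values and class sizes).
#' @export
make_extreme_quartile_labels <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 8) stop("need at least 8 non-missing values")
  cuts <- stats::quantile(values[ok], c(0.25, 0.75), names = FALSE, type = 7)
  if (cuts[1] >= cuts[2]) stop("degenerate distribution: quartile cuts coincide")
  labels <- rep(NA_character_, length(values))
  labels[ok & values <= cuts[1]] <- "Q1"
  labels[ok & values >= cuts[2]] <- "Q4"
  labels <- factor(labels, levels = c("Q1", "Q4"))
  list(labels = labels,
       report = list(q1_cut = cuts[1], q4_cut = cuts[2],
                     n_q1 = sum(labels == "Q1", na.rm = TRUE),
                     n_q4 = sum(labels == "Q4", na.rm = TRUE)))
}

#' Low-mean log transform
#'
#' Columns whose mean is below the threshold are replaced by
#' `log10(x + offset)`; all other columns pass through untouched.
#'
#' @param X Numeric matrix/data.frame of features.
#' @param threshold,offset Transform rule constants.
#' @return List with the transformed matrix and the affected column names.
#' @export
apply_low_mean_log <- function(X, threshold = 0.001, offset = 1e-6) {
  X <- as.matrix(X)
  transformed <- character()
  for (j in seq_len(ncol(X))) {
    mu <- mean(X[, j], na.rm = TRUE)
    if (!is.na(mu) && mu < threshold && all(X[, j] >= 0, na.rm = TRUE)) {
      X[, j] <- log10(X[, j] + offset)
      transformed <- c(transformed, colnames(X)[j])
    }
  }
  list(matrix = X, transformed = transformed)
}

# AUROC via the rank statistic (ties handled by midranks).
auroc <- function(scores, labels) {
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve (step interpolation, positive = Q4).
auprc <- function(scores, labels) {
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos)
  if (n1 == 0 || sum(!pos) == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  precision <- tp / seq_along(tp)
  recall <- tp / n1
  sum(precision * diff(c(0, recall)))
}

#' Run the prediction harness
#'
#' For each of `n_iterations` seeds: split 80:20 (stratified for
#' classification, plain random for regression), fit the boosted-tree learner
#' on the training split, and score the held-out split with AUROC and AUPRC
#' (classification) or Spearman rho (regression). Gain importances are
#' accumulated across iterations. Iterations where a class has fewer than 5
#' members after the split are skipped with a warning.
#'
#' @param features Numeric matrix/data.frame (rows = samples).
#' @param target Numeric variable (quartile labels are derived internally for
#'   classification) or a ready factor of Q1/Q4 labels.
#' @param config A [harness_config()].
#' @param permute_target If `TRUE`, the target is freshly permuted under each
#'   iteration's seed before splitting — the permutation null for calibrating
#'   chance-level performance. A single up-front permutation would leave
#'   dataset-level chance correlations that every split rediscovers; the
#'   per-iteration permutation destroys them.
#' @return A `harness_result` list: `metrics` (per-iteration table),
#'   `importance` (per-feature mean gain), `label_report`, `config`.
#' @export
run_harness <- function(features, target, config = harness_config(),
                        permute_target = FALSE) {
  stopifnot(inherits(config, "harness_config"))
  X0 <- as.matrix(features)
  if (is.null(colnames(X0))) colnames(X0) <- paste0("f", seq_len(ncol(X0)))
  storage.mode(X0) <- "double"

  label_report <- NULL
  if (config$task == "classify") {
    if (is.factor(target)) {
      labels <- target
    } else {
      lab <- make_extreme_quartile_labels(target)
      labels <- lab$labels
      label_report <- lab$report
    }
    keep <- !is.na(labels) & stats::complete.cases(X0)
    X <- X0[keep, , drop = FALSE]
    y <- as.numeric(labels[keep] == levels(labels)[2])
    ylab <- droplevels(labels[keep])
  } else {
    keep <- !is.na(target) & stats::complete.cases(X0)
    X <- X0[keep, , drop = FALSE]
    y <- as.numeric(target[keep])
  }
  tr <- apply_low_mean_log(X, config$log_transform_threshold,
                           config$log_transform_offset)
  X <- tr$matrix
  n <- nrow(X)
  if (n < 10) stop("too few usable samples for the harness")

  gain <- numeric(ncol(X))
  rows <- vector("list", config$n_iterations)
  y_orig <- y
  if (config$task == "classify") ylab_orig <- ylab
  for (it in seq_len(config$n_iterations)) {
    seed_it <- config$seed_base + it
    if (permute_target) {
      perm <- with_rng(seed_it * 2L + 1L, sample.int(n))
      y <- y_orig[perm]
      if (config$task == "classify") ylab <- ylab_orig[perm]
    }
    split <- with_rng(seed_it, {
      if (config$task == "classify") {
        # stratified: hold out test_fraction within each class
        test <- unlist(lapply(split(seq_len(n), ylab), function(idx) {
          sample(idx, max(1, round(config$test_fraction * length(idx))))
        }), use.names = FALSE)
      } else {
        test <- sample.int(n, max(1, round(config$test_fraction * n)))
      }
      test
    })
    train <- setdiff(seq_len(n), split)
    if (config$task == "classify") {
      cls_train <- table(ylab[train]); cls_test <- table(ylab[split])
      if (min(cls_train) < 5 || min(cls_test) < 1) {
        warning(sprintf("iteration %d skipped: class with < 5 members after split", it))
        next
      }
      fit <- .gbtree_fit_predict(X[train, , drop = FALSE], y[train],
                                 X[split, , drop = FALSE],
                                 "binary:logistic", config$trees,
                                 config$learning_rate, config$max_depth,
                                 config$subsample, config$colsample,
                                 1.0, config$l1_alpha, 1.0, seed_it)
      rows[[it]] <- data.table::data.table(
        iteration = it, seed = seed_it,
        auroc = auroc(fit$pred_test, ylab[split]),
        auprc = auprc(fit$pred_test, ylab[split]))
    } else {
      fit <- .gbtree_fit_predict(X[train, , drop = FALSE], y[train],
                                 X[split, , drop = FALSE],
                                 "reg:squarederror", config$reg_trees,
                                 config$reg_learning_rate, config$max_depth,
                                 1.0, 1.0, 1.0, 0.0, 1.0, seed_it)
      rho <- suppressWarnings(stats::cor(fit$pred_test, y[split],
                                         method = "spearman"))
      rows[[it]] <- data.table::data.table(iteration = it, seed = seed_it,
                                           spearman = rho)
    }
    gain <- gain + fit$importance
  }
  metrics <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  importance <- data.table::data.table(feature = colnames(X),
                                       mean_gain = gain / max(1, nrow(metrics)))
  data.table::setorder(importance, -mean_gain)
  structure(list(metrics = metrics[], importance = importance[],
                 label_report = label_report, config = config),
            class = "harness_result")
}

#' Predict alpha diversity from diet and lifestyle features
#'
#' Runs one classification harness per alpha-diversity metric (Shannon,
#' Pielou, observed features, Faith's PD), classifying the metric's extreme
#' quartiles from dietary, regularity and anthropometric features; exports
#' the gain-importance ranking per metric.
#'
#' @param frame Analysis frame ([build_cohort_frame()]).
#' @param config A [harness_config()] (task forced to classify).
#' @param alpha_cols Alpha-metric columns present in the frame.
#' @param feature_cols Feature columns; defaults to all numeric columns other
#'   than the alpha metrics.
#' @return Named list of `harness_result`, one per alpha metric.
#' @export
predict_alpha_from_diet <- function(frame, config = harness_config("classify"),
                                    alpha_cols = c("faith_pd", "shannon",
                                                   "observed", "pielou"),
                                    feature_cols = NULL) {
  frame <- data.table::as.data.table(frame)
  alpha_cols <- intersect(alpha_cols, names(frame))
  if (!length(alpha_cols)) stop("no alpha-metric columns in frame")
  if (is.null(feature_cols)) {
    numc <- names(frame)[vapply(frame, is.numeric, logical(1))]
    feature_cols <- setdiff(numc, c(alpha_cols, "participant_id"))
  }
  out <- lapply(alpha_cols, function(metric) {
    run_harness(frame[, feature_cols, with = FALSE], frame[[metric]], config)
  })
  names(out) <- alpha_cols
  out
}
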