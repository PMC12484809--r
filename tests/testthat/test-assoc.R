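test_that("partial_spearman reduces to plain Spearman without covariates", {
  withr::local_seed(4)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  res <- partial_spearman(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$n, 60)
  # y = x with a non-collinear covariate: near-perfect partial correlation
  z <- rnorm(60)
  expect_gt(partial_spearman(x, x, z)$rho, 0.99)
})

test_that("partial_spearman removes a confound and is monotone-invariant", {
  withr::local_seed(6)
  hits <- sapply(1:8, function(s) {
    set.seed(s)
    conf <- rnorm(120)
    x <- rnorm(120)              # independent of the confound
    y <- conf + rnorm(120, sd = 1e-8) # y is (essentially) the covariate
    abs(partial_spearman(x, y, conf)$rho) < 0.2
  })
  expect_gte(mean(hits), 7 / 8)

  x <- rexp(50); y <- x + rnorm(50, sd = 0.2); z <- rnorm(50)
  a <- partial_spearman(x, y, z)
  b <- partial_spearman(log(x), exp(y / 10), z) # strictly monotone transforms
  expect_equal(a$rho, b$rho, tolerance = 1e-12)

  expect_error(partial_spearman(rep(1, 30), rnorm(30)), "constant")
  expect_error(partial_spearman(rnorm(4), rnorm(4), matrix(rnorm(8), 4, 2)),
               "complete cases")
})

test_that("fdr_adjust matches the BH hand computation and orders sensibly", {
  expect_false(any(fdr_adjust(rep(1, 5))$discoveries))
  res <- fdr_adjust(c(0.01, 0.02, 0.9), q = 0.1)
  expect_equal(res$q_values, c(0.03, 0.03, 0.9))
  expect_equal(res$discoveries, c(TRUE, TRUE, FALSE))
  p <- runif(20)
  expect_true(all(fdr_adjust(p)$q_values >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fit_diversity_regression returns CIs, handles factors, and flags aliasing", {
  withr::local_seed(12)
  n <- 300
  frame <- data.table::data.table(
    hei_daily = runif(n, 30, 90),
    age = runif(n, 18, 70),
    bmi = rnorm(n, 25, 4),
    smoking = sample(c("non-smoker", "smoker", "ex-smoker"), n, replace = TRUE)
  )
  frame[, shannon := 0.019 * hei_daily + rnorm(n, sd = 0.3)]
  fit <- fit_diversity_regression(frame, shannon ~ hei_daily + age + bmi + smoking)
  co <- fit$coefficients[term == "hei_daily"]
  expect_true(co$ci_low < 0.019 & 0.019 < co$ci_high)
  # reference level respected: no "non-smoker" dummy term
  expect_false(any(grepl("non-smoker", fit$coefficients$term)))
  # adding a constant moves only the intercept
  frame2 <- data.table::copy(frame)[, shannon := shannon + 5]
  fit2 <- fit_diversity_regression(frame2, shannon ~ hei_daily + age + bmi + smoking)
  expect_equal(fit2$coefficients[term != "(Intercept)", estimate],
               fit$coefficients[term != "(Intercept)", estimate], tolerance = 1e-9)
  expect_equal(fit2$coefficients[term == "(Intercept)", estimate],
               fit$coefficients[term == "(Intercept)", estimate] + 5,
               tolerance = 1e-9)
  # aliased term
  frame[, hei_copy := hei_daily]
  expect_error(fit_diversity_regression(frame, shannon ~ hei_daily + hei_copy),
               "aliased")
})

test_that("null regression calibration: CI covers zero at roughly the nominal rate", {
  cover <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 150
    f <- data.table::data.table(x = runif(n, 30, 90), y = rnorm(n))
    fit <- fit_diversity_regression(f, y ~ x)
    co <- fit$coefficients[term == "x"]
    co$ci_low <= 0 && 0 <= co$ci_high
  })
  expect_gte(mean(cover), 0.8)
})

test_that("variance_explained behaves on trivial, null and nested blocks", {
  withr::local_seed(33)
  n <- 400
  frame <- data.table::data.table(out = rnorm(n), a = rnorm(n), b = rnorm(n),
                                  c = rnorm(n))
  ve <- variance_explained(frame, "out", list(self = "out"))
  expect_equal(ve[block == "self", r_squared], 1)
  noise <- variance_explained(frame, "out", list(noise = c("a", "b", "c")))
  expect_lt(noise[block == "noise", r_squared], 3 / (n - 1) * 5)
  nested <- variance_explained(frame, "out", list(small = "a", big = c("a", "b")))
  expect_gte(nested[block == "all", r_squared],
             max(nested[block != "all", r_squared]) - 1e-12)
  expect_error(variance_explained(frame, "out", list(empty = character())), "empty")
})

test_that("effect_size matches hand-computed d and the ANOVA eta-squared oracle", {
  expect_equal(effect_size(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$value, 0)
  withr::local_seed(2)
  x1 <- rnorm(2000); x2 <- rnorm(2000) + 1
  d <- effect_size(c(x1, x2), rep(c("g1", "g2"), each = 2000))
  expect_equal(d$statistic, "cohen_d")
  expect_equal(abs(d$value), 1, tolerance = 0.1)

  vals <- c(1, 2, 3, 4, 5, 6, 9, 8, 10)
  grp <- rep(c("a", "b", "c"), each = 3)
  f <- effect_size(vals, grp)
  gm <- mean(vals)
  ss_between <- sum(3 * (tapply(vals, grp, mean) - gm)^2)
  ss_total <- sum((vals - gm)^2)
  eta2 <- ss_between / ss_total
  expect_equal(f$value, sqrt(eta2 / (1 - eta2)), tolerance = 1e-12)
  expect_error(effect_size(1:3, c("a", "a", "b")), "2 observations")
})

test_that("build_cohort_frame merges without silent drops and associate runs FDR", {
  coh <- small_cohort(seed = 41, n = 40)
  prof <- diet_profile(qc_filter(aggregate_daily(coh$food_log)))
  am <- alpha_metrics(coh$feature_table, coh$tree)
  expect_message(
    frame <- build_cohort_frame(prof, am[1:35], coh$metadata),
    "unmatched")
  expect_equal(nrow(frame), length(intersect(prof$participant_id, am$sample_id[1:35])))
  unmatched <- attr(frame, "unmatched")
  expect_setequal(unmatched$metadata,
                  setdiff(coh$metadata$participant_id, frame$participant_id))

  res <- associate(frame, features = c("hei_daily", "cv_vegetables"),
                   targets = "shannon", covariates = c("age", "bmi"))
  expect_equal(nrow(res), 2)
  expect_true(all(res$q_fdr >= res$p_raw - 1e-12))
  expect_true(all(c("partial_rho", "p_raw", "q_fdr", "discovery", "n") %in% names(res)))
})

test_that("planted cohort recovers the signature association pattern", {
  coh <- generate_cohort(synth_config(n_participants = 300, n_taxa = 60,
                                      seq_depth_mean = 8000,
                                      effect_hei_diversity = 0.03,
                                      effect_cv_diversity = -0.008, seed = 61))
  prof <- diet_profile(qc_filter(aggregate_daily(coh$food_log)))
  am <- alpha_metrics(coh$feature_table)
  frame <- build_cohort_frame(prof, am, coh$metadata)
  res <- associate(frame, features = c("hei", "hei_daily", "cv_vegetables"),
                   targets = "shannon", covariates = c("age", "bmi"))
  expect_gt(res[feature == "hei", partial_rho], 0)
  expect_gt(res[feature == "hei_daily", partial_rho], 0)
  expect_lt(res[feature == "cv_vegetables", partial_rho], 0)
})
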