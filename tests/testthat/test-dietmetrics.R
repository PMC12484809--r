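specs <- read_component_specs()

test_that("component scoring follows the clamped linear standard", {
  adeq <- list(name = "a", direction = "adequacy", max_points = 5,
               density_basis = "per-1000-kcal", numerator = "x",
               full_score_at = 0.8, zero_score_at = 0)
  expect_equal(score_component(0.8, adeq), 5)
  expect_equal(score_component(2.0, adeq), 5)
  expect_equal(score_component(0.4, adeq), 2.5) # midpoint interpolation
  expect_equal(score_component(0, adeq), 0)

  mod <- list(name = "m", direction = "moderation", max_points = 10,
              density_basis = "per-1000-kcal", numerator = "x",
              full_score_at = 1.1, zero_score_at = 2.0)
  expect_equal(score_component(2.5, mod), 0)
  expect_equal(score_component(1.1, mod), 10)
  expect_equal(score_component(0.2, mod), 10)

  badspec <- adeq; badspec$zero_score_at <- 1
  expect_error(score_component(0.5, badspec), "full_score_at > zero_score_at")
})

test_that("component scores are monotone in density", {
  withr::local_seed(1)
  for (sp in specs) {
    d <- sort(runif(50, 0, 5))
    s <- score_component(d, sp)
    if (sp$direction == "adequacy") {
      expect_true(all(diff(s) >= 0), info = sp$name)
    } else {
      expect_true(all(diff(s) <= 0), info = sp$name)
    }
    expect_true(all(s >= 0 & s <= sp$max_points), info = sp$name)
  }
})

test_that("shipped HEI-2020 set totals 100 points and scores the boundary menus", {
  expect_equal(attr(specs, "total_points"), 100)
  ideal <- qc_filter(aggregate_daily(ideal_day_rows()), min_days = 1)
  expect_equal(hei_standard(ideal, specs)$hei, 100)
  worst <- qc_filter(aggregate_daily(worst_day_rows()), min_days = 1)
  expect_equal(hei_standard(worst, specs)$hei, 0)
})

test_that("two-day toy menu matches an independent per-component computation", {
  log <- data.table::rbindlist(list(
    log_row("P1", "2026-03-01", "fruits", grams = 150, kcal = 100),
    log_row("P1", "2026-03-01", "grains_cereals", grams = 120, kcal = 350,
            sfa = 2, mufa = 3, pufa = 3, sodium = 1.2, added_sugar = 20),
    log_row("P1", "2026-03-01", "meat", grams = 120, kcal = 300,
            sfa = 6, mufa = 7, pufa = 2, sodium = 0.7),
    log_row("P1", "2026-03-01", "dairy", grams = 200, kcal = 350, sfa = 5,
            mufa = 2, pufa = 1, added_sugar = 10),
    log_row("P1", "2026-03-02", "vegetables", grams = 250, kcal = 90),
    log_row("P1", "2026-03-02", "fast_food", grams = 300, kcal = 850,
            sfa = 14, mufa = 15, pufa = 6, sodium = 2.1, added_sugar = 15),
    log_row("P1", "2026-03-02", "oils_nuts", grams = 25, kcal = 150,
            sfa = 2, mufa = 7, pufa = 5)
  ))
  daily <- qc_filter(aggregate_daily(log), min_days = 1)

  # independent oracle: recompute means, densities and clamped scores from the
  # YAML numbers without touching the package's scoring engine internals
  cfg <- yaml::read_yaml(system.file("extdata", "hei2020.yaml", package = "dietrhythm"))
  mean_row <- as.list(colMeans(daily[, sapply(daily, is.numeric), with = FALSE]))
  oracle_total <- 0
  for (sp in cfg$components) {
    num <- eval(parse(text = sp$numerator), envir = mean_row)
    dens <- switch(sp$density_basis,
                   "per-1000-kcal" = num / (mean_row$energy_kcal / 1000),
                   "percent-of-energy" = 100 * num / mean_row$energy_kcal,
                   "ratio" = num)
    fr <- (dens - sp$zero_score_at) / (sp$full_score_at - sp$zero_score_at)
    oracle_total <- oracle_total + sp$max_points * min(max(fr, 0), 1)
  }
  expect_equal(hei_standard(daily, specs)$hei, oracle_total, tolerance = 1e-12)
})

test_that("day-wise HEI equals standard HEI on constant diets and averages day scores", {
  const_daily <- qc_filter(aggregate_daily(
    constant_diet_log("P1", ideal_day_rows(), n_days = 7)))
  expect_identical(hei_daily(const_daily, specs)$score$hei_daily,
                   hei_standard(const_daily, specs)$hei)

  single <- qc_filter(aggregate_daily(ideal_day_rows("P2")), min_days = 1)
  expect_equal(hei_daily(single, specs)$score$hei_daily,
               hei_standard(single, specs)$hei)

  # one ideal day (100) + one worst day (0): day-wise mean is 50 but the
  # pooled-mean standard score differs
  mix <- data.table::rbindlist(list(ideal_day_rows("P3", "2026-03-01"),
                                    worst_day_rows("P3", "2026-03-02")))
  mix_daily <- qc_filter(aggregate_daily(mix), min_days = 1)
  hd <- hei_daily(mix_daily, specs)
  expect_equal(sort(hd$days$hei_day), c(0, 100))
  expect_equal(hd$score$hei_daily, 50)
  expect_false(isTRUE(all.equal(hei_standard(mix_daily, specs)$hei, 50)))
})

test_that("compute_cv matches hand values, handles degenerate series, and is scale-invariant", {
  expect_equal(compute_cv(c(10, 10, 10)), 0)
  expect_equal(compute_cv(c(1, 2, 3)), 50) # mean 2, sample SD 1
  expect_true(is.na(compute_cv(c(0, 0, 0))))
  expect_true(is.na(compute_cv(5)))

  withr::local_seed(42)
  for (i in 1:25) {
    x <- rgamma(sample(3:20, 1), shape = 2, scale = 10)
    k <- runif(1, 0.1, 50)
    expect_equal(compute_cv(k * x), compute_cv(x), tolerance = 1e-10)
    expect_equal(compute_cv(x), 100 * sd(x) / mean(x))
  }
})

test_that("diet diversity indices match closed forms and peak at uniformity", {
  mk <- function(kcals) {
    rows <- data.table::rbindlist(lapply(seq_along(kcals), function(i) {
      log_row("P1", "2026-03-01", food_group_vocabulary()[i],
              grams = 100, kcal = kcals[i])
    }))
    qc_filter(aggregate_daily(rows), min_kcal = 1, min_days = 1)
  }
  one <- diet_diversity_daily(mk(2000))
  expect_equal(one$diet_shannon_mean, 0)
  expect_equal(one$gini_simpson_mean, 0)
  expect_equal(one$dds_mean, 1)

  four <- diet_diversity_daily(mk(rep(500, 4)))
  expect_equal(four$diet_shannon_mean, log(4), tolerance = 1e-12)
  expect_equal(four$gini_simpson_mean, 0.75)
  expect_equal(four$dds_mean, 4)

  skew <- diet_diversity_daily(mk(c(1000, 500, 500)))
  expect_equal(skew$gini_simpson_mean, 0.625) # 1 - (0.25 + 0.0625 + 0.0625)

  # uniform maximizes both indices over random perturbations
  withr::local_seed(9)
  for (i in 1:10) {
    kc <- runif(4, 100, 900)
    pert <- diet_diversity_daily(mk(kc))
    expect_lte(pert$diet_shannon_mean, four$diet_shannon_mean + 1e-12)
    expect_lte(pert$gini_simpson_mean, four$gini_simpson_mean + 1e-12)
  }
})

test_that("diet_profile assembles HEI, CV and diversity columns per participant", {
  coh <- small_cohort(seed = 21, n = 25)
  prof <- diet_profile(qc_filter(aggregate_daily(coh$food_log)))
  expect_true(all(c("hei", "hei_daily", "cv_hei", "cv_vegetables", "dds_mean",
                    "diet_shannon_mean", "gini_simpson_mean") %in% names(prof)))
  expect_true(all(prof$hei >= 0 & prof$hei <= 100))
  expect_true(all(prof$hei_daily >= 0 & prof$hei_daily <= 100))
  expect_true(all(prof$gini_simpson_mean >= 0 & prof$gini_simpson_mean < 1))
  expect_true(all(prof$cv_vegetables >= 0, na.rm = TRUE))
  # realized group CVs track the planted per-participant targets
  tr <- coh$truth[match(prof$participant_id, coh$truth$participant_id)]
  expect_gt(cor(prof$cv_vegetables, tr$target_cv_pct), 0.6)
})
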