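# Seeded synthetic cohort generator with planted diet-microbiome effects.
#
# The generator emulates a digital-nutrition cohort: ~2 weeks of food logging
# per participant, one 16S stool sample each, participant metadata and daily
# stool-quality self-reports. Planted structure: a participant's latent gut
# Shannon diversity is a linear function of their realized day-wise HEI
# (slope `effect_hei_diversity`, bits per HEI point) and of their intake-CV
# target (slope `effect_cv_diversity`, bits per CV percentage point), plus
# Gaussian noise. The abundance profile realizing a latent diversity target is
# a two-block mixture: a "responder" block of evenly distributed taxa whose
# total concentration grows with the target (and hence with diet quality),
# and a skewed "opportunist" background block; block weight is solved from
# the target entropy in closed form via uniroot. Counts are drawn
# Dirichlet-multinomial around the profile with negative-binomial library
# sizes, mimicking real sequencing overdispersion.

# Per-group generative parameters: log-scale location/spread of participant
# mean intakes (g/day), energy density (kcal/g), and the loading of a latent
# "diet healthiness" factor that induces realistic between-participant
# diet-quality variation (positive: eaten more by healthy eaters).
default_food_groups <- function() {
  data.table::data.table(
    group   = c("vegetables", "fruits", "meat", "dairy", "grains_cereals",
                "oils_nuts", "sugary_foods", "fast_food", "coffee", "others"),
    meanlog = log(c(220, 160, 110, 180, 200, 30, 60, 60, 250, 120)),
    sdlog   = c(0.35, 0.4, 0.45, 0.4, 0.3, 0.5, 0.5, 0.6, 0.7, 0.4),
    kcal_g  = c(0.35, 0.55, 2.2, 0.8, 2.6, 5.0, 4.0, 2.8, 0.05, 1.5),
    quality_loading = c(0.45, 0.45, -0.25, 0.15, 0.05, 0.4, -0.5, -0.7, 0, 0)
  )
}

# Per-gram nutrient composition by food group (rows align with
# default_food_groups()). Units: g/g for macronutrients and added sugar,
# g/g for sodium and alcohol, mg/g for potassium, magnesium, iron, calcium,
# phosphorus, zinc, vitamin C, niacin; ug/g for folate. Values are plausible
# field magnitudes, not a nutrient database.
default_composition <- function() {
  m <- rbind(
    #            fiber  prot   fat    carb   sfa    mufa   pufa   sodium  sugar  K     Mg    folate Fe     Ca    P     Zn     vitC   niacin alcohol
    vegetables   = c(0.025, 0.02, 0.003, 0.05, 0.001, 0.001, 0.001, 0.0004, 0.000, 2.9, 0.20, 0.60, 0.008, 0.40, 0.35, 0.004, 0.25, 0.007, 0),
    fruits       = c(0.022, 0.008, 0.003, 0.12, 0.001, 0.001, 0.001, 0.0000, 0.000, 1.9, 0.10, 0.25, 0.003, 0.10, 0.15, 0.001, 0.35, 0.004, 0),
    meat         = c(0.000, 0.22, 0.14, 0.00, 0.050, 0.060, 0.020, 0.0008, 0.000, 3.0, 0.22, 0.08, 0.020, 0.12, 1.90, 0.035, 0.00, 0.060, 0),
    dairy        = c(0.000, 0.035, 0.035, 0.05, 0.022, 0.010, 0.002, 0.0005, 0.000, 1.5, 0.11, 0.05, 0.000, 1.20, 0.95, 0.004, 0.01, 0.001, 0),
    grains_cereals = c(0.040, 0.10, 0.02, 0.65, 0.004, 0.007, 0.008, 0.0020, 0.005, 1.5, 0.45, 0.30, 0.012, 0.25, 1.20, 0.012, 0.00, 0.030, 0),
    oils_nuts    = c(0.080, 0.18, 0.55, 0.15, 0.070, 0.280, 0.180, 0.0010, 0.010, 6.0, 2.30, 0.60, 0.035, 1.00, 3.50, 0.030, 0.01, 0.015, 0),
    sugary_foods = c(0.010, 0.05, 0.22, 0.60, 0.120, 0.070, 0.020, 0.0015, 0.450, 1.5, 0.40, 0.10, 0.015, 0.55, 1.00, 0.010, 0.00, 0.005, 0),
    fast_food    = c(0.015, 0.11, 0.14, 0.28, 0.050, 0.055, 0.025, 0.0055, 0.030, 2.5, 0.25, 0.40, 0.018, 1.00, 1.80, 0.018, 0.01, 0.040, 0),
    coffee       = c(0.000, 0.001, 0.000, 0.002, 0.000, 0.000, 0.000, 0.0000, 0.000, 0.5, 0.03, 0.01, 0.000, 0.02, 0.03, 0.000, 0.00, 0.050, 0),
    others       = c(0.010, 0.05, 0.05, 0.15, 0.015, 0.020, 0.010, 0.0020, 0.020, 1.5, 0.20, 0.20, 0.010, 0.30, 0.70, 0.008, 0.02, 0.015, 0.01)
  )
  colnames(m) <- nutrient_columns()
  m
}

#' Synthetic cohort configuration
#'
#' Defaults state the emulated world: a cohort of 1000 participants tracking
#' for 14 days, ~200 gut taxa at a mean library size of 20000 reads, intake-CV
#' targets drawn uniformly on 20-120%, the latent diversity slope 0.019 bits
#' per day-wise HEI point, a negative CV slope, and a stool-report coupling
#' shifting "great"/"diarrhea" probabilities with diet-quality z-score. A
#' fixed 20% of tracking days are drawn below 1000 kcal to exercise the QC
#' filter.
#'
#' @param n_participants,n_days,n_taxa,seq_depth_mean Cohort dimensions.
#' @param food_groups `data.table` of per-group generative parameters; see
#'   `default_food_groups()`.
#' @param regularity_range Pair of CV percentages in (0, 300].
#' @param effect_hei_diversity Planted slope of latent Shannon (bits) per
#'   day-wise HEI point.
#' @param effect_cv_diversity Planted slope of latent Shannon per CV
#'   percentage point (expected negative).
#' @param stool_coupling Shift of great/diarrhea report probabilities per
#'   unit diet-quality z-score (log-odds scale).
#' @param low_kcal_fraction Fraction of days scaled below 1000 kcal.
#' @param diversity_noise_sd SD of latent-diversity noise (bits).
#' @param dirichlet_theta Dirichlet concentration total (overdispersion).
#' @param seed Root RNG seed; all randomness flows from it via named
#'   substreams.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_participants = 1000, n_days = 14, n_taxa = 200,
                         seq_depth_mean = 20000,
                         food_groups = default_food_groups(),
                         regularity_range = c(20, 120),
                         effect_hei_diversity = 0.019,
                         effect_cv_diversity = -0.005,
                         stool_coupling = 0.3,
                         low_kcal_fraction = 0.2,
                         diversity_noise_sd = 0.3,
                         dirichlet_theta = 2000,
                         seed = 1) {
  assert_scalar_count(n_participants, "n_participants")
  assert_scalar_count(n_days, "n_days")
  assert_scalar_count(n_taxa, "n_taxa", min = 2)
  assert_scalar_count(seq_depth_mean, "seq_depth_mean")
  if (length(regularity_range) != 2 || any(regularity_range <= 0) ||
      any(regularity_range > 300) || regularity_range[1] > regularity_range[2]) {
    stop("regularity_range must be an increasing pair within (0, 300]")
  }
  if (low_kcal_fraction < 0 || low_kcal_fraction >= 1) {
    stop("low_kcal_fraction must be in [0, 1)")
  }
  if (dirichlet_theta <= 0) stop("dirichlet_theta must be positive")
  structure(list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    n_taxa = as.integer(n_taxa), seq_depth_mean = as.integer(seq_depth_mean),
    food_groups = data.table::as.data.table(food_groups),
    regularity_range = as.numeric(regularity_range),
    effect_hei_diversity = effect_hei_diversity,
    effect_cv_diversity = effect_cv_diversity,
    stool_coupling = stool_coupling,
    low_kcal_fraction = low_kcal_fraction,
    diversity_noise_sd = diversity_noise_sd,
    dirichlet_theta = dirichlet_theta,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Random rooted bifurcating phylogeny
#'
#' Wraps [ape::rtree()] under a named RNG substream; tip labels follow the
#' generator's taxon-ID scheme so the tree plugs into synthetic feature
#' tables. Branch lengths are positive uniforms.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return A rooted `phylo` object with `n_taxa` tips.
#' @export
generate_tree <- function(n_taxa, seed = 1) {
  assert_scalar_count(n_taxa, "n_taxa", min = 2)
  tree <- with_rng(substream_seed(seed, "tree"), ape::rtree(n_taxa))
  tree$tip.label <- taxon_ids(n_taxa)
  tree
}

taxon_ids <- function(n) sprintf("ASV_%04d", seq_len(n))
participant_ids <- function(n) sprintf("P%04d", seq_len(n))

# Entropy (bits) of the two-block mixture at responder weight w.
mixture_entropy <- function(w, h_resp, h_bg) {
  hb <- function(x) ifelse(x <= 0 | x >= 1, 0, -x * log2(x) - (1 - x) * log2(1 - x))
  hb(w) + w * h_resp + (1 - w) * h_bg
}

# Geometric within-block weights and their entropy in bits.
geometric_block <- function(n, ratio) {
  w <- ratio^(seq_len(n) - 1)
  w <- w / sum(w)
  list(weights = w, entropy = -sum(w * log2(w)))
}

# Calibrate the latent -> realized Shannon map. Dirichlet resampling and
# finite sequencing depth shrink measured entropy by an amount that varies
# with evenness, which would attenuate planted slopes; simulating the
# measurement process on a grid of latent values and regressing realized on
# latent gives an affine map whose inverse makes the planted slope hold for
# the *measured* Shannon at the reference rarefaction depth.
calibrate_entropy_map <- function(resp, bg, theta, depth,
                                  h_range, n_grid = 15, n_rep = 40) {
  K <- length(resp$weights) + length(bg$weights)
  if (diff(h_range) < 0.5) h_range <- mean(h_range) + c(-0.5, 0.5)
  h_range <- pmin(pmax(h_range, bg$entropy + 0.05), log2(K) - 0.01)
  grid <- seq(h_range[1], h_range[2], length.out = n_grid)
  w <- solve_responder_weight(grid, resp$entropy, bg$entropy)
  realized <- vapply(seq_along(grid), function(i) {
    profile <- c(w[i] * resp$weights, (1 - w[i]) * bg$weights)
    mean(vapply(seq_len(n_rep), function(r) {
      g <- rgamma(K, shape = profile * theta)
      g[g == 0] <- 1e-12
      x <- rmultinom(1, depth, g / sum(g))[, 1]
      p <- x[x > 0] / depth
      -sum(p * log2(p))
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, grid), realized)
  list(a = fit$coefficients[1], b = fit$coefficients[2])
}

# Solve the responder-block weight whose mixture entropy matches `target`,
# restricted to the increasing branch so responder concentration grows with
# the target. Targets outside the attainable range are clamped.
solve_responder_weight <- function(target, h_resp, h_bg) {
  d_zero <- 1 / (1 + 2^(h_bg - h_resp)) # argmax of mixture entropy
  h_max <- mixture_entropy(d_zero, h_resp, h_bg)
  lo <- 1e-9
  vapply(target, function(h) {
    if (h >= h_max) return(d_zero)
    if (h <= mixture_entropy(lo, h_resp, h_bg)) return(lo)
    stats::uniroot(function(w) mixture_entropy(w, h_resp, h_bg) - h,
                   lower = lo, upper = d_zero, tol = 1e-10)$root
  }, numeric(1))
}

#' Generate a synthetic cohort
#'
#' Draws per-participant daily food-group intakes as gamma variates with the
#' participant's mean and CV target (shape `1/CV^2`, scale `mean * CV^2`),
#' derives nutrients and energy from a fixed per-group composition, computes
#' the latent diet-quality score by running the package's own day-wise HEI
#' scorer on the generated log, plants the configured diversity slopes, and
#' draws taxa counts Dirichlet-multinomial around entropy-targeted abundance
#' profiles. Stool categories are drawn daily from a softmax shifted by
#' `stool_coupling` times the diet-quality z-score. Identical configs
#' (including seed) give byte-identical outputs.
#'
#' @param config A [synth_config()].
#' @return A `synth_cohort` list: `food_log`, `feature_table`, `tree`,
#'   `metadata`, `stool_reports`, `truth`, `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  P <- config$n_participants; D <- config$n_days; K <- config$n_taxa
  fg <- config$food_groups
  G <- nrow(fg)
  pid <- participant_ids(P)

  food_log <- with_rng(substream_seed(config$seed, "foodlog"), {
    quality <- rnorm(P)
    cv_target <- runif(P, config$regularity_range[1], config$regularity_range[2]) / 100
    part_means <- exp(
      matrix(fg$meanlog, P, G, byrow = TRUE) +
        outer(quality, fg$quality_loading) +
        matrix(rnorm(P * G, sd = rep(fg$sdlog, each = P)), P, G)
    )
    # vector layout: participant fastest, then group, then day
    shape <- 1 / cv_target^2
    scale_pg <- as.vector(part_means * cv_target^2) # recycles cv^2 by participant
    log_dt <- data.table::data.table(
      participant_id = rep(pid, times = G * D),
      day = rep(seq_len(D), each = P * G),
      food_group = rep(rep(fg$group, each = P), times = D),
      grams = rgamma(P * G * D,
                     shape = rep(shape, times = G * D),
                     scale = rep(scale_pg, times = D))
    )
    # scale a fixed fraction of participant-days below the 1000-kcal QC bar,
    # preserving composition
    log_dt[, kcal := grams * fg$kcal_g[match(food_group, fg$group)]]
    day_kcal <- log_dt[, .(kcal = sum(kcal)), by = .(participant_id, day)]
    low <- runif(nrow(day_kcal)) < config$low_kcal_fraction
    day_kcal[, factor := data.table::fifelse(low, runif(.N, 600, 950) / pmax(kcal, 1), 1)]
    log_dt <- merge(log_dt, day_kcal[, .(participant_id, day, factor)],
                    by = c("participant_id", "day"))
    log_dt[, grams := grams * factor]
    log_dt[, factor := NULL]
    # split ~30% of group-days into two eating events
    split_frac <- runif(nrow(log_dt)) < 0.3
    share <- runif(nrow(log_dt), 0.2, 0.8)
    first <- data.table::copy(log_dt)[split_frac, grams := grams * share[split_frac]]
    second <- log_dt[split_frac][, grams := grams * (1 - share[split_frac])]
    events <- data.table::rbindlist(list(first, second))
    comp <- default_composition()
    gidx <- match(events$food_group, rownames(comp))
    events[, kcal := grams * fg$kcal_g[match(food_group, fg$group)]]
    for (nm in nutrient_columns()) {
      data.table::set(events, j = nm, value = events$grams * comp[gidx, nm])
    }
    events[, date := as.Date("2026-01-01") + day - 1L]
    events[, day := NULL]
    data.table::setorder(events, participant_id, date, food_group)
    events[, item_id := sprintf("item_%06d", seq_len(.N))]
    data.table::setcolorder(events, c("participant_id", "date", "item_id",
                                      "food_group", "grams", "kcal"))
    data.table::setattr(events, "cv_target", cv_target)
    events
  })
  cv_target <- attr(food_log, "cv_target")
  data.table::setattr(food_log, "cv_target", NULL)

  # latent diet quality: day-wise HEI over days meeting the energy bar,
  # computed with the package's own scorer on the generated log
  daily <- aggregate_daily(food_log)
  specs <- read_component_specs()
  scored_days <- daily[energy_kcal >= 1000]
  hd <- hei_daily(scored_days, specs)$score
  latent_hei <- hd$hei_daily[match(pid, hd$participant_id)]
  # participants with no >= 1000 kcal day fall back to the cohort mean score
  latent_hei[is.na(latent_hei)] <- if (nrow(hd)) mean(hd$hei_daily) else 60

  # planted latent diversity (bits)
  cv_pct <- cv_target * 100
  cv_center <- mean(config$regularity_range)
  h_base <- 4.5
  counts_seed <- substream_seed(config$seed, "counts")
  feature_table <- with_rng(counts_seed, {
    latent_h <- h_base +
      config$effect_hei_diversity * (latent_hei - 60) +
      config$effect_cv_diversity * (cv_pct - cv_center) +
      rnorm(P, sd = config$diversity_noise_sd)
    n_resp <- max(2L, as.integer(round(0.7 * K)))
    resp <- geometric_block(n_resp, 0.99)
    # skewed opportunist background: low entropy so targets well below the
    # uniform maximum stay inside the attainable range
    bg <- geometric_block(K - n_resp, 0.55)
    latent_h <- pmin(pmax(latent_h, bg$entropy + 0.1), log2(K) - 0.05)
    # invert the measurement shrinkage so planted slopes hold for measured
    # Shannon at the reference rarefaction depth
    cal <- calibrate_entropy_map(resp, bg, config$dirichlet_theta,
                                 depth = min(15000, config$seq_depth_mean),
                                 h_range = range(latent_h))
    target_h <- (latent_h - cal$a) / cal$b
    target_h <- pmin(pmax(target_h, bg$entropy + 0.05), log2(K) - 0.01)
    w <- solve_responder_weight(target_h, resp$entropy, bg$entropy)
    if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1)) {
      stop("planted concentrations degenerate; check effect sizes and ranges")
    }
    profile <- cbind(outer(w, resp$weights), outer(1 - w, bg$weights))
    alpha <- profile * config$dirichlet_theta
    gam <- matrix(rgamma(P * K, shape = alpha), P, K)
    gam[gam == 0] <- 1e-12
    probs <- gam / rowSums(gam)
    depth <- pmax(rnbinom(P, mu = config$seq_depth_mean, size = 50), 1000L)
    counts <- t(vapply(seq_len(P),
                       function(i) rmultinom(1, depth[i], probs[i, ])[, 1],
                       integer(K)))
    dimnames(counts) <- list(pid, taxon_ids(K))
    attr(counts, "latent_shannon") <- latent_h
    attr(counts, "responder_weight") <- w
    counts
  })
  latent_shannon <- attr(feature_table, "latent_shannon")
  responder_w <- attr(feature_table, "responder_weight")
  attr(feature_table, "latent_shannon") <- NULL
  attr(feature_table, "responder_weight") <- NULL

  tree <- generate_tree(K, seed = config$seed)

  metadata <- with_rng(substream_seed(config$seed, "metadata"), {
    bmi <- pmin(pmax(rnorm(P, 24, 3.5), 16), 42)
    data.table::data.table(
      participant_id = pid,
      age = round(runif(P, 18, 70)),
      bmi = round(bmi, 1),
      bmi_category = cut(bmi, c(-Inf, 18.5, 25, 30, Inf),
                         labels = c("underweight", "normal", "overweight", "obese"),
                         right = FALSE),
      gender = sample(c("female", "male"), P, replace = TRUE),
      smoking = sample(c("non-smoker", "smoker", "ex-smoker"), P,
                       replace = TRUE, prob = c(0.6, 0.2, 0.2)),
      defecation_freq = sample(c(0.5, 1, 1.5, 2, 3), P, replace = TRUE,
                               prob = c(0.15, 0.45, 0.2, 0.15, 0.05)),
      hunger = sample(1:10, P, replace = TRUE)
    )
  })

  stool_reports <- with_rng(substream_seed(config$seed, "stool"), {
    z <- as.numeric(scale(latent_hei))
    base <- log(c(great = 0.25, normal = 0.5, constipated = 0.13, diarrhea = 0.12))
    dir <- c(great = 1, normal = 0, constipated = -0.5, diarrhea = -1)
    util <- matrix(base, P, 4, byrow = TRUE) +
      config$stool_coupling * outer(z, dir)
    probs <- exp(util) / rowSums(exp(util))
    report_prob <- runif(P, 0.5, 1) # optional questionnaire compliance
    rows <- lapply(seq_len(P), function(i) {
      reported <- which(runif(D) < report_prob[i])
      if (!length(reported)) return(NULL)
      data.table::data.table(
        participant_id = pid[i],
        date = as.Date("2026-01-01") + reported - 1L,
        category = sample(names(dir), length(reported), replace = TRUE,
                          prob = probs[i, ])
      )
    })
    data.table::rbindlist(rows)
  })

  truth <- data.table::data.table(
    participant_id = pid,
    target_cv_pct = cv_pct,
    latent_hei = latent_hei,
    latent_shannon = latent_shannon,
    responder_weight = responder_w
  )

  structure(list(food_log = food_log, feature_table = feature_table,
                 tree = tree, metadata = metadata,
                 stool_reports = stool_reports, truth = truth,
                 config = config),
            class = "synth_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits `food_log.tsv`, `metadata.tsv`, `stool.tsv`, `truth.tsv`,
#' `feature_table.tsv`, `tree.nwk`, and — when biomformat is installed —
#' `feature_table.biom` (JSON BIOM).
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if absent).
#' @param biom Also write BIOM (default: if biomformat is available).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir,
                         biom = requireNamespace("biomformat", quietly = TRUE)) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  fw(cohort$food_log, "food_log.tsv")
  fw(cohort$metadata, "metadata.tsv")
  fw(cohort$stool_reports, "stool.tsv")
  fw(cohort$truth, "truth.tsv")
  ft <- data.table::as.data.table(cohort$feature_table, keep.rownames = "sample_id")
  fw(ft, "feature_table.tsv")
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  if (biom) {
    b <- biomformat::make_biom(t(cohort$feature_table))
    biomformat::write_biom(b, file.path(dir, "feature_table.biom"))
  }
  invisible(dir)
}
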