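# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# Minimal food-log row with all nutrient columns zero unless overridden.
log_row <- function(participant_id, date, food_group, grams, kcal,
                    item_id = "item", ...) {
  row <- data.table::data.table(
    participant_id = participant_id, date = as.Date(date), item_id = item_id,
    food_group = food_group, grams = grams, kcal = kcal
  )
  for (nm in dietrhythm::nutrient_columns()) {
    data.table::set(row, j = nm, value = 0)
  }
  dots <- list(...)
  for (nm in names(dots)) data.table::set(row, j = nm, value = dots[[nm]])
  row
}

# One "day" of intake rows replicated over n_days dates (constant diet).
constant_diet_log <- function(pid, day_rows, n_days) {
  data.table::rbindlist(lapply(seq_len(n_days), function(d) {
    rows <- data.table::copy(day_rows)
    data.table::set(rows, j = "date", value = as.Date("2026-03-01") + d - 1L)
    data.table::set(rows, j = "participant_id", value = pid)
    rows
  }))
}

# A one-day menu whose densities saturate every adequacy component and sit
# at/below every moderation full-score threshold of the shipped HEI-2020
# config (2000 kcal reference day).
ideal_day_rows <- function(participant_id = "P1", date = "2026-03-01") {
  data.table::rbindlist(list(
    log_row(participant_id, date, "fruits", grams = 300, kcal = 165),
    log_row(participant_id, date, "vegetables", grams = 400, kcal = 140),
    log_row(participant_id, date, "grains_cereals", grams = 180, kcal = 470,
            sfa = 1, mufa = 2, pufa = 2, sodium = 0.3),
    log_row(participant_id, date, "dairy", grams = 650, kcal = 520,
            sfa = 5, mufa = 3, pufa = 1, sodium = 0.3),
    log_row(participant_id, date, "meat", grams = 100, kcal = 220,
            sfa = 4, mufa = 6, pufa = 2, sodium = 0.2),
    log_row(participant_id, date, "oils_nuts", grams = 50, kcal = 485,
            sfa = 4, mufa = 18, pufa = 12, added_sugar = 5)
  ))
}

# A one-day menu scoring zero: nothing but refined-grain-rich fast food and
# sugar past every moderation zero threshold, no adequacy intake.
worst_day_rows <- function(participant_id = "P1", date = "2026-03-01") {
  data.table::rbindlist(list(
    log_row(participant_id, date, "fast_food", grams = 650, kcal = 1820,
            sfa = 35, mufa = 3, pufa = 1, sodium = 4, added_sugar = 90),
    log_row(participant_id, date, "sugary_foods", grams = 45, kcal = 180,
            sfa = 5, mufa = 0, pufa = 0, sodium = 1, added_sugar = 45)
  ))
}

# Small deterministic feature table.
toy_counts <- function(n_samples = 6, n_taxa = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, 20), n_samples, n_taxa)
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                      sprintf("T%02d", seq_len(n_taxa)))
  m
}

# Independent oracle for Faith's PD / unweighted UniFrac built on root-to-tip
# path enumeration with ape::nodepath (never touches the package's
# edge-incidence machinery).
observed_edge_set <- function(tree, taxa) {
  root <- length(tree$tip.label) + 1L
  edges <- character()
  for (tx in taxa) {
    tip <- match(tx, tree$tip.label)
    path <- ape::nodepath(tree, from = root, to = tip)
    for (i in seq_len(length(path) - 1)) {
      edges <- c(edges, paste(path[i], path[i + 1]))
    }
  }
  unique(edges)
}

edge_length_lookup <- function(tree) {
  stats::setNames(tree$edge.length, paste(tree$edge[, 1], tree$edge[, 2]))
}

oracle_faith_pd <- function(tree, taxa) {
  if (!length(taxa)) return(0)
  sum(edge_length_lookup(tree)[observed_edge_set(tree, taxa)])
}

oracle_unifrac_pair <- function(tree, taxa_a, taxa_b) {
  len <- edge_length_lookup(tree)
  ea <- observed_edge_set(tree, taxa_a)
  eb <- observed_edge_set(tree, taxa_b)
  shared <- intersect(ea, eb)
  uni <- sum(len[union(ea, eb)]) - sum(len[shared])
  uni / sum(len[union(ea, eb)])
}

# Small synthetic cohort for integration-style tests.
small_cohort <- function(seed = 7, n = 120, ...) {
  generate_cohort(synth_config(n_participants = n, n_days = 14, n_taxa = 80,
                               seq_depth_mean = 8000, seed = seed, ...))
}

# Shannon (bits) on raw counts, for correlation-sign checks where rarefaction
# is irrelevant.
raw_shannon <- function(counts) {
  p <- counts / rowSums(counts)
  -rowSums(ifelse(p > 0, p * log2(p), 0))
}
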