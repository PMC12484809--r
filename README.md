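# dietrhythm

Tools for asking how both **diet quality** and **day-to-day dietary
regularity** shape the gut microbiome, from longitudinal food logs and 16S
feature tables. The package targets analysts working with app-based food
diaries (participant × day × eating-event records) paired with a single
stool-sample microbiome profile per participant — and ships a seeded
synthetic-cohort generator with planted diet–microbiome effects, so every
stage of the pipeline is testable without access-restricted cohort data.

## What it computes

**Diet quality.** The Healthy Eating Index (HEI-2020) in two forms: the
standard score, computed once from across-day mean intakes, and the
*day-wise* score — HEI computed separately for each tracking day and averaged
per participant,

```
HEI_daily(i) = (1/D_i) * sum_d HEI(intake_{i,d})
```

which additionally penalizes irregular diet quality. Components are scored by
linear interpolation between energy-adjusted density cut-points
(adequacy components rise with density, moderation components fall), summing
to 100; the component set is a versioned YAML config
(`inst/extdata/hei2020.yaml`), so other index standards can be expressed
without code changes.

**Dietary regularity.** The day-to-day coefficient of variation per
nutrient/food group, `CV = SD/mean × 100%` (sample SD) over QC'd tracking
days, where days under 1000 kcal are dropped and participants with fewer than
6 remaining days are excluded. Dietary diversity indices (DDS, Shannon in
nats, Gini–Simpson) summarize daily kilocalorie shares across food groups.

**Microbiome.** Rarefaction to a fixed depth (default 15 000 reads),
prevalence filtering (~25% of samples), CLR transform, alpha diversity
(Shannon in bits, Pielou, observed features, Faith's PD), unweighted UniFrac,
and PCoA via Gower double-centering.

**Compositional log ratios.** Per-taxon differential effects against a
dietary variable (CLR-OLS slope per SD with bootstrap percentile intervals; a
taxon is *credible* when its 95% interval excludes zero), selection of the
top-k credible taxa split by effect sign into numerator/denominator reference
frames, and the per-sample statistic
`log10(sum counts numerator / sum counts denominator)`, correlated back to
the variable (Pearson). Externally computed effect tables can be ingested via
`read_effect_table()`.

**Associations and effect sizes.** Partial Spearman correlations
(rank-then-residualize) with Benjamini–Hochberg FDR control (threshold 0.1),
the Shannon-on-diet multiple regression with declared factor reference
levels, variance partitioning by feature block, and Cohen's d/f.

**Stool quality.** Per-participant proportions of daily self-reported
categories (great/normal/constipated/diarrhea; ≥5 reported days), top-k
classification, and Spearman screens against all cohort variables.

**Prediction harness.** Bidirectional gradient-boosted-tree prediction:
classify extreme quartiles (Q1 vs Q4) of diet variables from taxa, or of
alpha-diversity metrics from diet/lifestyle features, over repeated seeded
80:20 splits with AUROC/AUPRC (or Spearman for regression over the full
range) and gain-based feature importance. The boosted-tree learner is a
compact Rcpp implementation (this stack ships no gradient-boosting package)
exposing the standard hyperparameter surface.

## Worked example

```r
library(dietrhythm)

cfg    <- synth_config(n_participants = 300, n_taxa = 120, seed = 7)
cohort <- generate_cohort(cfg)

daily   <- qc_filter(aggregate_daily(cohort$food_log))
profile <- diet_profile(daily)
alpha   <- alpha_metrics(rarefy(cohort$feature_table, 15000, seed = 7),
                         cohort$tree)
frame   <- build_cohort_frame(profile, alpha, cohort$metadata)

associate(frame,
          features = c("hei", "hei_daily", "cv_vegetables", "cv_fruits"),
          targets = "shannon", covariates = c("age", "bmi"))
#>          feature partial_rho    p_raw    q_fdr     n
#> 1:     cv_fruits      -0.493 1.41e-18 2.82e-18   282
#> 2: cv_vegetables      -0.482 1.04e-17 1.38e-17   282
#> 3:           hei       0.440 1.07e-14 1.07e-14   282
#> 4:     hei_daily       0.539 1.60e-22 6.41e-22   282

fit <- fit_diversity_regression(frame, shannon ~ hei_daily + age + bmi)
fit$coefficients[fit$coefficients$term == "hei_daily"]
#>         term estimate      se     t        p ci_low ci_high
#> 1: hei_daily   0.0213 0.00185  11.5 3.03e-25 0.0176  0.0249
```

The planted world is recovered: both HEI forms associate positively with
Shannon diversity — the day-wise form more strongly than the standard form —
intake-CV associations are negative, and the regression slope's 95% CI covers
the planted 0.019 bits per day-wise HEI point.

## Command line

`inst/cli/dietrhythm.R` exposes `simulate`, `score-diet`, `alpha`, `beta`,
and `logratio` subcommands over TSV/Newick inputs; see the header of that
file for usage.
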