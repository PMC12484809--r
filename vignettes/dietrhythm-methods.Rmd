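---
title: "Models and methods behind dietrhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dietrhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the numerical choices
that matter. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The analysis problem

Longitudinal food logs (every eating event of every tracking day) make two
quantities observable that a food-frequency questionnaire cannot deliver:
*day-wise diet quality* and *temporal regularity of intake*. The package's
pipeline links those to a single per-participant gut microbiome profile:
diet-quality scoring, regularity metrics, microbial diversity, per-taxon
differential effects with compositional log ratios, covariate-adjusted
association tests, stool-quality features, and a bidirectional prediction
harness.

## Diet quality: standard and day-wise HEI

A diet-index component set is a list of adequacy and moderation components,
each with an energy-adjusted density basis (amount per 1000 kcal, percent of
energy, or a plain ratio) and two cut-points. Scores interpolate linearly
between `zero_score_at` and `full_score_at` and are clamped to
`[0, max_points]`. The shipped HEI-2020 set totals 100 points.

Two participant-level scores are computed. The **standard** score derives
densities from across-day mean intakes and mean energy; the **day-wise**
score computes a full HEI per tracking day and averages the day scores. On a
perfectly constant diet the two are identical — the package guarantees this
*bit-exactly* by using long-double mean accumulation in both paths (a
data.table `GForce`-optimized group mean accumulates in double precision and
breaks the identity in the last ulp, so both scorers deliberately bypass it).
On variable diets the day-wise score is additionally sensitive to quality
regularity, because the clamped component map is concave near saturation.

**Gram-to-equivalent conversions.** The log records food groups in grams,
not cup/oz equivalents, and no authoritative mapping accompanies such data.
The shipped config embeds approximate conversions (150 g per cup-equivalent
of fruit/vegetables, 245 g per cup-equivalent dairy, 28.35 g per
oz-equivalent) and fixed sub-group fractions (half of fruit counted as whole
fruit, half of grains as whole grains, a fifth of vegetables as greens and
beans; refined grains drawn from the grain, fast-food and sugary-food
groups). These are documented approximations, fully configurable in the YAML,
and the scoring engine itself is standard-agnostic. The refined-grain mapping
deliberately includes fast food so that a "worst-case" menu can reach the
zero thresholds of every moderation component while all adequacy components
are empty — with refined grains tied only to the grain group, whole and
refined grains would be perfectly coupled and the scale's lower boundary
unreachable.

**Degenerate densities.** A fatty-acid ratio of 0/0 scores zero points; a
positive-over-zero ratio is treated as infinite density and saturates the
adequacy component.

## Quality control and regularity

Tracking days below 1000 kcal are dropped, then participants with fewer than
6 remaining days are excluded entirely ("5 or fewer days" read strictly).
The exclusion report reconciles exactly: input days = kept + dropped. The QC
threshold is applied before *all* diet metrics (an open design point — it
could be restricted to CV computation alone — resolved here as a single
toggleable gate, keeping every metric on the same day set).

The regularity metric is `CV = sample SD / mean × 100` over QC'd tracking
days, with the n−1 denominator because per-participant day counts are small.
A group not eaten on a tracked day contributes an explicit 0 g — a tracked
day is defined by the participant logging anything that day — since a CV over
tracking days needs a value for every day. CV is undefined (missing) for a
zero-mean series or fewer than two days.

Dietary diversity uses daily kilocalorie shares across food groups: DDS
(groups above a threshold, default any positive grams), Shannon in nats, and
Gini–Simpson; participant values are across-day means.

## Microbiome processing

Rarefaction subsamples each retained sample without replacement to exactly
the target depth (default 15 000 reads; shallower samples are dropped and
reported). Shannon diversity uses log base 2 — the convention of the
dominant amplicon toolchain — with the base switchable; Pielou's evenness is
Shannon over log observed features (undefined for single-taxon samples).
Faith's PD and unweighted UniFrac share an edge-by-tip incidence
representation of the rooted tree; UniFrac is unique branch length over
total observed branch length per sample pair. The CLR transform
(`log(x + 1) − row mean of logs`) is applied to *raw* counts — pseudocount 1,
pre-rarefaction — matching the convention of count-model differential
abundance tools. PCoA double-centers `−D²/2` and drops negative eigenvalues
without correction (reported via message); proportions explained are over
positive eigenvalues only.

## Differential effects and log ratios

The effect estimator is an explicit surrogate for a Bayesian negative
binomial mixed model: per taxon, the OLS slope of CLR abundance on the
standardized variable, with 95% percentile intervals over sample-level
bootstrap resamples (default 500, mapping the posterior-draw count of the
original approach). With one stool sample per subject, subject-level random
effects are not identifiable anyway, and `read_effect_table()` ingests
externally computed posterior summaries so the downstream log-ratio stage is
unchanged when a genuine Bayesian fit exists. Standardization uses the
population SD, which makes the per-SD slope exactly invariant under sample
duplication.

Reference frames take the top-k credible taxa by |mean effect| (ties broken
by taxon ID for determinism) and split them by sign; ranking by absolute
effect is this package's choice, not a claim about any particular study's
rule. Samples with zero counts in either frame, or null metadata, are
removed and reported; the log ratio is base-10 of the summed-count ratio,
exactly invariant to per-sample depth scaling.

## Associations

Partial Spearman correlation ranks first (average ties) and residualizes the
ranks on covariates by least squares — rank-then-residual, not
residual-then-rank — then correlates residuals, with a t-based p-value on
n − 2 − k degrees of freedom. FDR control is Benjamini–Hochberg at threshold
0.1 (a source figure caption's "FDR Bonferroni Hochberg" wording is read as
Benjamini–Hochberg). The diversity regression is OLS with declared factor
reference levels (BMI "normal", smoking "non-smoker"); the canonical
specification regresses Shannon on day-wise HEI with age and BMI continuous
and no interactions. Cohen's d covers binary groupings; Cohen's f from
one-way ANOVA η² covers multi-category ones.

## Stool features

Participants with ≥5 reported days get per-category proportions over
*reported* days (so the four proportions sum to one). Classification labels
the top-20 by diarrhea proportion, then top-20 constipated, then top-50
great, remainder normal — extreme categories take precedence as the
clinically salient signal, each extreme label requires a strictly positive
proportion, and ties at the k-th rank break by participant ID. The
precedence order is this package's resolution of an underdetermined rule,
not a reconstruction of any study's.

## Prediction harness

Extreme-quartile labels use linear-interpolation quantiles at 25/75% with
the middle half excluded; Q4 is the positive class for AUPRC. Each of the
(default 100) iterations draws a seeded 80:20 split — stratified for
classification, plain random for regression — fits the boosted-tree learner,
and scores the held-out fold; gain importances accumulate across iterations.
Features with mean below 0.001 are log10(x + 1e-6)-transformed. Iteration
seeds are `seed_base + i` and recorded.

No gradient-boosting package exists in this R stack, so the learner is a
compact Rcpp implementation of second-order boosting: exact greedy splits,
level-wise depth-limited growth, per-tree row/column subsampling, L1/L2 leaf
regularization (classification defaults: 1000 trees, depth 6, colsample 0.8,
subsample 0.4, alpha 0.1, learning rate 0.005; regression: 1000 trees,
learning rate 0.05). It uses its own mt19937 stream, so results are
reproducible and independent of R's RNG state.

**The permutation null.** `run_harness(..., permute_target = TRUE)`
re-permutes the target under each iteration's seed. A single up-front
permutation leaves dataset-level chance correlations between features and
labels that every subsequent split rediscovers — median AUROC over splits
then concentrates near that dataset's chance level, which can sit far from
0.5 for one unlucky draw. Per-iteration permutation destroys that shared
structure and centers the null where a calibration check needs it.

## The synthetic cohort: what is emulated, what is not

Defaults state the emulated world: 1000 participants tracking 14 days
("at least two weeks"), ~200 taxa, mean library size 20 000 reads, intake-CV
targets uniform on 20–120%, 20% of days drawn under 1000 kcal to exercise
the QC gate, and stool reports with partial compliance so the 5-day filter
binds.

Daily food-group intakes are gamma (shape 1/CV², scale mean·CV²): positive
with exact mean/CV control. Participant mean intakes are log-normal around
group-level baselines, moved by a latent "healthiness" factor with positive
loadings on vegetables/fruits/oils-nuts and negative on sugary/fast food —
this induces realistic between-participant HEI spread. Energy and nutrients
derive from a fixed per-group composition table of plausible magnitudes (not
a nutrient database).

The planted diversity structure works in measured-Shannon units: latent
Shannon = base (4.5 bits) + `effect_hei_diversity` × (day-wise HEI − 60) +
`effect_cv_diversity` × (CV − range midpoint) + N(0, 0.3 bits). The day-wise
HEI used for planting is computed by the package's own scorer on the
generated log, so the planted predictor is *identical* to what a downstream
analyst recomputes — no errors-in-variables attenuation. The default HEI
slope is 0.019 bits per point, the regression-scale effect the pipeline is
expected to recover; the CV slope default (−0.005 bits per CV percentage
point) and the stool coupling (0.3 on the report log-odds scale) are chosen
to give moderate, clearly detectable signals at cohort scale.

A target entropy is realized as a two-block mixture: a "responder" block
(70% of taxa, near-uniform within) whose total weight grows with the target,
and a skewed opportunist background (geometric, ratio 0.55 — low entropy so
targets well below the uniform maximum stay attainable); the block weight is
solved from the closed-form mixture entropy. Counts are
Dirichlet-multinomial (concentration 2000) with negative-binomial library
sizes. Because Dirichlet jitter and finite depth shrink measured entropy by
an evenness-dependent amount, the generator calibrates the latent→realized
map by simulating the measurement process on a grid and inverting the fitted
affine map — so the planted slope holds for *measured* Shannon at the
reference rarefaction depth, which is what the acceptance-grade parameter
recovery checks.

Not emulated: realistic food-item vocabularies, sequencing error, taxonomic
structure in the tree (it is a random coalescent-style topology),
confounding between metadata and diet (age/BMI/smoking are independent noise
by design — so covariate adjustment is exercised, not stressed), and
multi-sample-per-subject designs. A green test on this cohort establishes
that the pipeline recovers planted effects of stated size under clean
conditions; it does not establish robustness to confounding or measurement
error in real cohorts.

## Numerical and design notes

- All generator randomness flows from one root seed through named substreams
  (foodlog/counts/tree/stool/metadata), so adding a component never perturbs
  another's draws; identical configs give byte-identical emitted files.
- Component configs are YAML; effect tables, profiles, distance matrices and
  cohort emissions are TSV (BIOM additionally when biomformat is present).
- `fdr_adjust` wraps the standard BH step-up; it never decreases a p-value.
- Bootstrap intervals use 2.5/97.5 percentiles; `mean_effect` is the
  bootstrap mean, the direct analogue of a posterior mean.
- The acceptance-scale simulations in `tests/testthat/test-acceptance.R` run
  at the stated sizes (50 seeds × 900 participants; 20 seeds × 500; 500 FDR
  replicates; 25 harness iterations at n = 400). A few *module*-level
  simulation tests are scaled down from spec-scale (noted inline) to keep
  the default suite fast; the acceptance file is the authoritative check.

## Known limitations

The HEI gram-to-equivalent conversions are approximations; absolute HEI
levels on real logs should be interpreted with that in mind (comparisons and
regressions within a cohort are unaffected by monotone mapping error to
first order). The bootstrap-OLS effect surrogate shares signs and ordering
with count-model posteriors but not magnitudes. The boosted-tree learner
targets fidelity of the harness contract, not feature-parity with xgboost
(no sparsity-aware splits, no histogram approximation); at cohort scales
used here it is exact greedy, which if anything is the stronger baseline.
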