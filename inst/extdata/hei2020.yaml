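# Healthy Eating Index 2020 component standards.
#
# Cut-points transcribe the published HEI-2020 scoring standard (13
# components, 5- or 10-point maxima, densities per 1000 kcal, percent of
# energy, or a fatty-acid ratio). Source food logs record food groups in
# grams, not USDA cup/oz equivalents, so each `numerator` is an arithmetic
# expression over per-day intake columns embedding APPROXIMATE gram-per-
# equivalent conversions (150 g per cup-eq fruit/vegetable, 245 g per cup-eq
# dairy, 28.35 g per oz-eq) and fixed sub-group fractions (half of fruit as
# whole fruit, half of grains as whole grains, a fifth of vegetables as
# greens and beans). These conversions are a documented approximation and are
# fully configurable: the scoring engine is standard-agnostic.
#
# density_basis:
#   per-1000-kcal    density = numerator / (energy_kcal / 1000)
#   percent-of-energy density = 100 * numerator / energy_kcal (numerator in kcal)
#   ratio            density = numerator as-is
version: HEI-2020
components:
  - name: total_fruits
    direction: adequacy
    max_points: 5
    density_basis: per-1000-kcal
    numerator: fruits / 150
    full_score_at: 0.8
    zero_score_at: 0.0
  - name: whole_fruits
    direction: adequacy
    max_points: 5
    density_basis: per-1000-kcal
    numerator: 0.5 * fruits / 150
    full_score_at: 0.4
    zero_score_at: 0.0
  - name: total_vegetables
    direction: adequacy
    max_points: 5
    density_basis: per-1000-kcal
    numerator: vegetables / 150
    full_score_at: 1.1
    zero_score_at: 0.0
  - name: greens_and_beans
    direction: adequacy
    max_points: 5
    density_basis: per-1000-kcal
    numerator: 0.2 * vegetables / 150
    full_score_at: 0.2
    zero_score_at: 0.0
  - name: whole_grains
    direction: adequacy
    max_points: 10
    density_basis: per-1000-kcal
    numerator: 0.5 * grains_cereals / 28.35
    full_score_at: 1.5
    zero_score_at: 0.0
  - name: dairy
    direction: adequacy
    max_points: 10
    density_basis: per-1000-kcal
    numerator: dairy / 245
    full_score_at: 1.3
    zero_score_at: 0.0
  - name: total_protein_foods
    direction: adequacy
    max_points: 5
    density_basis: per-1000-kcal
    numerator: (meat + oils_nuts) / 28.35
    full_score_at: 2.5
    zero_score_at: 0.0
  - name: seafood_plant_proteins
    direction: adequacy
    max_points: 5
    density_basis: per-1000-kcal
    numerator: oils_nuts / 28.35
    full_score_at: 0.8
    zero_score_at: 0.0
  - name: fatty_acids
    direction: adequacy
    max_points: 10
    density_basis: ratio
    numerator: (mufa + pufa) / sfa
    full_score_at: 2.5
    zero_score_at: 1.2
  - name: refined_grains
    direction: moderation
    max_points: 10
    density_basis: per-1000-kcal
    numerator: (0.5 * grains_cereals + 0.5 * fast_food + 0.25 * sugary_foods) / 28.35
    full_score_at: 1.8
    zero_score_at: 4.3
  - name: sodium
    direction: moderation
    max_points: 10
    density_basis: per-1000-kcal
    numerator: sodium
    full_score_at: 1.1
    zero_score_at: 2.0
  - name: added_sugars
    direction: moderation
    max_points: 10
    density_basis: percent-of-energy
    numerator: added_sugar * 4
    full_score_at: 6.5
    zero_score_at: 26.0
  - name: saturated_fats
    direction: moderation
    max_points: 10
    density_basis: percent-of-energy
    numerator: sfa * 9
    full_score_at: 8.0
    zero_score_at: 16.0
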