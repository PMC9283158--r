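# Worked-example multiverse configuration (synthetic column roles).
# Decision-point option ids must match the built-in resolvers:
# determinant, confounder_set, confounder_strategy, age_group, interaction.
roles:
  determinant: pct_weight_change
  mediator: fat_mass_kg
  outcome: bmd_mg_cm2
  pre_weight: lowest_weight_kg
  post_weight: weight_kg
  age: age
covariate_sets:
  full: [height_cm, age, smoking, alcohol_per_week, walking_min_day, sports,
         copd, stroke, arthritis, diabetes, corticosteroid_use, estrogen_use,
         shbg, pth, vitd_25oh, igf1, albumin]
  no_hormonal: [height_cm, age, smoking, alcohol_per_week, walking_min_day,
                sports, copd, stroke, arthritis, diabetes,
                corticosteroid_use, estrogen_use]
parameters:
  alpha: 0.05
  proportion_threshold: 20
  cie_threshold: 10
  reliability: 0.822
  age_threshold: 75
  n_draws: 20000
  seed: 1
decision_points:
  - name: determinant
    options: [continuous, increased_vs_stable, decreased_vs_stable]
  - name: confounder_set
    options: [full, no_hormonal]
  - name: confounder_strategy
    options: [a_priori, change_in_estimate]
  - name: age_group
    options: [all, under_75, over_75]
  - name: interaction
    options: [none, pure, total]
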