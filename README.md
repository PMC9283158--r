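# medmultiverse

Multiverse analysis of single-mediator models: enumerate every reasonable
combination of data-analytical decisions, run the full mediation analysis in
each resulting "universe", and summarise how robust the direct, indirect and
total effect estimates are with specification curves.

## The problem

A mediation analysis decomposes a total determinant–outcome effect into an
indirect effect transmitted through a mediator and a residual direct effect.
The classical three-equation system is

```
Y = i1 + c  X + e1            (total effect)
M = i2 + a  X + e2            (determinant -> mediator)
Y = i3 + c' X + b M + e3      (mediator -> outcome, direct effect)
```

with the indirect effect estimated as the product of coefficients `ab` or the
difference `c − c'`. Every concrete analysis of this kind rests on a stack of
arbitrary-but-defensible choices — how the determinant is coded, which
confounders are adjusted and how they were chosen, whether effects are
stratified by a moderator, whether a determinant–mediator interaction is
modelled, and which criterion declares "mediation present". A multiverse
analysis makes those researcher degrees of freedom explicit: declare each
decision point with its options, run *all* combinations, and report the whole
distribution of estimates instead of one hand-picked model.

`medmultiverse` implements this workflow for linear single-mediator models:

- **Decision grid** — `decision_point()` / `enumerate_universes()` build the
  Cartesian product of declared options; `detect_redundancy()` collapses
  universes whose resolved model specifications coincide. The built-in
  worked-example grid (`lasa_decision_points()`) covers determinant coding
  (continuous % weight change, or Edwards–Nunnally categories increased/
  decreased vs stable), two confounder panels (with and without hormonal
  markers), a-priori vs ≥10% change-in-estimate confounder selection, age
  moderation (all ages, <75, ≥75 via simple slopes), and interaction handling
  (none, pure, or total natural effects): 3 × 2 × 2 × 3 × 3 = 108 universes,
  36 distinct total-effect specifications.
- **Estimation** — OLS path coefficients (`estimate_paths()`,
  `simple_slopes()`); pure/total natural direct and indirect effects for the
  linear outcome model with determinant–mediator interaction
  (`natural_effects()`): with interaction coefficient `h` and mediator
  baseline `mu0`, `PNIE = (b + h x0) a (x1−x0)`,
  `TNIE = (b + h x1) a (x1−x0)`, `PNDE = (c' + h(mu0 + a x0))(x1−x0)`,
  `TNDE = (c' + h(mu0 + a x1))(x1−x0)`, with
  `PNDE + TNIE = TNDE + PNIE = total`.
- **Inference** — Monte Carlo confidence intervals (`monte_carlo_ci()`):
  coefficient vectors sampled from their estimated sampling distribution,
  percentile interval of the effect across draws; two mediation verdicts per
  universe (causal steps + proportion mediated ≥ 20%, and the CI of the
  indirect effect).
- **Reporting** — `summarize_verdicts()`, two-panel specification curves
  (`build_curve()`, `autoplot()`, `render_curve()`), CSV/JSON writers with a
  run manifest, and a CLI (`inst/cli/medmultiverse.R`).
- **Synthetic data** — a seeded generator (`simulate_mediation_data()`)
  emulating a cohort-style weight-change / fat-mass / bone-mineral-density
  mediation structure with known ground truth, so the whole pipeline is
  testable without any restricted data access.

## Worked example

```r
library(medmultiverse)

d <- simulate_mediation_data(mediation_sim_config(n = 264, seed = 1))
paths <- estimate_paths(d, "pct_weight_change", "fat_mass_kg", "bmd_mg_cm2",
                        covariates_outcome = lasa_multiverse_config()$covariate_sets$full)
tidy(paths)
#> # A tibble: 4 × 6
#>   path    term  estimate std.error statistic   p.value
#>   <chr>   <chr>    <dbl>     <dbl>     <dbl>     <dbl>
#> 1 c       .x       2.08     2.68       0.775 0.439
#> 2 a       .x       0.124    0.0307     4.04  0.0000741
#> 3 b       .m      13.4      5.76       2.33  0.0206
#> 4 c_prime .x       0.415    2.75       0.151 0.880
```

Per percentage point of weight gain, fat mass rises by `a` = 0.124 kg; each
kilogram of fat mass adds `b` = 13.4 mg/cm² of bone mineral density after
adjustment, so the indirect effect is `ab` ≈ 1.7 mg/cm² per percent — while
the direct effect `c'` is near zero and the total effect is not significant
on its own.

Running the full multiverse:

```r
res <- run_multiverse(d, config = lasa_multiverse_config(seed = 1))
summarize_verdicts(res)
#> # A tibble: 7 × 4
#>   metric                numerator denominator percent
#>   <chr>                     <int>       <int>   <dbl>
#> 1 mediated_criteria             0         108     0
#> 2 mediated_ci                  46         108    42.6
#> 3 indirect_significant         46         108    42.6
#> 4 direct_negative              39         108    36.1
#> 5 direct_nonsignificant       108         108   100
#> 6 total_positive               30          36    83.3
#> 7 total_significant             0          36     0
```

The indirect-effect CI declares mediation in 42.6% of the universes while the
causal-steps-plus-proportion criterion never fires here — the total effect is
too noisy at this sample size to pass the causal-steps gate, the classic
divergence between the two criteria. The original specification (first option
of every decision point) sits at rank 49 of 108, with an indirect effect of
1.66 mg/cm² per percent weight change, 95% Monte Carlo CI [0.25, 3.49]:

```r
cv <- build_curve(res, "indirect")
cv
#> <spec_curve> 108 indirect effect estimates, original specification at rank 49
autoplot(cv)                       # two-panel specification curve
render_curve(cv, "curve.svg")      # deterministic SVG
```

A shell-level interface wraps the same functions:

```sh
Rscript inst/cli/medmultiverse.R simulate --out data.csv --n 264 --seed 1
Rscript inst/cli/medmultiverse.R run --data data.csv --out results/
Rscript inst/cli/medmultiverse.R summarize --data results/results.csv
```

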