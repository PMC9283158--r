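---
title: "Multiverse mediation analysis: models, decisions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiverse mediation analysis: models, decisions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `medmultiverse`, the
decision grid it iterates over, and the design choices the package makes
where several defensible options exist.

## The mediation model

For determinant $X$, mediator $M$, outcome $Y$ and covariate vector $C$, the
package fits three linear regressions by ordinary least squares:

$$Y = i_1 + cX + \gamma_1'C + \varepsilon_1$$
$$M = i_2 + aX + \gamma_2'C + \varepsilon_2$$
$$Y = i_3 + c'X + bM + hXM + \gamma_3'C + \varepsilon_3$$

The total effect is $c$, the determinant–mediator path $a$, the
mediator–outcome path $b$ (adjusted for $X$), the direct effect $c'$, and
$h$ the optional determinant-by-mediator interaction ($h$ is this package's
symbol for that coefficient; the traditional literature names the term but
assigns it no letter). In the no-interaction case the indirect effect is the
product of coefficients $ab$, which equals the difference in coefficients
$c - c'$ *exactly* whenever equations 1 and 3 use the same covariate set —
an algebraic property of linear OLS that the test suite asserts to $10^{-8}$
across the engine's unmoderated no-interaction universes.

Standard errors are classical (homoskedastic), and coefficient tests use the
t distribution on the residual degrees of freedom rather than the normal:
several universes analyse small strata (e.g. the weight-loss category has a
few dozen subjects), where the difference matters. Robust standard errors,
generalized linear models, weighting and random effects are out of scope.

Missing data are handled by complete-case filtering per universe, never by
imputation: the setting this package targets has per-column missingness in
the low single digits percent, where complete-case analysis is defensible,
and the number of complete cases is reported per universe row.

### Natural effects with interaction

With the interaction term present, "the" indirect effect becomes ambiguous
and the package estimates pure and total natural direct/indirect effects
from the fitted coefficients. Writing $\mu_0$ for the mediator model's
expected value at $X = 0$ and a fixed covariate profile, the closed forms
for a contrast $x_0 \to x_1$ are

$$\mathrm{PNDE} = (c' + h(\mu_0 + a x_0))(x_1 - x_0), \quad
  \mathrm{TNDE} = (c' + h(\mu_0 + a x_1))(x_1 - x_0)$$
$$\mathrm{PNIE} = (b + h x_0)\,a\,(x_1 - x_0), \quad
  \mathrm{TNIE} = (b + h x_1)\,a\,(x_1 - x_0)$$

with $\mathrm{PNDE} + \mathrm{TNIE} = \mathrm{TNDE} + \mathrm{PNIE} =
\text{total}$, and the no-interaction reduction
$\mathrm{PNIE} = \mathrm{TNIE} = ab(x_1 - x_0)$. These are regression-based
plug-in estimators; a resampling estimator (simulating potential mediator
values from the fitted mediator model, including its residual distribution)
exists in the test suite as an independent oracle and agrees with the closed
forms to Monte Carlo error.

**Covariate profile.** When $h \ne 0$ the direct effects depend on where the
covariates are held. The package evaluates effects at the analysis sample's
covariate means (dummy-expanded factors enter through the means of their
indicator columns), because conditional-at-the-mean is the conventional
reporting point; the profile is stored in the output and can be overridden
per call. When $h = 0$ the indirect effects are profile-free.

**Determinant contrasts.** The continuous determinant uses $x_0 = 0$,
$x_1 = 1$ (one percentage point of weight change) by default. Each
categorical coding is a separate universe contrasting one change category
against stable weight, with $x_0 = 0$, $x_1 = 1$ on the category indicator.

## Monte Carlo confidence intervals

The sampling distribution of $ab$ (and of the natural effects) is skewed, so
symmetric normal-theory intervals are a poor fit. The package draws
coefficient vectors from a multivariate normal centred at the estimates with
the estimated coefficient covariance, evaluates the effect on each draw, and
takes the percentile interval. The mediator-model and outcome-model blocks
are drawn independently — they come from separate regressions with
independent error assumptions, so their estimators are asymptotically
independent given the design.

Defaults: 20 000 draws and a recorded seed, which stabilises the interval
endpoints to roughly two decimal places at the worked example's scale; the
same seeded draw stream makes every interval bit-reproducible. Per-universe
seeds are derived deterministically from the run seed and universe id.
Degenerate (zero) covariance collapses the interval onto the estimate;
non-positive-semi-definite covariance is rejected as a contract error.
Bootstrap and distribution-of-the-product intervals are deliberately not
implemented; the effect-function interface is generic enough to add them.

Across a multiverse the intervals are reported per universe with no
multiplicity adjustment: the intended reading is the pattern of estimates,
not any single test.

## The decision grid

`lasa_decision_points()` encodes the worked example's five decision points
(first option = the original specification):

1. **Determinant coding** — continuous percent weight change, or the
   Edwards–Nunnally categories *increased* / *decreased* vs *stable*.
2. **Confounder set** — the full panel including hormonal markers, or the
   reduced panel without them (the markers are plausibly downstream of the
   mediator, which makes adjusting for them hazardous).
3. **Confounder strategy** — a-priori adjustment, or selection of covariates
   whose single addition changes any of the $a$, $b$, $c'$ paths by at least
   10%.
4. **Age moderation** — all ages pooled, or simple slopes for the under-75 /
   75-plus strata.
5. **Interaction handling** — no interaction (traditional $ab$ and $c'$), or
   pure, or total natural effects.

That is $3 \times 2 \times 2 \times 3 \times 3 = 108$ universes. Both
mediation-verdict criteria are evaluated in *every* universe rather than
multiplying the grid. The mediator does not enter equation 1, so universes
differing only in interaction handling share one total-effect model: total
effects deduplicate to $3 \times 2 \times 2 \times 3 = 36$ specifications.

**Redundancy.** After resolution (i.e. after change-in-estimate selection has
produced concrete covariate sets), universes with identical resolved tuples
(coding, covariates, moderation, interaction) are collapsed: estimates are
computed once for a canonical member and reported for all members with a
`redundant_of` flag. With the default generator the selected sets differ
from the a-priori sets, so the standard grid has no redundancy — mirroring
the situation the grid was designed around.

### Edwards–Nunnally categorisation

Individual change is declared significant relative to measurement
unreliability: the pretest is shrunk towards the sample mean,
$\tilde{w} = r(w - \bar{w}) + \bar{w}$, and surrounded by a band of two
standard errors of measurement, $\pm 2\,s_w\sqrt{1-r}$, with reliability
$r = 0.822$ by default. A posttest above the band is *increased*, below it
*decreased*, inside it *stable*. Two variants circulate (± 2 SEm around the
adjusted pretest vs a z-score cut); the package implements the adjusted-
pretest band, and classifies the exact boundary as stable — change must
*exceed* the band, the conservative reading. As $r \to 1$ the band collapses
onto the pretest and any change becomes significant; this limit, the
boundary rule, and the exhaustiveness of the three-way partition are all
under test.

### Change-in-estimate selection

Candidates are evaluated one at a time against the unadjusted mediator and
outcome models, on the same complete-case rows for the adjusted and
unadjusted fits, with the relative change
$100(\hat\beta_{adj} - \hat\beta_{unadj})/\hat\beta_{unadj}$ computed for
$a$, $b$ and $c'$; a candidate reaching the threshold (default 10%,
inclusive) on any path is selected. The total-effect path does not
participate. One-at-a-time (rather than stepwise or joint) is the simplest
reading of the criterion; alternative selection strategies would themselves
belong in a user's multiverse. Paths whose unadjusted coefficient is
numerically zero are skipped with a warning, since the relative change is
then undefined.

Selection is executed once per (determinant coding, candidate set) and
cached. It does not depend on the moderation option because stratified
universes use simple slopes from the pooled interacted model — the data
situation feeding the selection is identical across strata — and it does not
depend on interaction handling because the interaction term is not part of
the selection models.

### Moderation by simple slopes

Stratum universes do not refit on subsets. The engine fits pooled models
augmented with $X\!\cdot\!Z$ terms (all three equations) and an
$M\!\cdot\!Z$ term (outcome model), then evaluates level-specific
coefficients as linear combinations, e.g. $a(z) = a + a_{xz}z$, with exact
standard errors from the pooled coefficient covariance. The total-effect
equation is moderated as well — a design choice the package makes so each
stratum carries a coherent level-specific total effect; results from
moderated universes are flagged.

One consequence is documented rather than hidden: in moderated universes the
outcome model contains an $M\!\cdot\!Z$ column whose projection onto the
design is not captured by the mediator model, so the exact
$ab = c - c'$ identity holds only in unmoderated, matched-covariate,
no-interaction universes; elsewhere the two indirect-effect versions agree
only asymptotically. Simple slopes also equal per-stratum refits exactly only
when *all* covariates are interacted with the moderator; with non-interacted
covariates the equivalence is approximate, and the tests assert it within
sampling error in the fully-interacted configuration only.

### Verdicts

- **Causal steps + proportion mediated** (the historical criterion): $c$,
  $a$ and $b$ each significant at $\alpha$ (default 0.05, strict
  inequality) *and* $|c'| < |c|$, *and* proportion mediated at least 20%.
- **CI criterion**: the Monte Carlo interval of the universe's indirect
  estimand excludes zero.

The proportion mediated is $100\,ab/c$; in interaction universes the
universe's indirect estimand is divided by the decomposition total
$\mathrm{PNDE} + \mathrm{TNIE}$, which reduces to $ab/c$ when $h = 0$. The
difference-in-coefficients version $100(c - c')/c$ is identical in the
matched linear case and does not generalize cleanly under interaction, which
is why the product form was chosen. When $|c| < 10^{-10}$ the proportion is
undefined and the criterion fails rather than silently propagating a NaN.
Proportions above 100% occur under inconsistent mediation (opposite-signed
direct and indirect effects) and are reported as-is with a flag.

The two criteria diverge by construction: the CI criterion ignores the
significance of the total effect, so inconsistent mediation (and indirect
effects whose proportion falls below 20%) produce CI-mediated universes that
the causal-steps criterion rejects. The acceptance suite reproduces this
mechanism on a fixture with positive $ab$, negative $c'$ and a null total
effect.

## The synthetic cohort generator

The generator emulates the *structure* of an aging-cohort mediation problem
— continuous percent weight change since early adulthood (with raw pre/post
weights kept consistent so the categorical coding can be derived), fat mass
in kg as mediator, hip bone mineral density in mg/cm² as outcome, a panel of
twelve anthropometric/lifestyle/disease/medication confounders, five
hormonal markers, age with a 75-year moderation threshold, and small
completely-at-random missingness. It makes no attempt to match real marginal
distributions, covariance structure beyond the declared linear effects,
non-linearities, or informative missingness — so passing tests demonstrate
the *methods* behave correctly under a known linear data-generating process,
not that any substantive conclusion transfers to real cohort data.

Defaults (`mediation_sim_config()`, the `lasa_like` preset), chosen once as
the package's study conditions:

- $n = 264$ subjects, the size of the worked example's female subsample.
- True paths $a = 0.25$ kg per percent, $b = 11.7$ mg/cm² per kg (so
  $ab \approx 2.9$ mg/cm² per percent, the scale of the worked example's
  headline estimate), $c' = -1.5$ mg/cm² per percent (slightly negative
  direct effect, as in the example), interaction $h = 0.05$.
- Percent weight change is a two-component mixture (10% weight-loss
  component at $-12\% \pm 8$, gain component at $+18\% \pm 10$) so the
  Edwards–Nunnally coding yields decreased/stable/increased groups of
  workable sizes with the decreased group clearly smallest.
- Residual standard deviations ($\sigma_M = 8$ kg, $\sigma_Y = 500$
  mg/cm²) size the original-specification indirect effect near the
  detection boundary — roughly 80% power — so a default run shows a mix of
  significant and non-significant universes. The outcome noise is
  deliberately generous relative to real bone-density dispersion; it is a
  power calibration, not a distributional claim.
- The moderator attenuates $a$ by 0.10 in the 75-plus stratum.
- The hormonal markers are generated *downstream* of the mediator
  ($H = \alpha + \lambda M + e$) with their residuals feeding the outcome.
  Consequently omitting them leaves $b$ unbiased while adjusting for them
  shifts $b$ by $-\sum\gamma\lambda$ — the generator's encoding of the
  posttreatment ambiguity that motivates carrying both confounder panels in
  the grid, and an asserted property of the test suite.
- Missingness is 1% per affected column by default (bounded at 7%), MCAR
  only, matching the complete-case analysis policy.

`true_natural_effects()` returns the ground-truth effects implied by a
configuration via the same closed forms, evaluated at the generator's
covariate means and reference stratum.

## Numerical choices

- OLS is solved through base R's pivoted QR; results match an explicit
  normal-equations solve to $10^{-8}$ on well-conditioned data (asserted
  against that oracle). Rank deficiency raises an error naming the aliased
  columns; a universe hitting it is recorded as a warning row, not a crash.
- Identity and decomposition tolerances are $10^{-8}$; the proportion-
  mediated zero guard is $10^{-10}$.
- Specification curves sort ascending with ties broken by universe id, so
  the curve is a deterministic, permutation-invariant function of the result
  set; rendering to SVG is byte-deterministic for identical input.
- Result CSVs serialise floating point at six significant digits, making
  reruns byte-identical and round-trips exact at the documented precision.
- Tests and examples run the engine at reduced Monte Carlo draw counts
  (1 500–5 000) and the calibration studies at $n = 500$ over 500
  replicates / $n = 20\,000$ for recovery checks; these sizes are the
  package's chosen trade-off between Monte Carlo error and runtime, and the
  assertions use tolerances appropriate to them.

## Known limitations

- Linear models only; no link functions, no longitudinal structures.
- No sensitivity analysis for unmeasured confounding; the no-unmeasured-
  confounding assumptions behind natural effects are the user's burden.
- No multiple-imputation or FIML missing-data handling (by design).
- Multiverse summaries are descriptive percentages; the inferential status
  of summary statistics over non-independent universes is an open
  methodological question, and the package deliberately does not attach
  standard errors to them.
- Decision points beyond the five built-in resolvers are rejected rather
  than silently ignored; extending the resolver vocabulary is the natural
  next step.
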