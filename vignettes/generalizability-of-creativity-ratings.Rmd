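---
title: "Generalizability analysis of divergent-thinking creativity ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizability analysis of divergent-thinking creativity ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtrater)
```

## The measurement problem

Divergent-thinking tasks ask people to produce many responses to an
open-ended prompt — alternative uses for a brick or a knife, consequences of
people no longer needing sleep or being twelve inches tall — and human
raters judge the creativity of those responses on a 1–5 scale. A person's
creativity score therefore depends not only on the person but on which
raters judged them and which items (prompts) they answered. Classical
reliability coefficients collapse all of that into a single undifferentiated
error term. Generalizability theory instead decomposes the observed-score
variance of the fully crossed person × item × rater design into seven
components:

\[
X_{pir} = \mu + \nu_p + \nu_i + \nu_r + \nu_{pi} + \nu_{pr} + \nu_{ir}
          + \varepsilon_{pir},
\]

with persons the object of measurement, items and raters random facets, and
the residual confounded with the three-way interaction. Task family
(alternative uses vs. consequences) is treated as a *fixed* partition, not a
modeled facet: the rating scales are family-specific and scores are never
pooled across families, so every analysis in this package runs within one
family's subtable (`split_by_family()`).

## Scoring systems

Three scoring systems feed the analysis:

* **Average rating** (`average_rating_scores()`): every individual response
  is rated by every rater; the cell score \(X_{pir}\) is the unweighted mean
  of rater \(r\)'s ratings over person \(p\)'s responses to item \(i\). With
  complete response-by-rater data, averaging over responses then raters or
  raters then responses yields the same per-item person mean; the package
  computes per-rater cell means first because those cells are the G-study's
  unit of analysis. For incomplete data the two orders differ and the
  functions refuse the input rather than guess.
* **Snapshot** (`snapshot_scores()`): one holistic rating per person × item
  × rater; validation only, no aggregation.
* **Fluency** (`fluency_scores()`): the count of responses per person ×
  item; raters do not enter.

No response de-duplication, category collapsing, or cleaning of nonsense
responses is performed; inputs are assumed pre-cleaned.

## G-study: expected mean squares

`mean_squares()` computes the classical balanced three-way ANOVA
decomposition from marginal and cell means, and
`estimate_variance_components()` solves the expected-mean-squares (EMS)
equations in closed form, e.g.
\(\hat\sigma^2(pi) = (MS_{pi} - MS_{pir})/n_r\) and
\(\hat\sigma^2(p) = (MS_p - MS_{pi} - MS_{pr} + MS_{pir})/(n_i n_r)\).

The EMS estimator was chosen over REML deliberately: on balanced-complete
data it is exact, closed-form, and testable against two independent
oracles (base R's ANOVA sums of squares, and a numeric solve of the 7 × 7
EMS system), whereas REML is iterative and approximate. On balanced data
with all estimates interior the two coincide; they can differ slightly when
an estimate goes negative, because REML constrains components to be
non-negative while EMS solves the unconstrained equations. Negative EMS
solutions are retained in `$raw` for diagnostics and truncated to zero in
the reported `$components`, the convention used in published G-study
tables. Unbalanced tables are refused outright — the user is pointed to
mixed-model (REML) tooling, which is out of scope here.

Percentages (`percent_variance()`) divide each truncated component by the
sum of truncated components. Report formatting follows the field's
convention: components to 3 decimals, percentages to 1, coefficients to 2,
with half-up rounding (`round_half_up()`), since published tables round
ties upward rather than to even.

## D-study: projecting to candidate designs

For a candidate design with \(n_i'\) items and \(n_r'\) raters, each
component is divided by the number of conditions it is averaged over:
person-by-item by \(n_i'\), person-by-rater by \(n_r'\), anything involving
both facets by \(n_i' n_r'\), the person variance by 1. Relative error
variance collects the person-interaction terms,

\[
\sigma^2_\delta = \frac{\sigma^2_{pi}}{n_i'} + \frac{\sigma^2_{pr}}{n_r'}
  + \frac{\sigma^2_{pir,e}}{n_i' n_r'},
\]

absolute error adds the facet main effects and their interaction, and the
two reliability-like coefficients are

\[
E\rho^2 = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2_\delta}, \qquad
\Phi = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2_\Delta},
\]

with \(\Phi \le E\rho^2\) always and 0.80 the conventional bar for
excellent generalizability. `coefficient_curve()` evaluates either
coefficient as one facet grows from 1 to `max_n`, and `minimal_design()`
returns the smallest integer facet size reaching a threshold (no
fractional-design interpolation).

### Printed-table arithmetic

`dstudy_table(..., printed = TRUE)` rounds the projected components to
three decimals *before* summing them into error variances, mirroring how
published D-study tables are laid out (the printed error variance equals
the sum of the printed component rows). Full precision is the default for
analysis. The two modes can disagree in the third decimal of the error
variances — a projected component like \(0.139/2 = 0.0695\) sits exactly on
a rounding boundary, and tables derived from unrounded estimates may print
either neighbor — but the coefficients agree at the two decimals at which
they are reported. For the same reason, `minimal_design()` answers derived
from rounded three-decimal inputs can differ by one from answers derived
from unrounded estimates near the 0.80 boundary: from the packaged
reference components for average-rated alternative uses, 5 items (with 3
raters) reach 0.80, while curves drawn from unrounded estimates place the
crossing at 4. The package reports what is reproducible from its inputs.

The worked reference values shipped in `reference_components()` keep one
further quirk of their source: the person variance used at the D-study
stage for average-rated consequences is 0.068 where the G-study table
prints 0.067 (`stage = "dstudy"` selects the former so the published
coefficients 0.52 and 0.27 reproduce exactly).

## Convergent validity

`composite_scores()` builds per-person variables (per item, or averaged
over a family's items) for each scoring system plus fluency, and
`validity_report()` computes sample means, standard deviations (n − 1
denominator; the conventional sample descriptive), and the pairwise Pearson
correlation matrix on complete cases. Zero-variance variables yield `NA`
correlations with a warning. At least three persons are required — with
two, every correlation is ±1 and the report would be vacuous.

## What the synthetic generator does and does not emulate

`simulate_scores()` draws each effect in the additive model above from an
independent zero-mean normal with its specified variance — exactly the
model the EMS estimator targets — so parameter recovery can be tested
against known truth. Its defaults reproduce the design the package is
built around: 80 persons, 2 items within a family, 3 raters, grand mean 3
(the 1–5 midpoint), and the packaged average-rating alternative-uses
components as generating truth. `simulate_response_level()` adds the
response layer: a zero-truncated Poisson number of responses per person ×
item (mean 6.5, matching observed fluency means of roughly 6.4–6.8; zero
truncation because fluency is at least 1 for anyone who responded), and
per response × rater an integer rating formed as the cell expectation plus
normal noise with SD 0.5 — a value chosen once so that raters disagree by
about half a scale point across responses within a cell, typical of
adjacent-category disagreement on 5-point scales — rounded and clipped to
1–5.

Continuous scores are the default because the estimation theory is
moment-based; clipping and rounding to the integer scale
(`discretize = TRUE`) shrinks tail variance and biases every component
estimate toward zero, which is why discretization is an option rather than
the default. The generator does not model rater drift over time, response
content or wording, semantic similarity between responses, or any
recruitment process. Passing tests on synthetic data therefore demonstrate
that the estimators recover the model they assume — not that real ratings
satisfy that model (real rating distributions are bounded, discrete, and
often skewed).

Determinism: one seed governs each generator call; `parameter_recovery()`
derives per-replicate seeds from the spec's seed via `sample.int()`, so a
replicate study is reproducible end to end.

## Problem sizes used in the test suite

Monte-Carlo checks in the shipped tests use 200 replicates of a
200-person × 8-item × 8-rater design for parameter recovery (the size at
which the person-component bias bound of 0.02 is a meaningful test of
unbiasedness without Monte-Carlo noise dominating), 1,000 randomized
component/design draws for the coefficient invariants, and 3 × 3 × 3 grids
for oracle equivalence — sizes chosen so the full suite completes in well
under a minute of simulation per property while keeping standard errors
small relative to the tolerances tested.

## Known limitations

* Balanced, fully crossed, complete designs only; one observation per cell.
  No nested, sparse, or multivariate designs.
* No confidence intervals on variance components or coefficients.
* The family facet is fixed by construction; nothing generalizes across
  task families.
* EMS truncation at zero introduces upward bias for components whose true
  value is near zero; use `$raw` when studying estimator behavior.
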