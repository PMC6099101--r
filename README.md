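# gtrater

Generalizability-theory analysis of subjectively rated performance data,
built around the fully crossed **person × item × rater** design used when
human raters score divergent-thinking (creativity) tasks on a 1–5 scale.

When several raters judge several prompts, a person's score varies with the
raters and items as much as with the person. `gtrater` quantifies each
source by decomposing observed scores under the additive crossed
random-effects model

```
X_pir = mu + nu_p + nu_i + nu_r + nu_pi + nu_pr + nu_ir + e_pir
```

into seven variance components (the **G-study**, estimated by the exact
expected-mean-squares method on balanced data), then projects those
components onto hypothetical designs with `n_i` items and `n_r` raters (the
**D-study**) to obtain

- relative error variance `sigma2_delta = sigma2_pi/n_i + sigma2_pr/n_r + sigma2_pir_e/(n_i*n_r)`,
- absolute error variance `sigma2_Delta` (the same plus the facet main effects),
- the generalizability coefficient `E_rho2 = sigma2_p / (sigma2_p + sigma2_delta)`, and
- the dependability coefficient `Phi = sigma2_p / (sigma2_p + sigma2_Delta)`,

with `Phi <= E_rho2` always and 0.80 the conventional bar for excellent
reliability. On top of that it provides scoring-system aggregation
(average-rating, snapshot, fluency), coefficient curves and minimal-design
recommendations, convergent-validity descriptives, and a synthetic-data
generator that draws from the very model the estimator assumes, so the whole
pipeline is testable without any external data.

Intended users: researchers scoring open-ended behavioral tasks with
multiple raters who need to decide *how many raters and items* their study
requires.

## Worked example

Simulate a response-level rating study (80 persons × 2 items × 3 raters,
each response rated by every rater), aggregate it, and run the G- and
D-studies:

```r
library(gtrater)

sp     <- simulation_spec(n_p = 80, n_i = 2, n_r = 3, seed = 42)
resp   <- simulate_response_level(sp)   # 3,099 rating rows
scores <- average_rating_scores(resp)   # one score per person-item-rater cell
vc     <- gstudy(scores, label = list(system = "average",
                                      family = "alternative_uses"))
print(vc)
#> G-study variance components [average, alternative_uses]
#>        source estimate percent
#>             p    0.232    38.4
#>             i    0.033     5.5
#>             r    0.049     8.1
#>         p x i    0.110    18.1
#>         p x r    0.002     0.3
#>         r x i    0.007     1.2
#>  p x i x r, e    0.172    28.4
```

38% of score variance is real person variance; raters and the
person-by-item interaction are the big error sources. Project to the
2-item, 3-rater design actually run:

```r
dstudy_table(vc, n_i = 2, n_r = 3)
#> D-study for 2 item(s) x 3 rater(s)
#>      quantity  n estimate
#>      sigma2_p  1    0.232
#>      ...
#>  sigma2_delta NA    0.084
#>  sigma2_Delta NA    0.118
#>        e_rho2 NA    0.730
#>           phi NA    0.660

minimal_design(vc, 0.80, varying = "items", fixed_n = 3, cap = 10)
#> [1] 3
```

So this simulated instrument reaches `E_rho2 = 0.73` as designed, and three
items (with 3 raters) would push it past 0.80.

The package also ships the reference component estimates from a published
G-study of this design (`reference_components()`); feeding them through the
same projection reproduces its reported coefficients:

```r
vc_ref <- reference_components("average", "alternative_uses", stage = "dstudy")
d <- dstudy_table(vc_ref, n_i = 2, n_r = 3, printed = TRUE)
round_half_up(c(e_rho2 = d$e_rho2, phi = d$phi), 2)
#> e_rho2    phi
#>   0.65   0.47
```

`run_pipeline(run_config(...))` wires the stages together and writes
G-study, D-study, curve, recommendation, and validity CSVs;
`inst/scripts/gtrater.R` exposes the same stages as shell subcommands.

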