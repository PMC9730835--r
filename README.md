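# soilscore

Hierarchical, config-driven soil-health assessment for agricultural
fields. `soilscore` is aimed at agronomists, soil-data services and
researchers who want to turn routine laboratory measurements into an
interpretable field score and concrete management advice.

## What it computes

Measured topsoil and field properties are mapped onto unitless **soil
function indicators** $I \in [0, 1]$ (0 = poor, 1 = optimum) by
configurable evaluation curves keyed by soil type × land use. For
nutrient functions the curves are anchored agronomically: $I = 0.5$ at
the level below which additional fertilization is recommended and
$I = 1$ at the optimum above which yield no longer responds.

Indicators are grouped into five categories (chemical, physical,
biological, environmental, management) and aggregated in three weighted
steps, each with its own correction factor:

1. **Within category, per year** — distance-to-target weights
   $w_i = 1/(I_i + c)$, $c = 0.2$: by the law of the minimum, the most
   limiting function dominates.
2. **Across years** — recent crops (age < 5 years) weigh 1.0, older
   years 0.5.
3. **Across categories** — weights $\log_2(n_k + 1)$ on the number of
   contributing functions per category.

Final and category scores are read as good (> 0.75), sufficient
(0.5–0.75) or poor (< 0.5). A nine-item visual soil assessment
(poor/moderate/good ratings) can replace the model-derived compaction
and aggregate-stability indicators. Per category, the engine recommends
the practice maximizing $\sum_f e(p,f)\,(1 - I_f)$ over an effectiveness
matrix. Redundancy (Spearman correlations, PCA), single-property error
propagation and aggregation-method comparison diagnostics audit the
index itself. A reproducible generator creates multi-year synthetic
field records, including good/poor field pairs.

The shipped battery and effectiveness matrix are illustrative defaults —
see `vignettes/soil-health-scoring.Rmd` for the methods and their
assumptions.

## Worked example

```r
library(soilscore)
fields <- generate_fields(simulation_config(n_fields = 50, seed = 7))
scores <- score_fields(fields)
head(scores, 3)
#>   field_id chemical physical biological final_score class
#> 1 F00001      0.744    0.658      0.637       0.733 sufficient
#> 2 F00002      0.519    0.481      0.457       0.583 sufficient
#> 3 F00003      0.585    0.683      0.959       0.737 sufficient

score_field(fields[fields$field_id == "F00002", ])
#> <score_report> field F00002
#>   biological    0.457  (n = 2, weight = 1.585)
#>   chemical      0.519  (n = 9, weight = 3.322)
#>   environmental 1.000  (n = 2, weight = 1.585)
#>   management    0.656  (n = 1, weight = 1.000)
#>   physical      0.481  (n = 8, weight = 3.170)
#>   final score   0.583  [sufficient]
```

Field F00002 is "sufficient": its environmental functions are at target,
but nutrient supply, physical structure and biological activity sit near
0.5, and the limiting-factor weighting pulls the final score (0.583)
below the plain mean of the sub-scores. The advisory module points at
the deficiencies per category:

```r
rec <- recommend_field(fields[fields$field_id == "F00002", ])
rec[rec$best, c("category", "practice_id", "label", "benefit")]
#>   category      practice_id label                                        benefit
#> 1 chemical      M8          fertilization conform maintenance and build…   2.46
#> 2 physical      M3          non-till practices                             0.541
#> 3 biological    M2          compost application                            0.426
#> 4 environmental M1          liming                                         0
```

(the zero-benefit environmental row is flagged `no_deficiency`: nothing
to fix there). The same workflows are available from the shell via the
bundled CLI (`inst/cli/soilscore`): `simulate`, `score`, `recommend` and
`diagnose` subcommands.

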