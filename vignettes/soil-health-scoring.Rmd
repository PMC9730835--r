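---
title: "Methods: hierarchical soil-health scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical soil-health scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilscore)
```

# The model

`soilscore` assesses the health of an agricultural field against the
objective of sustainable crop production. The assessment is hierarchical:

1. **Soil properties** — routine laboratory measurements (organic matter,
   pH, texture, nutrient pools, CEC, potentially mineralizable N, bulk
   density) plus field context (soil type, groundwater class, land use per
   year over up to ten years).
2. **Soil functions → indicators** — each configured soil function maps
   one property onto a unitless grade in $[0, 1]$ expressing the distance
   to its agronomic target (0 = poor, 1 = optimum). Functions are grouped
   into five categories: chemical, physical, biological, environmental and
   management.
3. **Aggregation** — three weighted steps produce category sub-scores and
   a final score.
4. **Advice** — per category, the farming practice that most effectively
   improves the poorly scoring functions.

Scores are interpreted as good ($> 0.75$), sufficient ($[0.5, 0.75]$) or
poor ($< 0.5$); both boundaries are read as "sufficient", matching the
half-open interval notation of the class definitions.

## Evaluation curves

The knowledge base behind nutrient interpretation is anchored at two
points: the level at which additional fertilization is recommended
(indicator $0.5$) and the optimum above which yield no longer responds
(indicator $1$). The functional form between anchors is not prescribed by
that anchoring, so the package uses the simplest shape that is exact at
both anchors and trivially invertible: a piecewise-linear curve through
$(x_0, 0)$, $(x_{1/2}, 0.5)$ and $(x_{opt}, 1)$, clipped outside. A
decreasing variant (anchors in reverse order) serves "more is worse"
properties; a trapezoid window serves optimum-range properties such as
pH; and a categorical lookup serves class-valued field properties such as
the groundwater class. Per-function curves are configuration, keyed by
soil type × land use with `"*"` wildcards (most specific entry wins).

The battery shipped in `inst/extdata/battery-default.yaml` (22 functions:
9 chemical, 8 physical, 2 biological, 2 environmental, 1 management) uses
illustrative parameters in the plausible range for Dutch-style topsoils.
It is deliberately **not** an authoritative calibration — national
implementations keep such thresholds in fertilizer-recommendation
knowledge bases — and every number can be overridden via `read_battery()`.
A load-time coverage rule requires at least two functions each for the
chemical, physical and biological aspects.

**Missing data.** A missing property yields a *missing* indicator, never
zero; downstream aggregation excludes missing values and renormalizes its
weights. This is equivalent to scoring only what was measured and is the
reason no imputation step exists.

## The three aggregation steps and their correction factors

Step 1 (within category, per year) uses distance-to-target weights

$$w_i = \frac{1}{I_i + c}, \qquad c = 0.2,$$

so that, following von Liebig's law of the minimum, the lowest indicator
— presumably the factor limiting crop production — dominates. The
weighted mean is idempotent (constant input $v$ gives $v$), strictly
below the arithmetic mean unless all inputs are equal, and monotone:
raising any single indicator never lowers the aggregate (the derivative
has numerator $c\sum w + \sum w I > 0$).

Step 2 (across years, per category) weights recent crops (age $< 5$
years) with $1.0$ and older years with $0.5$, renormalizing over the
years that actually carry a score.

Step 3 (across categories) weights each category by $\log_2(n_k + 1)$,
where $n_k$ is the number of distinct soil functions that contributed:
categories underpinned by more measurements are better supported and
count more, with diminishing returns; an empty category drops out
exactly.

The three formulas are this package's own concrete choices for the three
correction factors — smooth, strictly monotone, idempotent under equal
inputs — and all are overridable through `aggregation_config()`. The step
order (within-category per year → across years → across categories) is
fixed; when land use changes mid-rotation it is the yearly *category
scores* that are averaged, not raw indicators, which keeps each year's
evaluation internally consistent with that year's land use.

## Visual soil assessment

A nine-item visual assessment (earthworms, compaction, gray spots,
ponding, cracks, bio-pores, rooting depth, structure, crop cover), each
rated poor/moderate/good, can accompany a record. Ratings map onto
$\{0, 0.5, 1\}$ — the midpoint convention aligns "moderate" with the
fertilization-recommended anchor. When a complete VSA is present, the
structure rating replaces the model-derived aggregate-stability indicator
and the compaction rating replaces the compaction indicator (field
observation beats coarse model proxies for exactly these two functions);
everything else is untouched and the substitution is idempotent.

## Recommendations

Each practice $p$ carries an effectiveness $e(p, f) \in [0, 1]$ per soil
function, with applicability filters on land use and soil type. The
benefit of a practice for a category is

$$B(p) = \sum_{f \in \text{category}} e(p, f)\,(1 - I_f),$$

linear in the deficiency to mirror the distance-to-target logic; the
paper trail behind the shipped effectiveness matrix is deliberately
qualitative, so the matrix is labelled illustrative and fully
configurable. Ties break lexicographically by practice id, making
recommendations deterministic; when no function is deficient all benefits
are zero and the result is flagged `no_deficiency`.

# The synthetic-data generator

No deposited field records exist, so `generate_fields()` emulates the
structure the framework assumes: per-field soil type drawn from a mix
(defaults: sand 0.50, clay 0.33, loess 0.05, peat 0.12), a groundwater
class plausible for that soil type, truncated-normal property draws per
soil type (`default_property_params()`), a persistent land-use Markov
chain (stay probability 0.8, stationary mix grassland 0.50 / maize
0.15 / arable 0.35), ten years of records with multiplicative lab-style
noise (CV 3%, additive sd 0.1 for pH), and a property-linked VSA on the
most recent year for half the fields. All defaults were fixed once, on
agronomic plausibility for Dutch-style fields.

`generate_pairs()` emulates farmer-selected good/poor field pairs: both
members share one base property draw, rotation and context; each member
receives independent yearly noise; and the poor member's
biologically/physically linked properties are shifted toward deficiency
(organic matter and PMN scaled by $1 - \textit{offset}$, bulk density by
$1 + 0.4\,\textit{offset}$). At offset 0 the members are exchangeable; at
offsets $\geq 0.15$ the shift dominates the 3% noise, so score-based
recovery of the good member saturates quickly — recovery rates are
therefore tested as non-decreasing in the offset. VSA ratings derive from
the shifted properties (with a 15% one-level rating-noise probability),
so pair scoring exercises the substitution path end to end.

What the generator does *not* emulate: spatial autocorrelation and
regression-kriging artifacts of national property maps, genuine
correlation structure among nutrients, measurement-method differences
between laboratories, and management practices that respond to soil
state. Passing tests on synthetic data therefore demonstrate the
correctness and internal consistency of the scoring machinery, not the
agronomic validity of the illustrative thresholds on real fields.

# Diagnostics

- `correlation_matrix()`: Spearman rank correlations between indicators,
  pairwise deletion, `NA` (with a warning) for constant columns or pairs
  with fewer than three complete observations.
- `pca_variance()`: eigen-decomposition of the Pearson correlation matrix
  of complete-case rows (management excluded); fractions are clipped at
  zero, so rank-deficient input yields a zero tail. No row weighting is
  applied.
- `perturb_and_score()`: recomputes the full pipeline with one property
  scaled by $1 + \delta$ (relative, the default) or shifted by $\delta$,
  reporting per-field changes of every sub-score and the final score.
- `compare_aggregations()`: final scores under the default nonlinear
  weighting, a linear variant, and the minimum indicator. "Linear" keeps
  the category structure and the $\log_2(n_k+1)$ category weights and
  only switches the step-1 limiting-factor weights off; this is the
  variant for which the row-wise ordering
  $\min \le \text{nonlinear} \le \text{linear}$ holds by construction
  (with a flat overall mean instead, a large category scoring low can
  break the inequality).

# Numerical choices and limitations

- All aggregation is in double precision; scores are clamped to $[0,1]$
  only to absorb $10^{-16}$-scale drift, and `classify_score()` tolerates
  $10^{-9}$ outside the unit interval for the same reason.
- Problem sizes in the test suite (up to 10,000-row indicator tables, 500
  synthetic fields in the reproduction script, 50 seeds × 4 offsets for
  pair recovery) were chosen so the whole suite runs comfortably on a
  laptop while keeping Monte Carlo noise well below the tested margins.
- The management category is a single config-supplied 0--1 score passed
  through an identity curve; the expert system that would produce it is
  out of scope, and survey-style runs may exclude the category via
  `aggregation_config(include_management = FALSE)`.
- Environmental indicators here are simple N-pool proxies; the validated
  simulation models a national implementation would use are out of scope.
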