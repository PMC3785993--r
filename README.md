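# frailmap

Similarity-based frailty assessment for elderly cohorts, at desk scale.

Frailty — the age-related loss of physiological reserve that raises the
risk of falls, dependence and death — has no agreed absolute index.
`frailmap` implements a *relative* assessment instead: a studied patient
is compared against a stored stack of previously assessed patient
instances over a canonical set of 61 mixed-type frailty variables, and
the most similar instances are presented as a compact, similarity-ranked
treemap that a geriatrician can read at a glance. The package also covers
the two flanking tasks of such a system: deriving gait "dispersion
measure" variables from a tri-axial accelerometer recording, and running
a longitudinal nutritional-evolution analysis over repeated assessments.

## The model

Patients are compared with the weighted **Gower general similarity
coefficient**, the standard proximity measure for records that mix
quantitative, qualitative and binary data:

```
        Σ_k  w_k δ_ijk s_ijk
S_ij = ----------------------
        Σ_k  w_k δ_ijk
```

where for variable *k* with weight *w_k* ∈ [0, 1]:

* quantitative: `s_ijk = 1 − |x_ik − x_jk| / R_k`, with range `R_k` taken
  over the stack's non-missing values (a zero range scores 1);
* qualitative and binary: `s_ijk = 1` iff the values match, else 0;
* `δ_ijk = 1` when both values are present (comparable), 0 otherwise, so
  missing values drop out of numerator and denominator alike. In the
  optional asymmetric binary mode, co-absence of a syndrome also sets
  `δ = 0`, as in Gower's original dichotomous rule.

The 61 variables are partitioned into six clinical groups —
anthropometric (9), functional (6), nutritional (13), cognitive (2),
geriatric syndromes (11) and gait dispersion measures (20) — and carry
per-variable weights so an assessment can focus on any clinical domain.
Repeat assessments may carry values forward ("kept" markers), which are
resolved by forward-filling the patient's most recent earlier value.

The assessment result is a **treemap**: the studied instance is the root,
its top 3 neighbors by similarity form level 2, and each of those
contributes its own top neighbors (computed against *that* node, among
instances not yet placed) as level 3 — at most three levels and three
children per node, so exactly four ranked neighbor lists are computed.
Nodes carry `{parent instance id, instance id, age, similarity
coefficient}` and render to JSON and SVG.

## Worked example

```r
library(frailmap)

# a synthetic 20-patient cohort (10 M / 10 F, ages moment-matched to the
# study demographics), 3 assessments each
stk  <- generate_cohort(cohort_spec(seed = 42))
stk1 <- stk[stk$iteration == 1, ]          # first-assessment instances

rank_neighbors(stk1, target = 1) |> head(3)
#>       i     j coefficient effective_weight
#> 1     1    10       0.731               61
#> 2     1    14       0.664               61
#> 3     1     3       0.658               61

tm <- build_treemap(stk1, root = 1)
tm
#> <frailty_treemap> root instance 1, 13 nodes, depth 3
#> 1 (sim 1.000, age 86.47312)
#>   10 (sim 0.731, age 78.33904)
#>     6 (sim 0.729, age 78.09275)
#>     ...
glance(tm)
#>   root_instance_id n_nodes depth max_children n_ranked_lists
#> 1                1      13     3            3              4
```

The ranking says instance 1 is most like instance 10 (coefficient 0.731
over all 61 comparable, fully weighted variables), and the treemap nests
the thirteen most similar instances under the root with at most three
children per node. `autoplot(tm)` draws the nested rectangles with areas
proportional to similarity; `treemap_to_json()` / `write_treemap_svg()`
export the formalized result.

The longitudinal analysis weights nine nutritional/anthropometric
variables at 1 and everything else at 0, then tracks per-sex group means
across the three assessment stages:

```r
rep <- evolution_report(stk)
tidy(rep) |> head(4)
#>   stage   sex  variable         mean  n    no_data
#> 1 initial F    weight           72.6  10   FALSE
#> 2 initial F    body_mass_index  31.8  10   FALSE
#> ...
glance(rep)
#>   n_stages n_variables n_suppressed n_declined n_maintained n_improved
#> 1        3           9            0         20            0         16
```

Means backed by fewer than `min_n` (default 3) contributing values are
suppressed as `no_data`; deltas between consecutive stages are labelled
declined / maintained / improved.

A thin command-line wrapper is installed as `exec/frailmap` with
subcommands `simulate`, `features`, `similarity`, `assess` and `evolve`.

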