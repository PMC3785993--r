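---
title: "Methods: mixed-type similarity, treemap assessment and nutritional evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-type similarity, treemap assessment and nutritional evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailmap)
```

`frailmap` provides a relative frailty assessment: instead of scoring a
patient on an absolute index, it measures how similar a studied patient
instance is to every instance in a stored patient stack, under a
clinician-controlled weighting of 61 frailty variables, and formalizes
the result as a bounded treemap. This vignette records the model, the
design decisions taken where the design was genuinely open, the numerical
choices, and what the synthetic data used in the tests can and cannot
show.

## The variable schema

A patient instance is the complete set of frailty variables for one
patient at one assessment time. The canonical schema has 61 variables in
six groups with a fixed 9/6/13/2/11/20 partition:

```{r}
dplyr::count(frailty_schema(), group, kind)
```

Group membership was reconstructed from the standard frailty-record
factor list, which names slightly more items than the group sizes admit.
Two mapping decisions were required and are fixed here:

* the anthropometric "drug number" item is not a separate variable; its
  content is covered by the geriatric *polypharmacy* flag, bringing the
  anthropometric group to its printed size of 9 (the record-level
  `gender` and `age_years` variables mirror the instance metadata);
* the independence-in-daily-living level is carried as a qualitative
  *functional* variable (`adl_independence`, five dependence levels),
  bringing that group to its printed size of 6. The free-text pathology
  groupings of the record have no room in the fixed partition and are
  out of scope.

Geriatric syndromes are binary flags; the nutritional group is the
13-analyte lab panel with canonical units (g/dl, mg/dl, thousand/mcl,
…); cognitive is the two mental-status scores. Each quantitative
variable also carries a plausible clinical range (`lo`, `hi`) used only
by the synthetic-data generators, never by the similarity computation.

### Missing and kept values

A value is `present`, `missing`, or `kept` (`k` in the CSV dialect): not
re-measured at a later assessment and carried forward. `resolve_kept()`
replaces each kept value by the same patient's most recent earlier
present value of that variable, or `missing` when no antecedent exists;
the operation is idempotent and a kept marker in a first-iteration row is
rejected at parse time. This forward-fill reading is the one under which
the packaged study-pattern fixture reproduces its source's existing-value
accounting: 1057 present values at iteration 1, and 644 at iteration 2
*when resolvable kept values are counted* (`count_existing_values(...,
count_kept = TRUE)`). The printed third-iteration total of that source
(913) is not reproducible from its printed per-group counts under any
counting rule we tried (present-only gives 653, with kept 851); the
discrepancy is documented here rather than resolved, and no test asserts
it.

## Gait dispersion measures

Twenty schema variables summarise a tri-axial accelerometer recording of
a gait exercise: per axis, the arithmetic mean, sample standard deviation
(n − 1), absolute mean difference, variance, amplitude (max − min) and
Pearson coefficient of variation (sd / |mean|); plus the mean and sample
sd of the acceleration magnitude `sqrt(x² + y² + z²)`. Three readings
were fixed:

* *absolute mean difference* is the mean absolute deviation about the
  axis mean — not the Gini mean difference and not successive
  differences; it is the simplest reading of the term and is pinned by
  exact unit tests (`[1, 2, 3]` gives 2/3);
* the 20-variable composition is 6 statistics × 3 axes plus the two
  magnitude statistics: the seven named indicators are per-axis except
  *acceleration mean*, which is taken as a magnitude statistic, and a
  magnitude sd completes the count;
* standard deviations and variances are sample (n − 1) statistics, the
  small-sample clinical convention, so test expectations are exact.

An axis with mean exactly 0 has an undefined coefficient of variation;
it is flagged with a warning and stored as missing, not an error.
Preprocessing is a centered moving average per axis (odd window, default
5 samples; the half-window edge samples are dropped) followed by trimming
a fixed duration (default 1 s) from each end — the named filtering and
segmentation steps with the simplest deterministic operators, both
configurable.

## The weighted Gower coefficient

Similarity between instances *i* and *j* is

$$S_{ij} = \frac{\sum_k w_k\,\delta_{ijk}\,s_{ijk}}
                {\sum_k w_k\,\delta_{ijk}},$$

the standard Gower form for mixed data: quantitative variables score
$1 - |x_{ik}-x_{jk}|/R_k$, qualitative and binary variables score
exact-match 0/1, and $\delta_{ijk}=0$ removes a variable from both sums
when either value is missing. Decisions:

* **Ranges.** $R_k$ is computed from the non-missing values of the
  current stack — the population under study — not from fixed clinical
  bounds. A zero range (all observed values equal) scores 1: two
  patients cannot differ on a variable that does not vary.
* **Binary mode.** The default is *symmetric*: two patients both
  without dementia agree on dementia, which is the clinically meaningful
  reading for syndrome flags. Gower's original dichotomous rule
  (co-absence is not comparable) is available as
  `similarity_config("asymmetric")`.
* **Weights.** Per-variable, in [0, 1]. Group-level weights in a
  profile file are expanded uniformly — each member variable receives
  the group's weight value — so a single mechanism serves both
  granularities. Setting a weight to 0 makes the coefficient provably
  invariant to that variable (the basis of the nutritional analysis
  below).
* **Degenerate pairs.** A pair with no comparable weighted variable has
  an undefined coefficient; `gower_similarity()` raises an explicit
  error and `similarity_matrix()` flags the cell as `NA` rather than
  silently reporting 0.
* Ties in neighbor rankings are broken by ascending instance id, making
  every ranking, treemap and rendering deterministic.

Units are normalized before comparison (`normalize_units()`): values
tagged with a non-canonical unit are converted multiplicatively (g to
kg, g/l to g/dl, m/s² to g, …); unknown units are an error, never a
guess.

## Treemap construction and layout

The studied instance is the root (similarity 1, level 1). Its top
`max_children` (default 3) neighbors form level 2; breadth-first, each
level-2 node's children are *its own* top neighbors — similarity is
computed against the child's parent, not the root — among instances not
yet placed anywhere in the tree (`exclusion_policy = "placed_nodes"`).
This strictest duplicate-free reading matches the observation that
reported trees never repeat a node; a `"path_only"` mode that excludes
only ancestors is kept as a switch, as is a `same_patient_rule` that can
bar other instances of the root's patient (default `allow`: a
first-iteration stack has one instance per patient, so the rule never
bites there). Depth is capped at `max_depth` = 3 levels counting the
root, so on a sufficiently large stack exactly 1 + 3 ranked lists are
computed — deeper levels would carry ever-lower coefficients and clutter
the reading.

Layout is slice-and-dice: children partition their parent's rectangle,
alternating split direction per level, with areas proportional to their
similarity coefficients within each sibling set. Squarified layouts were
deliberately not used — the cited treemap idea is generic, and
slice-and-dice is the simplest deterministic tiling. The SVG color ramp
is a linear RGB interpolation from `#DEEBF7` (similarity 0) to `#08519C`
(similarity 1); the endpoints are fixed so renderings are byte-identical
across runs, which the tests assert.

## Nutritional evolution analysis

The longitudinal analysis selects nine variables — weight, body mass
index, fat mass, lean mass, total water, total protein, hemoglobin,
serum albumin, lymphocytes — by weighting them 1 and everything else 0.
Stages map to iterations: *initial* (1), *spontaneous* (2, the
unassisted evolution), *post-supplementation* (3, after a period of
protein supplementation). For each stage × sex, `stage_means()` averages
the present values per variable; a mean backed by fewer than `min_n`
contributing values is suppressed as `no_data`. The suppression
threshold of the original analysis is unpublished; the default here is
`min_n = 3` (a mean of one or two elderly patients is not a group
statement), and it is configurable. `stage_delta()` reports signed
differences where both means exist and labels trends `declined` /
`maintained` / `improved` with a configurable half-band `epsilon`
(default 0). The *clinical* direction of improvement is
variable-specific (more albumin is good; more weight is ambiguous), so
the tool reports raw signs and leaves direction semantics to the
caller. Elapsed time between stages is metadata only; the analysis is
not time-weighted.

## Synthetic data: what it emulates, and what it does not

The package ships two generators, both deterministic under a seed and
both first-class, tested code.

`generate_cohort()` emulates the studied cohort's structure: 20 patients
(10 women, 10 men), three assessments each. Per-sex ages are
**moment-matched** — a seeded normal draw is affinely rescaled so the
sample mean and sd equal the specification exactly (women 85.43 ± 3.22,
men 81.80 ± 4.74 years) — making the printed demographic statistics
exact, deterministic targets rather than expectations. (The source's
overall mean of 83.58 is mildly inconsistent with its sex-specific means,
which average 83.615; the generator matches the sex-specific moments.)
Variable values are invented, as no per-variable distributions were
published: quantitative values uniform within each variable's schema
range, categories uniform, syndrome flags with prevalence 0.3. Later
iterations evolve quantitative values as *previous + shift + noise*
(noise sd = 5 % of the variable's range by default), so a generated
stage shift of −d is recoverable by `stage_delta()` up to sampling noise
— the parameter-recovery tests use this.

`table_pattern_fixture()` reproduces the *state pattern* of the source
cohort exactly — which variables are present, kept or missing for every
patient × iteration × group, including the two patients (6 and 14)
without a third instance and the instance-id blocks 1–20 / 22–41 /
47–64 — with synthetic values under a fixed packaged seed. One
transcription ambiguity (a shifted geriatric-row entry for patient 6,
inconsistent with its missing third instance) is resolved as *iteration
2 kept, iteration 3 absent*.

Consequently, passing tests show that the *mechanics* — counting,
resolution, similarity, ranking, tree construction — are correct, and
that the structural and demographic claims reproduce. They cannot show
agreement with the original similarity percentages (e.g. the 73.4 %
top-neighbor figure), because the underlying clinical values were never
published; those numbers are explicitly out of the package's reach, and
nothing in the test suite pretends otherwise.

## Numerical and scale choices

* All statistics are plain two-pass computations in double precision;
  the dispersion measures are tested against independent two-pass
  references at 1e-12 relative tolerance.
* CSV and JSON writers format doubles with `%.17g`, so write–read round
  trips are bit-exact; the treemap JSON serializer is hand-rolled for
  the same reason (and tested byte-for-byte).
* Test problem sizes — cohorts of 14–20 instances, 200 seeded stacks for
  the treemap property suite, 500 similarity pairs, 100 synthetic gait
  signals — keep the whole suite within a couple of minutes on one core
  while giving the property checks real coverage; they are the package's
  chosen defaults, and all generators scale to larger sizes by argument.

## Known limitations

* The pre-clustering of candidates by sex and age that a larger stack
  would warrant is not implemented, matching the scope of the system
  this package models.
* No other proximity measures (Euclidean, Mahalanobis, …) and no formal
  cluster analysis: the Gower coefficient and the bounded treemap are
  the assessment.
* The unit-conversion registry covers metric clinical units only;
  anything else errs on the side of refusing to guess.
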