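---
title: "Methods: recall capture, intake computation and two-method validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recall capture, intake computation and two-method validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recall24)
```

## The measurement model

A self-administered 24-hour recall estimates what one participant consumed on
one calendar day (midnight to midnight — the "previous 24-hour period" is
interpreted as the previous calendar day so that replicate days align with
mean-daily-intake arithmetic). The recall proceeds in passes, and `recall24`
models each pass as a state with preconditions rather than a screen:

1. **Meal listing** — meals/snacks with time (HH:MM) and preparation
   location; the session keeps meals sorted by time.
2. **Item entry** — foods selected by free-text search over descriptions and
   alias tags (case-insensitive substring matching with diacritics folded;
   ranking: exact description, description prefix, description substring,
   tag-only; alphabetical tie-break).
3. **Detail entry** — completeness-of-collection prompts. Probe questions
   either annotate the entry or substitute a more specific item (e.g.
   homemade vs retail); linked foods are offered because they are commonly
   consumed with the primary selection (milk with cereal). Portion responses
   resolve to grams immediately.
4. **Review / finalization** — frequently-forgotten-foods checklist,
   supplements, usual-intake flag. Finalization fails loudly while any entry
   lacks a resolved weight or an answered probe, and the session is immutable
   afterwards.

Because every pass is an ordinary function call, a JSON answer script can
drive a whole session non-interactively; that is exactly how the test suite
exercises the engine.

### Portion-size resolution

Most items carry a set of three photograph anchors with known gram weights
`w1 < w2 < w3`. A respondent picks an image and a relation:

* "exactly this size" → the anchor weight `w_i`;
* "greater/less than" between anchors → the midpoint toward the neighbour;
* beyond the outermost anchors the midpoint rule is extended symmetrically:
  `w3 + (w3 − w2)/2` above the largest image, and `w1 − (w2 − w1)/2` below
  the smallest, floored at `w1/2` so a weight can never reach zero. The
  floor matters only when the lower anchor gap exceeds `w1`, but portion
  photograph series with such a skew exist.

Unit-portion items (crackers, biscuits) resolve as `unit_weight × count`.
These rules make resolved weight strictly monotone in both the image index
and the relation, which the suite asserts property-style.

### From sessions to intakes

Daily nutrients are linear: `Σ (weight_g / 100) × per-100 g composition`,
with supplements adding `dose_count ×` per-dose composition on top (the
generic option of a supplement category is the per-nutrient **median** over
its branded members; a nutrient absent from a member counts as 0 and an even
member count takes the mean of the two middle values). Food-group intakes
are summed gram weights per configured group. Mean daily intake over
replicate days uses the arithmetic mean and an n−1 SD; a single observed day
reports SD 0 with a `single_day` flag rather than erroring, so one-day
pipelines still run.

The default nutrient schema covers energy plus 26 nutrients (g, mg or µg as
conventional); the default food-group list has the 19 analysis groups used
for between-method comparison of food-group intakes. Both are arguments, not
constants. A finer group/category structure can ride along as item metadata;
no mapping between the two granularities is asserted because none is
defined.

### Energy adjustment

Correlation analyses run on energy-adjusted values to remove energy-level
confounding: energy-bearing macronutrients become percentage of energy,
`%E = g × factor / energy_kcal × 100`, and every other nutrient becomes its
amount per 10 MJ, `x × 10 / (kcal × 4.184/1000)`. The kcal/g factors default
to the UK convention — protein 4, carbohydrate 3.75 (monosaccharide
equivalents), fat 9, alcohol 7, fiber 2 — and are configurable because %E
adjustment is standard while the factor set is a convention. Fat and
carbohydrate sub-fractions (saturated/mono/poly; sugars/starch) use their
parent's factor. Energy itself is never re-derived from macronutrients: the
database's energy column is authoritative, and the factors are used only for
the %E scale. With that convention, a diet composed purely of the
energy-bearing macronutrients has %E values summing to exactly 100 when its
energy is computed from the same factors — an invariant in the test suite.

## The validation battery

Given per-participant mean daily intakes under two methods (aligned
participant sets are enforced), the report computes per nutrient:

* **Correlation** — Pearson and Spearman, raw and energy-adjusted, with
  strength bands resolved as half-open intervals: poor < 0.3 ≤ acceptable
  < 0.5 ≤ good < 0.7 ≤ very good. The printed convention for these bands
  overlaps at 0.3; the half-open resolution keeps the classification a
  partition.
* **Deattenuation** — an observed correlation computed from the mean of `n`
  replicate days is attenuated by within-person variance. The corrected
  coefficient is `R1 = R0 · √(1 + (s²w/s²b)/n)` with the variance components
  from a one-way ANOVA over the replicate days of the replicate-based method
  (method A): `s²w` is the within mean square and
  `s²b = (MS_between − MS_within)/k0`, where `k0` is the common replicate
  count when balanced and `(N − Σn²ᵢ/N)/(m−1)` otherwise; `k0` also serves
  as `n` in the formula for unbalanced data. When `MS_between ≤ MS_within`
  the between component is floored at a small ε with a warning — the
  inflation is then meaningless and the report shows it as such. `|R1|` can
  exceed 1; the value is reported uncapped with a `capped` flag. The raw
  (not energy-adjusted) Pearson coefficient is the one deattenuated, because
  the replicate-day variance components are estimated on the raw scale.
* **Cross-classification** — participants are assigned to quartiles by rank
  (`floor(4(rank − 0.5)/n) + 1`, average ranks for ties) under each method;
  the report gives the percentage in the same quartile (exact), same or
  adjacent (inclusive of exact), two apart (disagreement) and three apart
  (extreme). The three non-overlapping categories plus exact+adjacent
  partition to 100%.
* **Difference tests** — Shapiro–Wilk on the paired differences routes to a
  paired *t* (p > 0.05) or a Wilcoxon signed-rank (zero differences dropped,
  average-rank ties, normal approximation). All-zero differences are a
  degenerate "no difference" case reported as p = 1 with a flag instead of
  an undefined test. Food-group intakes use an independent-samples *t* with
  pooled variance by default — the convention of that literature despite the
  paired design — with Welch and a paired alternative behind configuration
  flags; the report records which test ran.
* **Bland–Altman** — limits `mean(d) ± k·SD(d)` with `k = 2` (the literal
  "2 standard deviations" convention; 1.96 is a config switch), the
  percentage of differences inside the limits, and a `comparable` verdict
  when that percentage exceeds 95. For iid normal differences ±2 SD covers
  ≈95.45% in the large-sample limit, so the rule is just attainable and the
  Monte-Carlo coverage test pins it inside [93, 98] at n = 10⁴.

### Biomarker agreement

Recovery biomarkers (urinary urea, sodium, potassium) track intake in
near-constant proportion; concentration biomarkers (plasma ascorbic acid,
carotenoids, omega-3 index) correlate without being proportional. The report
computes Spearman ρ per configured pairing, after two exclusions:

* **Supplement users** are dropped (supplemental intake reaches the
  biomarker but not the food-only intake estimate).
* **Incomplete 24-h urine collections** are dropped from urinary pairings:
  more than 1 missed void, total volume < 0.5 L, or a creatinine index
  (observed/expected creatinine excretion) outside [0.7, 1.3]. Expected
  excretion is 23 mg/kg/day for males and 18 for females; observed mmol/d
  converts at 113.12 mg/mmol. The norms and bounds are configurable and the
  screen can be disabled; every triggered reason is reported, not only the
  first.

Urinary sodium is corrected for incomplete excretion before pairing:
estimated intake = excretion / 0.90 (fraction configurable), mmol × 23 =
mg. Division by a constant cannot change a rank correlation, but the report
carries the corrected values because intake-scale comparisons need them.

Evaluation-questionnaire blocks are simple proportion summaries,
`100 × count/total` rounded **half-up** to one decimal — half-up, not R's
banker's rounding, because that is how such tables are conventionally
printed and it keeps recomputed percentages reproducible from counts.

## The synthetic cohort

The generator targets the statistical structure the validation analysis
assumes, not culinary realism:

* **Usual intakes** are log-normal between participants (dietary intakes are
  positive and right-skewed; geometric mean 2000 kcal for energy with
  geometric SD 1.3 by default, food groups GSD 1.5).
* **Days** multiply the usual intake by independent mean-1 log-normal
  factors: a per-variable day effect (within-person CV 0.25), a per-day
  factor shared across all variables of a participant-day (portion-size
  error correlates across nutrients), method bias (1 unless configured) and
  per-variable method noise. Everything multiplicative, so intakes stay
  positive and a bias of 0.9 yields a long-run mean of 0.9 × usual exactly.
  On the log scale the variance components are analytic —
  `s²w = log(1+cv²_day) + log(1+cv²_noise) + log(1+cv²_shared)`,
  `s²b = log(GSD)²` — which is what the variance-recovery tests check
  against.
* **Biomarkers** follow the pairing models: recovery = coefficient × recent
  intake × noise (urea 4.86 mmol per g protein, from ~16% nitrogen and ~85%
  of urinary N as urea; sodium fraction 0.90 matching the correction;
  potassium 0.77), concentration = intercept + slope × usual intake +
  Gaussian noise, creatinine = sex norm × weight × small noise. Missed
  voids, low volumes and supplement use are Bernoulli so the exclusion
  machinery has real work.
* **Sessions**: given a target energy, items and portion responses are added
  greedily from the portion grid, never exceeding 1.1 × target, until
  0.9 × target is reached; probes are answered deterministically with the
  first option and substitutions are resolved before an item's energy is
  counted. Unreachable targets are flagged, not fudged.

The default scenario is 39 participants, 3 recall days against a 4-day
diary — the shape of a small biomarker-validation study. What the generator
does **not** emulate: correlated nutrient intakes within a person beyond the
shared day factor (real diets correlate through foods), day-of-week and
seasonal structure, energy under-reporting that depends on adiposity or
social desirability, and measurement error correlated between the two
methods. Passing tests therefore demonstrate that the statistics recover the
structure they assume — not that any particular real instrument is valid.

## Numerical and design choices

* Quartile assignment uses average ranks then flooring; for n ≥ 4 distinct
  values all four quartiles are non-empty, and ties behave symmetrically.
* Zero-variance correlation input errors; a zero-variance **difference**
  vector in the paired test routes nonparametric (Shapiro–Wilk is undefined
  on constants), and all-zero differences short-circuit to the flagged
  p = 1.
* `s²b` floored at 1e-8 (configurable) when the ANOVA says "no between
  variance"; deattenuation then explodes by design and the `capped` flag
  plus the warning make it visible.
* Session JSON round trips are exact (numbers serialized at full precision),
  and a write→read→write cycle is a byte-level fixed point — asserted over
  randomized sessions.
* All generators take an explicit seed and restore the caller's RNG state;
  identical (config, seed) gives byte-identical artifacts.
* Problem sizes in the test suite are chosen to keep the full run under a
  minute while leaving Monte-Carlo margins wide: 100-seed level/power
  checks, 500 × 3 variance recovery, n = 10⁴ coverage, 50-seed
  deattenuation recovery against a ±0.05 band on a true 0.7.

## Limitations

* Deattenuation assumes the classical measurement-error model
  (independent, additive-on-the-analysis-scale within-person deviations);
  with systematic day-of-week structure the corrected coefficient is still
  biased.
* The report emits raw p-values only; no multiple-testing correction is
  applied across the ~27 nutrients and 19 groups, matching the conventions
  of the validation literature it mirrors.
* The creatinine-index norms are population constants; individual muscle
  mass varies, so the screen is a blunt instrument and the report flags
  prominently when it fires.
* No under-reporter identification (e.g. Goldberg cut-offs) and no
  estimation of "true intake" beyond deattenuation.
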