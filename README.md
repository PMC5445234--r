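# recall24

A headless R toolkit for **self-administered multiple-pass 24-hour dietary
recall** studies and for the statistics used to validate one dietary
assessment method against another.

Web-based recall tools walk a respondent through several passes — listing the
previous day's meals and times, adding foods from a searchable database,
answering probe and linked-food prompts, sizing portions against photograph
anchors, and reviewing frequently forgotten foods and supplements — and then
convert the answers into nutrient and food-group intakes. Validating such a
tool against a reference method (say, a semi-weighed food diary) uses a
well-established statistical battery. `recall24` implements both halves as
plain, scriptable R so the whole workflow can be developed, tested and
simulated without a web front-end or study data:

* **Food/supplement database** — items with per-100 g composition, food
  groups, search tags (so "Houmus" still finds "Hummus"), probe questions,
  linked foods, and portion specifications; referential integrity checked on
  load.
* **Recall engine** — a forward-only session state machine
  (meal listing → item entry → detail entry → review → finalized), drivable
  non-interactively by a JSON answer script. Portion responses resolve to
  grams: anchor weights for "exactly this size", midpoints between anchors
  for "less/greater than", symmetric extrapolation beyond the outermost
  images (`w3 + (w3−w2)/2` above; `max(w1 − (w2−w1)/2, w1/2)` below), and
  `unit_weight × count` for unit foods.
* **Intake computation** — per-day nutrient vectors
  (`Σ weight/100 × composition`, supplements added per dose), food-group
  gram totals, means ± SD over replicate days, and energy adjustment
  (macronutrients as %E via kcal/g factors; everything else per 10 MJ).
* **Validation statistics** — Pearson/Spearman correlations (raw and
  energy-adjusted) with strength bands (≥0.7 very good, 0.5–0.69 good,
  0.3–0.49 acceptable, <0.3 poor); deattenuation
  `R1 = R0·√(1 + (s²w/s²b)/n)` with variance components from a one-way
  ANOVA over replicate days; quartile cross-classification
  (exact / exact+adjacent / 2 apart / 3 apart); Bland–Altman limits of
  agreement `mean(d) ± 2·SD(d)` with the ">95% of points within limits"
  comparability rule; Shapiro–Wilk-routed paired tests (paired *t* /
  Wilcoxon signed-rank) and independent-samples *t* for food groups;
  recovery and concentration biomarker correlations with supplement-user
  exclusion, 24-h urine completeness screening (missed voids, <0.5 L volume,
  creatinine index outside [0.7, 1.3]) and the 90% sodium-excretion
  correction; evaluation-questionnaire proportion summaries.
* **Synthetic data** — log-normal usual intakes between participants,
  log-normal day-to-day variation within, multiplicative method bias/noise
  with a shared per-day factor, biomarkers linear in intake with noise, and
  session composition that hits target energies within ±10%, so every module
  is testable end to end from a seed.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` for Bland–Altman panels, and a
thin `recall24` command-line script (`inst/cli/`) with
`simulate / db-validate / recall-run / intakes / compare / evaluate`
subcommands.

## Worked example

Simulate a 39-participant validation study (3 recall days vs a 4-day diary),
then build the full agreement report:

```r
library(recall24)

cfg    <- simulation_config(n_participants = 39)
cohort <- simulate_cohort(cfg, seed = 1)
recall <- method_dataset(simulate_method_days(cohort, "recall", config = cfg, seed = 2), "recall")
diary  <- method_dataset(simulate_method_days(cohort, "diary",  config = cfg, seed = 3), "diary")
bio    <- simulate_biomarkers(cohort, recall$means, cfg, seed = 4)

report <- build_validation_report(recall, diary, biomarkers = bio)
glance(report)
#> # A tibble: 1 × 8
#>   method_a method_b n_participants n_nutrients n_food_groups median_pearson_r ...
#> 1 recall   diary                39          27            19            0.733
```

Per-nutrient agreement (means per method, raw Pearson r, deattenuated R1,
strength band, difference-test p):

```r
dplyr::select(tidy(report, "nutrients"),
              variable, mean_a, mean_b, pearson_r, R1, strength_raw, diff_p)
#>   variable      mean_a  mean_b pearson_r    R1 strength_raw diff_p
#> 1 calcium       913.    897.       0.817 0.929 very_good     0.581
#> 2 carbohydrate  242.    239.       0.701 0.835 very_good     0.744
#> 3 carotene     2064.   1986.       0.659 0.777 good          0.395
#> 5 energy       2073.   1974.       0.628 0.805 good          0.275
#> 6 fat            77.3    74.5      0.377 0.492 acceptable    0.467
```

Deattenuation inflates each observed coefficient for the day-to-day variance
in the 3 replicate recall days (fat's R1 of 0.49 vs raw 0.38 shows a nutrient
whose within-person variance is large). Bland–Altman for the macronutrient
panel — with both methods unbiased, mean differences sit near zero and ≥95%
of participants fall inside the ±2 SD limits for most panels:

```r
tidy(report, "bland_altman")
#>   variable     mean_difference  loa_low loa_high pct_within_loa comparable
#> 1 energy                 98.7  -1015.    1213.             97.4 TRUE
#> 2 protein                 1.47   -29.0     32.0            94.9 FALSE
#> 3 carbohydrate            2.95  -109.     115.             97.4 TRUE
autoplot(report)   # faceted Bland–Altman plot
```

Biomarker block (Spearman ρ on participants surviving the supplement-user and
urine-completeness exclusions; n drops from 39 accordingly):

```r
dplyr::select(tidy(report, "biomarkers"), method, pairing, spearman_rho, n)
#>   method pairing                                    spearman_rho     n
#> 1 diary  urinary urea ~ protein (g/d)                      0.753    22
#> 2 diary  urinary potassium ~ potassium (mg/d)              0.616    22
#> 3 diary  urinary sodium (corrected) ~ sodium (mg/d)        0.721    22
```

The same pipeline runs from a shell:

```sh
inst/cli/recall24 simulate --out study/ --seed 1
inst/cli/recall24 compare --method-a study/intakes_recall.csv \
    --method-b study/intakes_diary.csv --biomarkers study/biomarkers.csv --out report/
```

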