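test_that("generated databases are valid, deterministic and hit configured fractions", {
  db <- generate_food_database(100, seed = 42)
  expect_s3_class(db, "food_db") # construction implies all invariants hold
  rep <- validate_database(db)
  expect_equal(rep$n_items, 100)
  expect_true(all(default_food_groups() %in% db$foods$food_group))

  # same seed -> byte-identical database files
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_food_db(generate_food_database(100, seed = 42), f1)
  write_food_db(generate_food_database(100, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    generate_food_database(100, seed = 1)$foods$energy,
    generate_food_database(100, seed = 2)$foods$energy
  ))

  # tagging fraction: at n = 751 the tagged count concentrates near 484
  big <- generate_food_database(751, seed = 13)
  n_tagged <- validate_database(big)$n_tagged
  p <- 484 / 751
  expect_lt(abs(n_tagged - 751 * p), 4 * sqrt(751 * p * (1 - p)))

  expect_error(generate_food_database(10, seed = 1), "at least")
})

test_that("cohort usual intakes follow the configured log-normal structure", {
  cfg <- simulation_config(n_participants = 500)
  co <- simulate_cohort(cfg, seed = 7)
  energy <- co$usual$usual[co$usual$variable == "energy"]
  gm <- exp(mean(log(energy)))
  expect_lt(abs(gm - 2000) / 2000, 0.02)
  expect_true(all(co$usual$usual > 0))

  # degenerate spread: geometric SD 1 makes all participants identical
  flat <- simulate_cohort(
    simulation_config(n_participants = 20, nutrient_gsd = 1, group_gsd = 1),
    seed = 8
  )
  expect_equal(stats::sd(flat$usual$usual[flat$usual$variable == "energy"]), 0)

  expect_false(identical(
    simulate_cohort(cfg, seed = 1)$usual$usual,
    simulate_cohort(cfg, seed = 2)$usual$usual
  ))
})

test_that("method days carry bias, within-person variation and recoverable variance components", {
  noiseless <- simulation_config(
    n_participants = 10, within_cv = 0,
    method_profiles = list(recall = list(bias = 1, noise_cv = 0, shared_day_cv = 0))
  )
  co <- simulate_cohort(noiseless, seed = 1)
  days <- simulate_method_days(co, "recall", n_days = 2, config = noiseless, seed = 2)
  merged <- dplyr::inner_join(days, co$usual, by = c("participant_id", "variable", "kind"))
  expect_equal(merged$food_only, merged$usual)

  # a 0.9 multiplicative bias on protein shows up in the long-run mean
  biased <- simulation_config(
    n_participants = 1, within_cv = 0.2,
    method_profiles = list(recall = list(
      bias = c(protein = 0.9), noise_cv = 0.1, shared_day_cv = 0
    ))
  )
  co1 <- simulate_cohort(biased, seed = 3)
  many <- simulate_method_days(co1, "recall", n_days = 10000, config = biased, seed = 4)
  usual_p <- co1$usual$usual[co1$usual$variable == "protein"]
  mean_p <- mean(many$food_only[many$variable == "protein"])
  expect_lt(abs(mean_p / usual_p - 0.9), 0.02)
  # unbiased variables keep mean ratio near 1
  usual_e <- co1$usual$usual[co1$usual$variable == "energy"]
  expect_lt(abs(mean(many$food_only[many$variable == "energy"]) / usual_e - 1), 0.02)

  # ANOVA on log replicates recovers the configured within/between ratio
  cfg <- simulation_config(
    n_participants = 500, within_cv = 0.25, nutrient_gsd = 1.3,
    method_profiles = list(recall = list(bias = 1, noise_cv = 0.1, shared_day_cv = 0.08))
  )
  co2 <- simulate_cohort(cfg, seed = 5)
  days2 <- simulate_method_days(co2, "recall", n_days = 3, config = cfg, seed = 6)
  en <- days2[days2$variable == "energy", ]
  vc <- variance_components(tibble::tibble(
    participant_id = en$participant_id, value = log(en$food_only)
  ))
  sw2_true <- log(1 + 0.25^2) + log(1 + 0.1^2) + log(1 + 0.08^2)
  sb2_true <- log(1.3)^2
  expect_lt(abs(vc$sw2 / vc$sb2 - sw2_true / sb2_true) / (sw2_true / sb2_true), 0.15)
})

test_that("biomarkers track intake with the configured structure", {
  cfg <- simulation_config(n_participants = 50)
  cfg$biomarker$recovery_noise_cv <- 0
  cfg$missed_void_prob <- 0
  cfg$low_volume_prob <- 0
  co <- simulate_cohort(cfg, seed = 9)
  bio <- simulate_biomarkers(co, config = cfg, seed = 10)

  # noise-free recovery: urinary sodium is exactly 90% of intake in mmol,
  # and the intake estimator inverts it
  sodium_mg <- co$usual$usual[co$usual$variable == "sodium"]
  expect_equal(bio$sodium_mmol_d, 0.9 * sodium_mg / 23, tolerance = 1e-12)
  expect_equal(
    sodium_intake_estimate(bio$sodium_mmol_d)$intake_mg_d, sodium_mg,
    tolerance = 1e-12
  )

  # noise-free urea is a monotone function of protein: Spearman rho = 1
  protein <- co$usual$usual[co$usual$variable == "protein"]
  expect_equal(cor(bio$urea_mmol_d, protein, method = "spearman"), 1)

  # with noise tuned for a population rank correlation near 0.65
  cfg2 <- simulation_config(n_participants = 300, nutrient_gsd = 1.3)
  cfg2$biomarker$recovery_noise_cv <- 0.31
  co2 <- simulate_cohort(cfg2, seed = 11)
  bio2 <- simulate_biomarkers(co2, config = cfg2, seed = 12)
  protein2 <- co2$usual$usual[co2$usual$variable == "protein"]
  rho <- cor(bio2$urea_mmol_d, protein2, method = "spearman")
  expect_lt(abs(rho - 0.65), 0.1)
})

test_that("composed recall sessions hit their energy targets within tolerance, deterministically", {
  db <- generate_food_database(80, seed = 61)
  set.seed(62)
  targets <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:20),
    date = "2016-03-01",
    energy_kcal = runif(20, 1200, 3200)
  )
  sessions <- simulate_recall_sessions(db, targets, seed = 63)
  unreachable <- attr(sessions, "unreachable")
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    expect_equal(s$state, "finalized")
    di <- compute_daily_intake(s, db)
    kcal <- di$food_only[di$variable == "energy" & di$kind == "nutrient"]
    if (!unreachable[i]) {
      expect_gte(kcal, 0.9 * targets$energy_kcal[i] - 1e-9)
      expect_lte(kcal, 1.1 * targets$energy_kcal[i] + 1e-9)
    }
  }
  expect_lte(sum(unreachable), 2) # the generated DB spans ordinary targets

  again <- simulate_recall_sessions(db, targets, seed = 63)
  for (i in seq_along(sessions)) expect_equal(tidy(again[[i]]), tidy(sessions[[i]]))
})

test_that("a noise-free paired simulation yields perfect agreement end to end", {
  cfg <- simulation_config(
    n_participants = 12, within_cv = 0,
    method_profiles = list(
      recall = list(bias = 1, noise_cv = 0, shared_day_cv = 0),
      diary = list(bias = 1, noise_cv = 0, shared_day_cv = 0)
    )
  )
  co <- simulate_cohort(cfg, seed = 71)
  ma <- method_dataset(simulate_method_days(co, "recall", config = cfg, seed = 72), "recall")
  mb <- method_dataset(simulate_method_days(co, "diary", config = cfg, seed = 73), "diary")
  rep <- suppressWarnings(build_validation_report(ma, mb))
  expect_true(all(abs(rep$nutrients$pearson_r - 1) < 1e-12))
  expect_true(all(abs(rep$nutrients$spearman_rho - 1) < 1e-12))
  expect_true(all(rep$nutrients$pct_exact == 100))
  expect_true(all(rep$nutrients$no_difference))
  expect_true(all(rep$nutrients$diff_p == 1))
  expect_true(all(rep$bland_altman$loa_low == 0 & rep$bland_altman$loa_high == 0))
  expect_true(all(rep$bland_altman$pct_within_loa == 100))
})

test_that("an under-reporting bias on one food group shows directionally in the report", {
  cfg <- simulation_config(
    n_participants = 25,
    method_profiles = list(
      recall = list(bias = 1, noise_cv = 0.1, shared_day_cv = 0.05),
      diary = list(
        bias = c("Alcoholic beverages" = 0.5), noise_cv = 0.1, shared_day_cv = 0.05
      )
    )
  )
  co <- simulate_cohort(cfg, seed = 81)
  ma <- method_dataset(simulate_method_days(co, "recall", config = cfg, seed = 82), "recall")
  mb <- method_dataset(simulate_method_days(co, "diary", config = cfg, seed = 83), "diary")
  rep <- suppressWarnings(build_validation_report(ma, mb))
  alc <- rep$food_groups[rep$food_groups$food_group == "Alcoholic beverages", ]
  expect_gt(alc$mean_a, alc$mean_b)
})
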