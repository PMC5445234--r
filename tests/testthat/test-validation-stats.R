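test_that("Shapiro-Wilk routing separates heavy-tailed from normal data", {
  set.seed(101)
  heavy <- stats::rcauchy(50)
  route <- normality_route(heavy)
  expect_equal(as.character(route), "nonparametric")
  expect_lt(attr(route, "p.value"), 0.05)

  # level: truly normal data routes parametric in >= 90% of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    as.character(normality_route(stats::rnorm(200))) == "parametric"
  }, logical(1))
  expect_gte(mean(hits), 0.90)

  expect_error(normality_route(rep(3, 10)), "constant")
  expect_error(normality_route(c(1, 2)), "at least 3")
})

test_that("method correlations behave at the degenerate extremes and match a rank oracle", {
  x <- c(5, 9, 1, 7, 3, 8, 2, 6)
  same <- correlate_methods(x, x)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$spearman_rho, 1)

  rev <- correlate_methods(x, -x)
  expect_equal(rev$spearman_rho, -1)

  y <- c(4, 8, 2, 9, 1, 7, 3, 5)
  got <- correlate_methods(x, y)
  # brute-force Spearman: Pearson correlation of the rank vectors
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$spearman_rho, oracle, tolerance = 1e-12)
  expect_equal(got$n, 8)

  expect_error(correlate_methods(rep(1, 5), 1:5), "zero-variance")
  expect_error(correlate_methods(1:2, 2:1), "at least 3")
})

test_that("energy-adjusted correlation mode rescales both methods before correlating", {
  set.seed(7)
  a <- rlnorm(20, log(80), 0.2)
  b <- a * rlnorm(20, 0, 0.1)
  ea <- rlnorm(20, log(2000), 0.15)
  eb <- rlnorm(20, log(2000), 0.15)
  adj <- correlate_methods(a, b,
    mode = "energy_adjusted", variable = "protein",
    energy_a = ea, energy_b = eb
  )
  oracle <- cor(a * 4 / ea * 100, b * 4 / eb * 100)
  expect_equal(adj$pearson_r, oracle, tolerance = 1e-12)
  # per-10MJ scaling for a micronutrient is a participant-wise monotone map
  adj2 <- correlate_methods(a, b,
    mode = "energy_adjusted", variable = "vitamin_c",
    energy_a = ea, energy_b = eb
  )
  oracle2 <- cor(a * 10 / (ea * 4.184 / 1000), b * 10 / (eb * 4.184 / 1000))
  expect_equal(adj2$pearson_r, oracle2, tolerance = 1e-12)
})

test_that("correlation strength bands use half-open boundaries", {
  expect_equal(classify_correlation(0.75), "very_good")
  expect_equal(classify_correlation(0.70), "very_good")
  expect_equal(classify_correlation(0.69), "good")
  expect_equal(classify_correlation(0.50), "good")
  expect_equal(classify_correlation(0.32), "acceptable")
  expect_equal(classify_correlation(0.30), "acceptable")
  expect_equal(classify_correlation(0.29), "poor")
  expect_equal(classify_correlation(-0.8), "poor")
  expect_error(classify_correlation(1.2), "not a correlation")
})

test_that("deattenuation matches its closed form and the ANOVA components match hand computation", {
  d <- deattenuate(0.5, sw2 = 1, sb2 = 1, n_rep = 3)
  expect_equal(d$R1, 0.5 * sqrt(4 / 3), tolerance = 1e-12)
  expect_false(d$capped)

  expect_equal(deattenuate(0.5, sw2 = 0, sb2 = 1, n_rep = 3)$R1, 0.5)

  # balanced 6 participants x 3 days: mean squares by the textbook formulas,
  # computed here from scratch rather than via the package path
  set.seed(202)
  values <- matrix(rnorm(18, rep(rnorm(6, 0, 2), each = 3), 1), ncol = 3, byrow = TRUE)
  reps <- tibble::tibble(
    participant_id = rep(paste0("p", 1:6), each = 3),
    value = as.vector(t(values))
  )
  grand <- mean(values)
  msb <- 3 * sum((rowMeans(values) - grand)^2) / (6 - 1)
  msw <- sum((values - rowMeans(values))^2) / (18 - 6)
  vc <- variance_components(reps)
  expect_equal(vc$sw2, msw, tolerance = 1e-12)
  expect_equal(vc$sb2, (msb - msw) / 3, tolerance = 1e-12)
  expect_equal(vc$k0, 3)

  # R1 inflates and the capped flag fires (value reported uncapped)
  big <- deattenuate(0.9, sw2 = 4, sb2 = 1, n_rep = 2)
  expect_gt(abs(big$R1), 1)
  expect_true(big$capped)

  expect_error(
    variance_components(tibble::tibble(participant_id = c("a", "b"), value = 1:2)),
    "replicate"
  )
  expect_warning(
    variance_components(tibble::tibble(
      participant_id = rep(c("a", "b", "c"), each = 2),
      value = c(1, 2, 1.5, 1.6, 1.2, 1.9)
    )),
    "floored"
  )
})

test_that("deattenuation never shrinks the coefficient", {
  set.seed(11)
  for (k in 1:50) {
    r0 <- runif(1, -0.95, 0.95)
    sw2 <- runif(1, 0, 5)
    sb2 <- runif(1, 0.1, 5)
    n <- sample(2:6, 1)
    r1 <- deattenuate(r0, sw2 = sw2, sb2 = sb2, n_rep = n)$R1
    expect_gte(abs(r1) + 1e-12, abs(r0))
    if (sw2 == 0) expect_equal(r1, r0)
  }
})

test_that("cross-classification handles identical, reversed and random rankings", {
  x <- c(3, 1, 4, 1.5, 5, 9, 2, 6)
  cc <- cross_classify(x, x * 2 + 1) # monotone map: identical ranking
  expect_equal(cc$pct_exact, 100)
  expect_equal(cc$pct_exact_plus_adjacent, 100)
  expect_equal(cc$pct_disagreement + cc$pct_extreme, 0)

  # reversed ranks, n = 8: quartiles 1,1,2,2,3,3,4,4 against 4,4,3,3,2,2,1,1
  a <- 1:8
  cc <- cross_classify(a, rev(a))
  expect_equal(cc$pct_exact, 0)
  expect_equal(cc$pct_extreme, 50)
  expect_equal(cc$pct_exact_plus_adjacent, 50)

  expect_error(cross_classify(1:3, 3:1), "at least 4")
})

test_that("cross-classification equals a brute-force quartile oracle and sums to 100", {
  oracle_quartile <- function(v) {
    n <- length(v)
    r <- rank(v, ties.method = "average")
    floor(4 * (r - 0.5) / n) + 1
  }
  set.seed(303)
  for (k in 1:100) {
    n <- sample(4:60, 1)
    a <- rnorm(n)
    b <- if (k %% 3 == 0) sample(a) else a + rnorm(n, 0, 0.8)
    if (k %% 5 == 0) a <- round(a) # induce ties
    cc <- cross_classify(a, b)
    d <- abs(oracle_quartile(a) - oracle_quartile(b))
    expect_equal(cc$pct_exact, 100 * mean(d == 0))
    expect_equal(cc$pct_exact_plus_adjacent, 100 * mean(d <= 1))
    expect_equal(cc$pct_disagreement, 100 * mean(d == 2))
    expect_equal(cc$pct_extreme, 100 * mean(d == 3))
    expect_lte(cc$pct_exact, cc$pct_exact_plus_adjacent)
    expect_equal(
      cc$pct_exact_plus_adjacent + cc$pct_disagreement + cc$pct_extreme, 100,
      tolerance = 0.2
    )
  }
})

test_that("Bland-Altman limits, coverage and the comparability rule are computed as specified", {
  zero <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(zero$loa_low, 0)
  expect_equal(zero$loa_high, 0)
  expect_equal(zero$pct_within_loa, 100)
  expect_true(zero$comparable)

  a <- c(0, 1, 2, 3, 4)
  b <- c(2, 2, 2, 2, 2)
  ba <- bland_altman(a, b) # d = -2,-1,0,1,2
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sqrt(2.5))
  expect_equal(ba$loa_low, -2 * sqrt(2.5))
  expect_equal(ba$loa_high, 2 * sqrt(2.5))
  expect_equal(ba$pct_within_loa, 100)

  # +/- 2 SD covers about 95.4% of iid normal differences
  set.seed(404)
  d <- rnorm(10000)
  ba2 <- bland_altman(d, rep(0, 10000))
  expect_gte(ba2$pct_within_loa, 93)
  expect_lte(ba2$pct_within_loa, 98)

  # k is configurable
  ba3 <- bland_altman(a, b, analysis_config(ba_k = 1.96))
  expect_equal(ba3$loa_high, 1.96 * sqrt(2.5))

  expect_error(bland_altman(1:2, 2:1), "at least 3")
})

test_that("paired difference tests route by normality and flag all-zero differences", {
  same <- paired_difference_test(1:10, 1:10)
  expect_equal(same$p, 1)
  expect_true(same$all_zero)
  expect_equal(same$test_used, "none")

  # a known 6-pair example: Wilcoxon signed-rank statistic by hand
  a <- c(12, 9, 7, 15, 11, 8)
  b <- c(10, 11, 4, 10, 10, 9)
  d <- a - b # 2,-2,3,5,1,-1  -> |d| ranks: 3.5,3.5,5,6,1.5,1.5
  w <- suppressWarnings(stats::wilcox.test(d, exact = FALSE))
  manual_v <- sum(rank(abs(d))[d > 0]) # 3.5 + 5 + 6 + 1.5 = 16
  expect_equal(manual_v, 16)
  expect_equal(unname(w$statistic), manual_v)

  # power: a one-SD shift at n=100 is detected at p < .01 almost always
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(100)
    paired_difference_test(x + 1, x + rnorm(100, 0, 0.5))$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # routing: heavy-tailed differences take the signed-rank branch
  set.seed(9)
  x <- rnorm(40)
  res <- paired_difference_test(x + stats::rcauchy(40, scale = 2), x)
  expect_equal(res$test_used, "wilcoxon_signed_rank")
})

test_that("independent difference test uses the pooled t by default and Welch behind the flag", {
  set.seed(15)
  a <- rnorm(30, 10, 2)
  b <- rnorm(30, 12, 2)
  res <- independent_difference_test(a, b)
  oracle <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$p, oracle$p.value)
  expect_equal(res$test_used, "independent_t")

  welch <- independent_difference_test(a, b, analysis_config(welch = TRUE))
  expect_equal(welch$p, stats::t.test(a, b)$p.value)
  expect_equal(welch$test_used, "welch_t")
})

test_that("urine completeness screening reports every triggered exclusion reason", {
  rec <- function(...) {
    modifyList(
      list(
        sex = "male", weight_kg = 80, urine_volume_l = 1.5, missed_voids = 0,
        creatinine_mmol_d = 23 * 80 / 113.12
      ),
      list(...)
    )
  }
  ok <- urine_completeness(rec())
  expect_true(ok$included)
  expect_length(ok$reasons, 0)
  expect_equal(ok$creatinine_index, 1, tolerance = 1e-12)

  lowvol <- urine_completeness(rec(urine_volume_l = 0.4))
  expect_false(lowvol$included)
  expect_match(lowvol$reasons, "volume<0.5L", all = FALSE)

  voids <- urine_completeness(rec(missed_voids = 2))
  expect_false(voids$included)
  expect_match(voids$reasons, "missed voids", all = FALSE)

  lowcr <- urine_completeness(rec(creatinine_mmol_d = 0.5 * 23 * 80 / 113.12))
  expect_false(lowcr$included)
  expect_match(lowcr$reasons, "creatinine index", all = FALSE)

  multi <- urine_completeness(rec(urine_volume_l = 0.3, missed_voids = 3))
  expect_length(multi$reasons, 2)

  # female norm: 18 mg/kg/day
  f <- urine_completeness(rec(sex = "female", weight_kg = 60, creatinine_mmol_d = 18 * 60 / 113.12))
  expect_equal(f$creatinine_index, 1, tolerance = 1e-12)

  expect_error(urine_completeness(rec(sex = NA)), "sex and weight")
  skipidx <- urine_completeness(rec(sex = NA, creatinine_mmol_d = NA),
    check_creatinine_index = FALSE
  )
  expect_true(skipidx$included)
})

test_that("sodium intake back-calculation divides by the excretion fraction", {
  expect_equal(sodium_intake_estimate(90)$intake_mmol_d, 100)
  expect_equal(sodium_intake_estimate(0)$intake_mmol_d, 0)
  est <- sodium_intake_estimate(130.5)
  expect_equal(est$intake_mmol_d, 145)
  expect_equal(est$intake_mg_d, 3335)
  expect_error(sodium_intake_estimate(-1), "negative")
})

test_that("proportion summaries reproduce printed percentage conventions", {
  pref <- summarize_proportions(c(tool = 80, reference = 37, other = 1))
  expect_equal(pref$pct, c(67.8, 31.4, 0.8))

  hide <- summarize_proportions(c(no = 113, yes = 5))
  expect_equal(hide$pct[1], 95.8)

  zero <- summarize_proportions(c(a = 0, b = 10))
  expect_equal(zero$pct, c(0, 100))

  expect_error(summarize_proportions(c(a = 0, b = 0)), "positive")
  expect_error(summarize_proportions(c(a = -1, b = 2)), "non-negative")
})

test_that("Spearman correlations are invariant under monotone transforms", {
  set.seed(21)
  a <- rlnorm(30)
  b <- a * rlnorm(30, 0, 0.4)
  base <- correlate_methods(a, b)$spearman_rho
  expect_equal(correlate_methods(exp(a), b)$spearman_rho, base)
  expect_equal(correlate_methods(a, log(b))$spearman_rho, base)
  expect_equal(correlate_methods(rank(a), b)$spearman_rho, base)
})

test_that("biomarker correlations exclude supplement users and incomplete urine collections", {
  set.seed(31)
  n <- 39
  pid <- sprintf("p%03d", 1:n)
  protein <- rlnorm(n, log(80), 0.25)
  means <- tibble::tibble(
    participant_id = pid, variable = "protein", kind = "nutrient", mean = protein
  )
  bio <- tibble::tibble(
    participant_id = pid, sex = "male", weight_kg = 80,
    urine_volume_l = 1.5, missed_voids = 0,
    urea_mmol_d = 5 * protein, # exactly monotone
    creatinine_mmol_d = 23 * 80 / 113.12,
    supplement_user = c(rep(TRUE, 15), rep(FALSE, 24))
  )
  pairing <- tibble::tibble(
    biomarker = "urea_mmol_d", sample = "urine", variables = list("protein"),
    kind = "nutrient", corrected = FALSE, pairing = "urea ~ protein"
  )
  res <- biomarker_correlation(means, bio, pairing)
  expect_equal(res$spearman_rho, 1)
  expect_equal(res$n, 24) # 39 minus 15 supplement users
  expect_equal(res$n_excluded_supplement, 15)

  # incomplete collections come out of urinary analyses too
  bio2 <- bio
  bio2$missed_voids[16:19] <- 2
  res2 <- biomarker_correlation(means, bio2, pairing)
  expect_equal(res2$n, 20)
  expect_equal(res2$n_excluded_urine, 4)

  # noisy but real signal keeps a high rank correlation
  set.seed(32)
  means3 <- tibble::tibble(
    participant_id = sprintf("q%03d", 1:100), variable = "protein",
    kind = "nutrient", mean = rlnorm(100, log(80), 0.25)
  )
  bio3 <- tibble::tibble(
    participant_id = means3$participant_id, sex = "male", weight_kg = 80,
    urine_volume_l = 1.5, missed_voids = 0,
    urea_mmol_d = 5 * means3$mean * rlnorm(100, 0, 0.15),
    creatinine_mmol_d = 23 * 80 / 113.12,
    supplement_user = FALSE
  )
  res3 <- biomarker_correlation(means3, bio3, pairing)
  expect_gt(res3$spearman_rho, 0.8)

  bio4 <- bio
  bio4$supplement_user <- c(rep(TRUE, 37), rep(FALSE, 2))
  expect_error(biomarker_correlation(means, bio4, pairing), "fewer than 3")
})

test_that("the assembled report is complete, serializable and degenerate-safe", {
  cfg <- simulation_config(
    n_participants = 16,
    method_profiles = list(
      recall = list(bias = 1, noise_cv = 0.12, shared_day_cv = 0.08),
      diary = list(bias = 1, noise_cv = 0.08, shared_day_cv = 0.05)
    )
  )
  co <- simulate_cohort(cfg, seed = 51)
  ma <- method_dataset(simulate_method_days(co, "recall", config = cfg, seed = 52), "recall")
  mb <- method_dataset(simulate_method_days(co, "diary", config = cfg, seed = 53), "diary")
  bio <- simulate_biomarkers(co, ma$means, cfg, seed = 54)
  counts <- tibble::tibble(
    question = "preference", category = c("tool", "reference", "other"),
    count = c(80, 37, 1)
  )
  rep <- suppressWarnings(
    build_validation_report(ma, mb, biomarkers = bio, evaluation_counts = counts)
  )
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$nutrients), 27)
  expect_equal(nrow(rep$food_groups), 19)
  expect_equal(nrow(rep$bland_altman), 5)
  expect_equal(nrow(rep$biomarkers), 14) # 7 pairings x 2 methods
  expect_equal(rep$evaluation$pct, c(67.8, 31.4, 0.8))
  expect_true(all(!is.na(rep$nutrients$n)))

  g <- glance(rep)
  expect_equal(g$n_participants, 16)

  dir <- withr::local_tempdir()
  write_validation_report(rep, dir)
  rep2 <- read_validation_report(dir)
  expect_equal(tidy(rep2, "nutrients"), tidy(rep, "nutrients"))
  expect_equal(tidy(rep2, "food_groups"), tidy(rep, "food_groups"))
  expect_equal(tidy(rep2, "biomarkers"), tidy(rep, "biomarkers"))
  expect_equal(rep2$methods, rep$methods)

  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")

  # misaligned participant sets fail loudly
  mb_bad <- method_dataset(
    dplyr::filter(mb$days, participant_id != "p001"), "diary"
  )
  expect_error(build_validation_report(ma, mb_bad), "misalignment")
})
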