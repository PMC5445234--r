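#' Route between parametric and nonparametric tests
#'
#' Shapiro-Wilk normality check used to decide which difference test applies:
#' parametric when the test does not reject normality at `alpha`
#' (`p > alpha`), nonparametric otherwise. For a paired comparison the check
#' runs on the differences; for an independent comparison run it on each
#' sample.
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @param alpha Significance level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`, with attributes `statistic`
#'   and `p.value` from the Shapiro-Wilk test.
#' @export
normality_route <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("normality check needs at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("normality check is undefined for a constant vector", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  structure(
    if (sw$p.value > alpha) "parametric" else "nonparametric",
    statistic = unname(sw$statistic), p.value = sw$p.value
  )
}

#' Correlation between two assessment methods
#'
#' Pearson and Spearman coefficients between per-participant mean daily
#' intakes from two methods, raw or energy-adjusted. In energy-adjusted mode
#' both sides are first rescaled with [energy_adjust()] arithmetic:
#' percentage of energy for energy-bearing macronutrients, amount per 10 MJ
#' for everything else, using each participant's own energy intake under the
#' respective method.
#'
#' @param a,b Aligned numeric vectors of per-participant values (`n >= 3`).
#' @param mode `"raw"` or `"energy_adjusted"`.
#' @param variable Variable name (needed for energy-adjusted mode).
#' @param energy_a,energy_b Per-participant energy intake (kcal) under each
#'   method (energy-adjusted mode only).
#' @param config An [analysis_config()].
#' @return One-row tibble: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`, `mode`.
#' @export
correlate_methods <- function(a, b, mode = c("raw", "energy_adjusted"),
                              variable = NULL, energy_a = NULL, energy_b = NULL,
                              config = analysis_config()) {
  mode <- match.arg(mode)
  config <- as_analysis_config(config)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("correlation needs at least 3 pairs", call. = FALSE)
  if (mode == "energy_adjusted") {
    stopifnot(!is.null(variable), !is.null(energy_a), !is.null(energy_b))
    a <- adjust_vector(a, variable, energy_a[ok], config)
    b <- adjust_vector(b, variable, energy_b[ok], config)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation is undefined for zero-variance input", call. = FALSE)
  }
  pe <- suppressWarnings(stats::cor.test(a, b, method = "pearson"))
  sp <- suppressWarnings(stats::cor.test(a, b, method = "spearman", exact = FALSE))
  tibble::tibble(
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    n = length(a), mode = mode
  )
}

adjust_vector <- function(x, variable, energy_kcal, config) {
  map <- macronutrient_factor_map(config)
  if (variable == "energy") return(x)
  if (variable %in% names(map)) {
    x * config$energy_factors[[map[[variable]]]] / energy_kcal * 100
  } else {
    x * 10 / (energy_kcal * config$kj_per_kcal / 1000)
  }
}

#' Classify correlation strength
#'
#' Conventional strength bands for validation studies, resolved as half-open
#' intervals: poor below 0.3, acceptable in [0.3, 0.5), good in [0.5, 0.7),
#' very good at 0.7 and above. The coefficient is used as given (a strongly
#' negative coefficient is "poor" agreement, not "very good").
#'
#' @param r Numeric vector of correlation coefficients in [-1, 1].
#' @return Character vector: `"poor"`, `"acceptable"`, `"good"`,
#'   `"very_good"`.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1 is not a correlation", call. = FALSE)
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r >= 0.7 ~ "very_good",
    r >= 0.5 ~ "good",
    r >= 0.3 ~ "acceptable",
    .default = "poor"
  )
}

#' Variance components from replicate intake days
#'
#' One-way random-effects ANOVA with participant as the factor. The
#' within-person variance is the within mean square; the between-person
#' variance is `(MS_between - MS_within) / k0`, where `k0` is the common
#' replicate count when balanced and `(N - sum(n_i^2)/N) / (m - 1)` for
#' unbalanced data. When the between mean square does not exceed the within
#' mean square the between-person component is floored at a small positive
#' epsilon with a warning.
#'
#' @param replicates Data frame with columns `participant_id` and `value`
#'   (one row per replicate day), or a list of per-participant numeric
#'   vectors.
#' @param sb2_epsilon Floor for the between-person component.
#' @return List: `sw2`, `sb2`, `k0`, `n_participants`, `n_obs`, `floored`.
#' @export
variance_components <- function(replicates, sb2_epsilon = 1e-8) {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    replicates <- tibble::tibble(
      participant_id = rep(
        if (is.null(names(replicates))) as.character(seq_along(replicates)) else names(replicates),
        lengths(replicates)
      ),
      value = unlist(replicates, use.names = FALSE)
    )
  }
  replicates <- replicates[!is.na(replicates$value), , drop = FALSE]
  ni <- table(replicates$participant_id)
  ni <- ni[ni >= 2]
  if (length(ni) < 2) {
    stop("variance components need >= 2 participants with >= 2 replicate days", call. = FALSE)
  }
  replicates <- replicates[replicates$participant_id %in% names(ni), , drop = FALSE]
  fit <- stats::aov(value ~ factor(participant_id), data = replicates)
  tab <- stats::anova(fit)
  msb <- tab$`Mean Sq`[1]
  msw <- tab$`Mean Sq`[2]
  N <- sum(ni)
  m <- length(ni)
  k0 <- (N - sum(ni^2) / N) / (m - 1)
  sb2 <- (msb - msw) / k0
  floored <- FALSE
  if (sb2 <= 0) {
    warning("between mean square does not exceed within mean square; sb2 floored at epsilon")
    sb2 <- sb2_epsilon
    floored <- TRUE
  }
  list(sw2 = msw, sb2 = sb2, k0 = k0, n_participants = m, n_obs = N, floored = floored)
}

#' Deattenuate an observed between-method correlation
#'
#' A correlation computed from the mean of a few replicate recall days is
#' attenuated by within-person day-to-day variance. The corrected coefficient
#' is `R1 = R0 * sqrt(1 + (sw2/sb2)/n)`, where `sw2/sb2` is the ratio of
#' within- to between-person variance from a one-way ANOVA over the replicate
#' days and `n` is the number of replicates per person (the effective
#' replicate count `k0` for unbalanced data). `|R1|` never falls below
#' `|R0|`; when the inflation pushes `|R1|` past 1 the value is reported
#' uncapped with `capped = TRUE`.
#'
#' @param R0 Observed correlation coefficient.
#' @param replicates Replicate day values, as in [variance_components()], or
#'   `NULL` when `sw2`, `sb2` and `n_rep` are given directly.
#' @param sw2,sb2,n_rep Variance components and replicate count, if already
#'   known.
#' @param config An [analysis_config()] (for the sb2 floor).
#' @return One-row tibble: `R0`, `sw2`, `sb2`, `lambda` (sw2/sb2), `n_rep`,
#'   `R1`, `capped`.
#' @export
deattenuate <- function(R0, replicates = NULL, sw2 = NULL, sb2 = NULL, n_rep = NULL,
                        config = analysis_config()) {
  config <- as_analysis_config(config)
  stopifnot(abs(R0) <= 1)
  if (!is.null(replicates)) {
    vc <- variance_components(replicates, sb2_epsilon = config$sb2_epsilon)
    sw2 <- vc$sw2; sb2 <- vc$sb2; n_rep <- n_rep %||% vc$k0
  }
  stopifnot(!is.null(sw2), !is.null(sb2), !is.null(n_rep), sw2 >= 0, sb2 > 0, n_rep > 0)
  R1 <- R0 * sqrt(1 + (sw2 / sb2) / n_rep)
  tibble::tibble(
    R0 = R0, sw2 = sw2, sb2 = sb2, lambda = sw2 / sb2, n_rep = n_rep,
    R1 = R1, capped = abs(R1) > 1
  )
}

quartile_assign <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  q <- floor(4 * (r - 0.5) / n) + 1
  pmin(pmax(q, 1L), 4L)
}

#' Quartile cross-classification of two methods
#'
#' Each participant is assigned to a quartile of the distribution under each
#' method (ranks with average ties, quartile `floor(4*(rank - 0.5)/n) + 1`).
#' Agreement is summarized as the percentage classified into the same
#' quartile (exact), the same or adjacent quartile (exact plus adjacent,
#' inclusive of exact), two quartiles apart (disagreement) and three apart
#' (extreme disagreement).
#'
#' @param a,b Aligned per-participant values from the two methods (`n >= 4`).
#' @return One-row tibble: `pct_exact`, `pct_exact_plus_adjacent`,
#'   `pct_disagreement`, `pct_extreme`, `n`.
#' @export
cross_classify <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 4) stop("cross-classification needs at least 4 pairs", call. = FALSE)
  d <- abs(quartile_assign(a) - quartile_assign(b))
  tibble::tibble(
    pct_exact = 100 * mean(d == 0),
    pct_exact_plus_adjacent = 100 * mean(d <= 1),
    pct_disagreement = 100 * mean(d == 2),
    pct_extreme = 100 * mean(d == 3),
    n = n
  )
}

#' Bland-Altman agreement analysis
#'
#' Limits of agreement on the per-participant differences `d = a - b`:
#' `mean(d) +/- k * SD(d)` with `k = 2` by default. The two methods are
#' called comparable when more than `ba_comparable_pct` (default 95) percent
#' of the differences fall within the limits.
#'
#' @param a,b Aligned per-participant values (`n >= 3`).
#' @param config An [analysis_config()] (`ba_k`, `ba_comparable_pct`).
#' @return Object of class `bland_altman`: a one-row tibble with
#'   `mean_difference`, `sd_difference`, `loa_low`, `loa_high`,
#'   `pct_within_loa`, `comparable`, `n`, and the per-participant plot data
#'   in `attr(, "points")` (columns `mean`, `difference`).
#' @export
bland_altman <- function(a, b, config = analysis_config()) {
  config <- as_analysis_config(config)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - config$ba_k * s
  hi <- m + config$ba_k * s
  pct <- 100 * mean(d >= lo & d <= hi)
  out <- tibble::tibble(
    mean_difference = m, sd_difference = s, loa_low = lo, loa_high = hi,
    pct_within_loa = pct, comparable = pct > config$ba_comparable_pct, n = n
  )
  attr(out, "points") <- tibble::tibble(mean = (a + b) / 2, difference = d)
  class(out) <- c("bland_altman", class(out))
  out
}

#' @rdname bland_altman
#' @param object,x A `bland_altman` result.
#' @param ... Unused.
#' @export
autoplot.bland_altman <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_difference, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high), linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of methods", y = "Difference (A - B)",
      subtitle = sprintf(
        "mean diff %.3g, limits [%.3g, %.3g], %.1f%% within",
        object$mean_difference, object$loa_low, object$loa_high, object$pct_within_loa
      )
    ) +
    ggplot2::theme_minimal()
}

#' Paired difference test with normality routing
#'
#' Tests whether two methods report systematically different values for the
#' same participants. The Shapiro-Wilk test on the differences routes to a
#' paired t-test (normal) or a Wilcoxon signed-rank test (otherwise; zero
#' differences dropped, average ranks for ties). When every difference is
#' zero the comparison is degenerate and is reported as `p = 1` with
#' `test_used = "none"` and `all_zero = TRUE`.
#'
#' @param a,b Aligned per-participant values (`n >= 3`).
#' @param config An [analysis_config()] (`normality_alpha`).
#' @return One-row tibble: `test_used`, `statistic`, `p`, `n`, `all_zero`.
#' @export
paired_difference_test <- function(a, b, config = analysis_config()) {
  config <- as_analysis_config(config)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("paired test needs at least 3 pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    return(tibble::tibble(
      test_used = "none", statistic = NA_real_, p = 1, n = length(d), all_zero = TRUE
    ))
  }
  route <- if (stats::sd(d) == 0) "nonparametric" else normality_route(d, config$normality_alpha)
  if (route == "parametric") {
    t <- stats::t.test(a, b, paired = TRUE)
    tibble::tibble(
      test_used = "paired_t", statistic = unname(t$statistic), p = t$p.value,
      n = length(d), all_zero = FALSE
    )
  } else {
    w <- suppressWarnings(stats::wilcox.test(d[d != 0], exact = FALSE, correct = TRUE))
    tibble::tibble(
      test_used = "wilcoxon_signed_rank", statistic = unname(w$statistic), p = w$p.value,
      n = length(d), all_zero = FALSE
    )
  }
}

#' Independent-samples difference test
#'
#' Two-sample t-test on group means (equal-variance pooled test by default,
#' Welch's correction behind the config flag), as used for daily food-group
#' intakes.
#'
#' @param a,b Numeric vectors, `n >= 3` each.
#' @param config An [analysis_config()] (`welch`).
#' @return One-row tibble: `test_used`, `statistic`, `p`, `n_a`, `n_b`.
#' @export
independent_difference_test <- function(a, b, config = analysis_config()) {
  config <- as_analysis_config(config)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("independent test needs at least 3 values per group", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(tibble::tibble(
      test_used = "none", statistic = NA_real_,
      p = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0,
      n_a = length(a), n_b = length(b)
    ))
  }
  t <- stats::t.test(a, b, var.equal = !config$welch)
  tibble::tibble(
    test_used = if (config$welch) "welch_t" else "independent_t",
    statistic = unname(t$statistic), p = t$p.value, n_a = length(a), n_b = length(b)
  )
}

#' Screen a 24-hour urine collection for completeness
#'
#' A collection is excluded when the participant reported more than the
#' allowed number of missed voids, the total volume is below the minimum, or
#' the creatinine index (observed over expected urinary creatinine excretion)
#' falls outside the configured bounds. Expected excretion is
#' `norm(sex) * weight_kg` with sex-specific norms in mg/kg/day; observed
#' creatinine in mmol/d is converted at 113.12 mg/mmol. All triggered reasons
#' are reported, not just the first.
#'
#' @param record One biomarker record: list or one-row data frame with
#'   `missed_voids`, `urine_volume_l`, `creatinine_mmol_d` and (when the
#'   index check is enabled) `sex` ("male"/"female") and `weight_kg`.
#' @param config An [analysis_config()].
#' @param check_creatinine_index Enable the creatinine-index screen.
#' @return List: `included` (logical), `reasons` (character),
#'   `creatinine_index` (NA when not checked).
#' @export
urine_completeness <- function(record, config = analysis_config(),
                               check_creatinine_index = TRUE) {
  config <- as_analysis_config(config)
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  reasons <- character(0)
  if (!is.null(record$missed_voids) && !is.na(record$missed_voids) &&
    record$missed_voids > config$missed_void_max) {
    reasons <- c(reasons, sprintf("missed voids > %d", config$missed_void_max))
  }
  if (!is.null(record$urine_volume_l) && !is.na(record$urine_volume_l) &&
    record$urine_volume_l < config$urine_volume_min_l) {
    reasons <- c(reasons, sprintf("volume<%sL", format(config$urine_volume_min_l)))
  }
  index <- NA_real_
  if (check_creatinine_index) {
    if (is.null(record$sex) || is.null(record$weight_kg) ||
      is.na(record$sex) || is.na(record$weight_kg)) {
      stop("creatinine index check requires sex and weight_kg", call. = FALSE)
    }
    norm <- config$creatinine_mg_per_kg[[match.arg(record$sex, c("male", "female"))]]
    expected_mg <- norm * record$weight_kg
    observed_mg <- record$creatinine_mmol_d * config$creatinine_mg_per_mmol
    index <- observed_mg / expected_mg
    if (index < config$creatinine_index_bounds[1] || index > config$creatinine_index_bounds[2]) {
      reasons <- c(reasons, sprintf(
        "creatinine index %.2f outside [%s, %s]", index,
        format(config$creatinine_index_bounds[1]), format(config$creatinine_index_bounds[2])
      ))
    }
  }
  list(included = length(reasons) == 0, reasons = reasons, creatinine_index = index)
}

#' Estimate sodium intake from 24-h urinary sodium
#'
#' Urinary sodium represents only part of sodium consumed; the intake
#' estimate divides the excreted amount by the excretion fraction (default
#' 0.90) and converts mmol to mg at 23 mg/mmol.
#'
#' @param urinary_na_mmol_d Non-negative urinary sodium (mmol/day).
#' @param config An [analysis_config()] (`sodium_excretion_fraction`).
#' @return Tibble: `intake_mmol_d`, `intake_mg_d`.
#' @export
sodium_intake_estimate <- function(urinary_na_mmol_d, config = analysis_config()) {
  config <- as_analysis_config(config)
  if (any(urinary_na_mmol_d < 0, na.rm = TRUE)) {
    stop("urinary sodium cannot be negative", call. = FALSE)
  }
  mmol <- urinary_na_mmol_d / config$sodium_excretion_fraction
  tibble::tibble(intake_mmol_d = mmol, intake_mg_d = mmol * 23)
}

#' Summarize evaluation-questionnaire counts as percentages
#'
#' @param counts Named non-negative counts (or a two-column data frame
#'   `category`, `count`); total must be positive.
#' @return Tibble `category`, `count`, `pct` with percentages rounded
#'   half-up to one decimal.
#' @export
summarize_proportions <- function(counts) {
  if (is.data.frame(counts)) counts <- setNames(counts$count, counts$category)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  tibble::tibble(
    category = names(counts),
    count = as.numeric(counts),
    pct = round_half_up(100 * as.numeric(counts) / total, 1)
  )
}
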