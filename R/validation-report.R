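#' Default biomarker-to-intake pairings
#'
#' The standard pairings between recovery/concentration biomarkers and the
#' dietary variables they track: urinary urea with protein, urinary potassium
#' with potassium, corrected urinary sodium with sodium, plasma ascorbic acid
#' with vitamin C and with fruit-and-vegetable intake, plasma carotenoids
#' with fruit-and-vegetable intake, and the omega-3 index with fish intake.
#'
#' @return Tibble with columns `biomarker` (record column name), `sample`
#'   (`"urine"`/`"plasma"`), `variables` (list-column of intake variables to
#'   sum), `kind`, `corrected` (apply the sodium excretion correction) and a
#'   human-readable `pairing` label.
#' @export
default_biomarker_pairings <- function() {
  tibble::tibble(
    biomarker = c(
      "urea_mmol_d", "potassium_mmol_d", "sodium_mmol_d",
      "ascorbic_acid_umol_l", "ascorbic_acid_umol_l", "carotenoids_umol_l",
      "omega3_index"
    ),
    sample = c("urine", "urine", "urine", "plasma", "plasma", "plasma", "plasma"),
    variables = list(
      "protein", "potassium", "sodium",
      "vitamin_c", c("Fruit and fruit dishes", "Veg and veg dishes"),
      c("Fruit and fruit dishes", "Veg and veg dishes"),
      "Fish and fish dishes"
    ),
    kind = c(
      "nutrient", "nutrient", "nutrient", "nutrient", "food_group",
      "food_group", "food_group"
    ),
    corrected = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    pairing = c(
      "urinary urea ~ protein (g/d)",
      "urinary potassium ~ potassium (mg/d)",
      "urinary sodium (corrected) ~ sodium (mg/d)",
      "plasma ascorbic acid ~ vitamin C (mg/d)",
      "plasma ascorbic acid ~ fruit and veg (g/d)",
      "plasma carotenoids ~ fruit and veg (g/d)",
      "omega-3 index ~ fish (g/d)"
    )
  )
}

#' Correlate biomarkers with reported intake
#'
#' Spearman correlations between biomarker measures and per-participant mean
#' daily intakes under one assessment method. Participants flagged as
#' supplement users are excluded (both urinary and plasma analyses);
#' incomplete 24-hour urine collections (missed voids, low volume, creatinine
#' index out of bounds) are additionally excluded from urinary pairings.
#'
#' @param means Per-participant means tibble (`participant_id`, `variable`,
#'   `kind`, `mean`), e.g. `method_dataset(...)$means`.
#' @param biomarkers Tibble with one row per participant: `participant_id`,
#'   `supplement_user`, urine fields (`urine_volume_l`, `missed_voids`,
#'   `urea_mmol_d`, `sodium_mmol_d`, `potassium_mmol_d`,
#'   `creatinine_mmol_d`), plasma fields (`ascorbic_acid_umol_l`,
#'   `carotenoids_umol_l`, `omega3_index`) and, for the creatinine index,
#'   `sex` and `weight_kg`.
#' @param pairings Pairing table, see [default_biomarker_pairings()].
#' @param config An [analysis_config()].
#' @param exclude_supplement_users Drop flagged supplement users.
#' @param check_creatinine_index Enable the creatinine-index urine screen.
#' @return Tibble with one row per pairing: `pairing`, `biomarker`, `sample`,
#'   `spearman_rho`, `p`, `n`, `strength`, `n_excluded_supplement`,
#'   `n_excluded_urine`.
#' @export
biomarker_correlation <- function(means, biomarkers,
                                  pairings = default_biomarker_pairings(),
                                  config = analysis_config(),
                                  exclude_supplement_users = TRUE,
                                  check_creatinine_index = TRUE) {
  config <- as_analysis_config(config)
  biomarkers <- tibble::as_tibble(biomarkers)
  stopifnot("participant_id" %in% names(biomarkers))
  if (!"supplement_user" %in% names(biomarkers)) biomarkers$supplement_user <- FALSE

  urine_ok <- vapply(seq_len(nrow(biomarkers)), function(i) {
    rec <- as.list(biomarkers[i, , drop = FALSE])
    if (is.null(rec$urine_volume_l)) return(TRUE)
    urine_completeness(rec, config, check_creatinine_index = check_creatinine_index)$included
  }, logical(1))

  out <- list()
  for (j in seq_len(nrow(pairings))) {
    p <- pairings[j, ]
    keep <- rep(TRUE, nrow(biomarkers))
    n_sup <- 0L
    if (exclude_supplement_users) {
      n_sup <- sum(biomarkers$supplement_user & keep)
      keep <- keep & !biomarkers$supplement_user
    }
    n_ur <- 0L
    if (p$sample == "urine") {
      n_ur <- sum(!urine_ok & keep)
      keep <- keep & urine_ok
    }
    bm <- biomarkers[[p$biomarker]][keep]
    if (p$corrected) bm <- sodium_intake_estimate(bm, config)$intake_mg_d
    intake <- means |>
      dplyr::filter(
        .data$kind == p$kind, .data$variable %in% p$variables[[1]],
        .data$participant_id %in% biomarkers$participant_id[keep]
      ) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(intake = sum(.data$mean), .groups = "drop")
    idx <- match(biomarkers$participant_id[keep], intake$participant_id)
    x <- intake$intake[idx]
    ok <- !is.na(x) & !is.na(bm)
    if (sum(ok) < 3) {
      stop(sprintf("fewer than 3 participants left for pairing '%s'", p$pairing), call. = FALSE)
    }
    ct <- suppressWarnings(stats::cor.test(bm[ok], x[ok], method = "spearman", exact = FALSE))
    out[[j]] <- tibble::tibble(
      pairing = p$pairing, biomarker = p$biomarker, sample = p$sample,
      spearman_rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
      strength = classify_correlation(unname(ct$estimate)),
      n_excluded_supplement = n_sup, n_excluded_urine = n_ur
    )
  }
  dplyr::bind_rows(out)
}

means_wide <- function(md, participants) {
  md$means |>
    dplyr::filter(.data$participant_id %in% participants) |>
    dplyr::arrange(match(.data$participant_id, participants))
}

pull_variable <- function(means, var, knd, participants) {
  v <- means |>
    dplyr::filter(.data$variable == var, .data$kind == knd)
  v$mean[match(participants, v$participant_id)]
}

#' Build the full two-method validation report
#'
#' Assembles the complete agreement analysis between two assessment methods
#' into one structured object: per-nutrient means, raw and energy-adjusted
#' correlations with strength labels, deattenuated coefficients (variance
#' components from method A's replicate days), normality-routed paired
#' difference tests, quartile cross-classification, Bland-Altman analysis for
#' the macronutrient panel; per-food-group means, difference tests and
#' cross-classification; biomarker correlations with exclusion bookkeeping;
#' and evaluation-questionnaire proportion summaries.
#'
#' @param method_a,method_b [method_dataset()] objects covering the same
#'   participants (method A is the replicate-based method whose day-to-day
#'   variance drives deattenuation).
#' @param biomarkers Optional biomarker tibble, see [biomarker_correlation()].
#' @param evaluation_counts Optional tibble `question`, `category`, `count`.
#' @param config An [analysis_config()].
#' @param ba_variables Nutrients given a Bland-Altman analysis.
#' @param group_test `"independent"` (convention for daily food-group
#'   intakes) or `"paired"`; the report records which was used.
#' @param check_creatinine_index Passed to [biomarker_correlation()].
#' @return Object of class `validation_report`.
#' @export
build_validation_report <- function(method_a, method_b,
                                    biomarkers = NULL,
                                    evaluation_counts = NULL,
                                    config = analysis_config(),
                                    ba_variables = c(
                                      "energy", "protein", "carbohydrate",
                                      "fat", "fiber"
                                    ),
                                    group_test = c("independent", "paired"),
                                    check_creatinine_index = TRUE) {
  stopifnot(inherits(method_a, "method_dataset"), inherits(method_b, "method_dataset"))
  config <- as_analysis_config(config)
  group_test <- match.arg(group_test)
  pa <- sort(unique(method_a$means$participant_id))
  pb <- sort(unique(method_b$means$participant_id))
  if (!identical(pa, pb)) {
    stop(
      "participant misalignment between methods: only in A: [",
      paste(setdiff(pa, pb), collapse = ", "), "]; only in B: [",
      paste(setdiff(pb, pa), collapse = ", "), "]",
      call. = FALSE
    )
  }
  participants <- pa
  ma <- means_wide(method_a, participants)
  mb <- means_wide(method_b, participants)
  energy_a <- pull_variable(ma, "energy", "nutrient", participants)
  energy_b <- pull_variable(mb, "energy", "nutrient", participants)

  variables <- ma |>
    dplyr::distinct(.data$variable, .data$kind)
  nutrients <- variables$variable[variables$kind == "nutrient"]
  groups <- variables$variable[variables$kind == "food_group"]

  safe_cor <- function(...) {
    tryCatch(correlate_methods(...), error = function(e) {
      tibble::tibble(
        pearson_r = NA_real_, pearson_p = NA_real_, spearman_rho = NA_real_,
        spearman_p = NA_real_, n = NA_integer_, mode = NA_character_
      )
    })
  }

  rep_days_a <- method_a$days

  nut_rows <- purrr::map(nutrients, function(v) {
    a <- pull_variable(ma, v, "nutrient", participants)
    b <- pull_variable(mb, v, "nutrient", participants)
    raw <- safe_cor(a, b, mode = "raw", config = config)
    adj <- safe_cor(a, b,
      mode = "energy_adjusted", variable = v,
      energy_a = energy_a, energy_b = energy_b, config = config
    )
    deatt <- tibble::tibble(R1 = NA_real_, lambda = NA_real_, n_rep = NA_real_, capped = NA)
    if (!is.na(raw$pearson_r)) {
      reps <- rep_days_a |>
        dplyr::filter(.data$variable == v, .data$kind == "nutrient") |>
        dplyr::transmute(.data$participant_id, value = .data$food_only)
      deatt <- tryCatch(
        deattenuate(raw$pearson_r, replicates = reps, config = config)[
          , c("R1", "lambda", "n_rep", "capped")
        ],
        error = function(e) deatt
      )
    }
    dt <- paired_difference_test(a, b, config)
    cc <- cross_classify(a, b)
    tibble::tibble(
      variable = v,
      mean_a = mean(a), sd_a = stats::sd(a),
      mean_b = mean(b), sd_b = stats::sd(b),
      pearson_r = raw$pearson_r, pearson_p = raw$pearson_p,
      spearman_rho = raw$spearman_rho, spearman_p = raw$spearman_p,
      pearson_r_adj = adj$pearson_r, pearson_p_adj = adj$pearson_p,
      spearman_rho_adj = adj$spearman_rho, spearman_p_adj = adj$spearman_p,
      strength_raw = classify_correlation(raw$pearson_r),
      strength_adjusted = classify_correlation(adj$pearson_r),
      R1 = deatt$R1, lambda = deatt$lambda, n_rep = deatt$n_rep, capped = deatt$capped,
      test_used = dt$test_used, diff_statistic = dt$statistic, diff_p = dt$p,
      no_difference = dt$all_zero,
      pct_exact = cc$pct_exact, pct_exact_plus_adjacent = cc$pct_exact_plus_adjacent,
      pct_disagreement = cc$pct_disagreement, pct_extreme = cc$pct_extreme,
      n = length(a)
    )
  }) |> dplyr::bind_rows()

  grp_rows <- purrr::map(groups, function(v) {
    a <- pull_variable(ma, v, "food_group", participants)
    b <- pull_variable(mb, v, "food_group", participants)
    dt <- if (group_test == "independent") {
      independent_difference_test(a, b, config) |>
        dplyr::transmute(.data$test_used, statistic = .data$statistic, p = .data$p)
    } else {
      paired_difference_test(a, b, config) |>
        dplyr::transmute(.data$test_used, statistic = .data$statistic, p = .data$p)
    }
    cc <- cross_classify(a, b)
    raw <- safe_cor(a, b, mode = "raw", config = config)
    tibble::tibble(
      food_group = v,
      mean_a = mean(a), sd_a = stats::sd(a),
      mean_b = mean(b), sd_b = stats::sd(b),
      spearman_rho = raw$spearman_rho, spearman_p = raw$spearman_p,
      test_used = dt$test_used, diff_statistic = dt$statistic, diff_p = dt$p,
      pct_exact = cc$pct_exact, pct_exact_plus_adjacent = cc$pct_exact_plus_adjacent,
      pct_disagreement = cc$pct_disagreement, pct_extreme = cc$pct_extreme,
      n = length(a)
    )
  }) |> dplyr::bind_rows()

  ba_rows <- list()
  ba_points <- list()
  for (v in intersect(ba_variables, nutrients)) {
    a <- pull_variable(ma, v, "nutrient", participants)
    b <- pull_variable(mb, v, "nutrient", participants)
    ba <- bland_altman(a, b, config)
    pts <- attr(ba, "points")
    pts$participant_id <- participants
    pts$variable <- v
    ba_rows[[v]] <- tibble::as_tibble(ba) |> dplyr::mutate(variable = v, .before = 1)
    ba_points[[v]] <- pts[, c("variable", "participant_id", "mean", "difference")]
  }

  bio <- NULL
  if (!is.null(biomarkers)) {
    bio <- dplyr::bind_rows(
      biomarker_correlation(method_a$means, biomarkers,
        config = config,
        check_creatinine_index = check_creatinine_index
      ) |> dplyr::mutate(method = method_a$method, .before = 1),
      biomarker_correlation(method_b$means, biomarkers,
        config = config,
        check_creatinine_index = check_creatinine_index
      ) |> dplyr::mutate(method = method_b$method, .before = 1)
    )
  }

  eval_tbl <- NULL
  if (!is.null(evaluation_counts)) {
    evaluation_counts <- tibble::as_tibble(evaluation_counts)
    eval_tbl <- evaluation_counts |>
      dplyr::group_by(.data$question) |>
      dplyr::group_modify(~ summarize_proportions(setNames(.x$count, .x$category))) |>
      dplyr::ungroup()
  }

  structure(
    list(
      methods = c(a = method_a$method, b = method_b$method),
      n_participants = length(participants),
      participants = participants,
      nutrients = nut_rows,
      food_groups = grp_rows,
      bland_altman = dplyr::bind_rows(ba_rows),
      ba_points = dplyr::bind_rows(ba_points),
      biomarkers = bio,
      evaluation = eval_tbl,
      group_test = group_test,
      config = unclass(config)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s vs %s, n=%d\n", x$methods[["a"]], x$methods[["b"]],
    x$n_participants
  ))
  cat(sprintf(
    "  nutrients: %d | food groups: %d | Bland-Altman: %d | biomarker pairings: %d\n",
    nrow(x$nutrients), nrow(x$food_groups), nrow(x$bland_altman),
    if (is.null(x$biomarkers)) 0L else nrow(x$biomarkers)
  ))
  invisible(x)
}

#' Tidy one block of a validation report
#'
#' @param x A `validation_report`.
#' @param block `"nutrients"`, `"food_groups"`, `"bland_altman"`,
#'   `"ba_points"`, `"biomarkers"` or `"evaluation"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.validation_report <- function(x, block = c(
                                     "nutrients", "food_groups", "bland_altman",
                                     "ba_points", "biomarkers", "evaluation"
                                   ), ...) {
  block <- match.arg(block)
  out <- x[[block]]
  if (is.null(out)) {
    stop(sprintf("report has no '%s' block", block), call. = FALSE)
  }
  out
}

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Tibble: participant count, number of nutrients/groups analysed,
#'   median raw Pearson r, share of nutrients at least "acceptable", share of
#'   Bland-Altman panels meeting the comparability rule.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    method_a = x$methods[["a"]], method_b = x$methods[["b"]],
    n_participants = x$n_participants,
    n_nutrients = nrow(x$nutrients),
    n_food_groups = nrow(x$food_groups),
    median_pearson_r = stats::median(x$nutrients$pearson_r, na.rm = TRUE),
    pct_acceptable_or_better = 100 * mean(
      x$nutrients$strength_raw %in% c("acceptable", "good", "very_good"),
      na.rm = TRUE
    ),
    pct_ba_comparable = if (nrow(x$bland_altman) > 0) {
      100 * mean(x$bland_altman$comparable)
    } else {
      NA_real_
    }
  )
}

#' Bland-Altman panel plot for a validation report
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot faceted by nutrient.
#' @export
autoplot.validation_report <- function(object, ...) {
  if (nrow(object$ba_points) == 0) stop("report has no Bland-Altman points", call. = FALSE)
  lims <- object$bland_altman
  ggplot2::ggplot(object$ba_points, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(
      data = lims, ggplot2::aes(yintercept = .data$mean_difference)
    ) +
    ggplot2::geom_hline(
      data = tidyr::pivot_longer(lims[, c("variable", "loa_low", "loa_high")],
        c("loa_low", "loa_high"),
        names_to = "limit", values_to = "y"
      ),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(
      x = "Mean of methods", y = sprintf("Difference (%s - %s)", object$methods[["a"]], object$methods[["b"]]),
      title = "Bland-Altman limits of agreement"
    ) +
    ggplot2::theme_minimal()
}

#' Write a validation report to disk
#'
#' Writes `report.json` (the whole report, round-trippable with
#' [read_validation_report()]) plus one CSV per block: `nutrients.csv`,
#' `food_groups.csv`, `bland_altman.csv`, `bland_altman_points.csv` and,
#' when present, `biomarkers.csv` and `evaluation.csv`.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obj <- unclass(report)
  obj$methods <- as.list(obj$methods) # keep the a/b names in JSON
  jsonlite::write_json(obj, file.path(dir, "report.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  readr::write_csv(report$nutrients, file.path(dir, "nutrients.csv"), progress = FALSE)
  readr::write_csv(report$food_groups, file.path(dir, "food_groups.csv"), progress = FALSE)
  readr::write_csv(report$bland_altman, file.path(dir, "bland_altman.csv"), progress = FALSE)
  readr::write_csv(report$ba_points, file.path(dir, "bland_altman_points.csv"), progress = FALSE)
  if (!is.null(report$biomarkers)) {
    readr::write_csv(report$biomarkers, file.path(dir, "biomarkers.csv"), progress = FALSE)
  }
  if (!is.null(report$evaluation)) {
    readr::write_csv(report$evaluation, file.path(dir, "evaluation.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' Read a validation report written by [write_validation_report()]
#'
#' @param path Path to `report.json` (or the directory holding it).
#' @return A `validation_report`.
#' @export
read_validation_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (block in c("nutrients", "food_groups", "bland_altman", "ba_points", "biomarkers", "evaluation")) {
    if (!is.null(obj[[block]]) && length(obj[[block]]) > 0) {
      obj[[block]] <- tibble::as_tibble(obj[[block]])
    } else {
      obj[[block]] <- NULL
    }
  }
  obj$methods <- unlist(obj$methods)
  obj$participants <- unlist(obj$participants)
  for (nm in c("energy_factors", "creatinine_mg_per_kg", "creatinine_index_bounds")) {
    obj$config[[nm]] <- unlist(obj$config[[nm]])
  }
  structure(obj, class = "validation_report")
}
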