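# run expr with a temporary RNG state seeded at `seed` (caller state restored)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# sd of log for a multiplicative (lognormal) error with coefficient of
# variation cv; meanlog chosen so the factor has mean 1
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))
rfactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- lnorm_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

default_nutrient_gm <- function() {
  c(
    energy = 2000, protein = 80, carbohydrate = 230, sugars = 90, starch = 130,
    fiber = 20, fat = 75, saturated_fat = 28, monounsaturated_fat = 26,
    polyunsaturated_fat = 13, retinol = 400, carotene = 2000, vitamin_d = 3,
    vitamin_b12 = 4, folate = 250, vitamin_e = 8, riboflavin = 1.6, niacin = 35,
    vitamin_b6 = 1.9, vitamin_c = 80, calcium = 900, magnesium = 280, iron = 11,
    copper = 1.2, zinc = 9, potassium = 3000, sodium = 2800
  )
}

default_group_gm <- function() {
  setNames(
    c(180, 95, 100, 50, 250, 70, 30, 12, 90, 140, 200, 300, 75, 250, 900,
      1600, 65, 110, 25),
    default_food_groups()
  )
}

#' Simulation configuration
#'
#' Defines the statistical structure of a simulated validation cohort:
#' log-normal usual intakes between participants, log-normal day-to-day
#' variation within participants, multiplicative method-specific bias and
#' random error (with a shared per-day factor so errors correlate across
#' nutrients, as portion-size error does), biomarkers linearly related to
#' intake with noise, and the missingness processes the urine-completeness
#' screen reacts to.
#'
#' The default cohort mirrors a small validation study: 39 participants, 3
#' non-consecutive recall days for the test method against a 4-day diary
#' reference, geometric SD 1.3 between participants and a 25% within-person
#' day-to-day CV (a between/within variance ratio near 1 on the log scale).
#'
#' @param n_participants Cohort size.
#' @param n_recall_days Replicate days for the recall method.
#' @param n_diary_days Replicate days for the diary method.
#' @param nutrient_gm,group_gm Named geometric means of usual daily intakes.
#' @param nutrient_gsd,group_gsd Geometric SD of usual intakes between
#'   participants (scalar or named per variable).
#' @param within_cv Within-person day-to-day CV of true intake.
#' @param method_profiles Named list per method; each a list with `bias`
#'   (scalar or named multiplicative bias per variable), `noise_cv`
#'   (per-variable random error CV) and `shared_day_cv` (CV of the per-day
#'   factor shared across variables).
#' @param biomarker List of biomarker-model constants: `urea_mmol_per_g_protein`,
#'   `sodium_fraction`, `potassium_fraction`, recovery noise CV, plasma
#'   intercepts/slopes/noise SDs, creatinine noise CV.
#' @param missed_void_prob Probability a urine collection has an excludable
#'   number of missed voids.
#' @param low_volume_prob Probability of an excludably low urine volume.
#' @param supplement_user_frac Fraction flagged as supplement users.
#' @param female_frac Fraction female.
#' @param weight_mean,weight_sd Body weight (kg) distribution,
#'   `c(male=, female=)`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 39,
                              n_recall_days = 3,
                              n_diary_days = 4,
                              nutrient_gm = default_nutrient_gm(),
                              nutrient_gsd = 1.3,
                              group_gm = default_group_gm(),
                              group_gsd = 1.5,
                              within_cv = 0.25,
                              method_profiles = list(
                                recall = list(bias = 1, noise_cv = 0.15, shared_day_cv = 0.10),
                                diary = list(bias = 1, noise_cv = 0.10, shared_day_cv = 0.08)
                              ),
                              biomarker = list(
                                urea_mmol_per_g_protein = 4.86,
                                sodium_fraction = 0.90,
                                potassium_fraction = 0.77,
                                recovery_noise_cv = 0.25,
                                ascorbic_intercept = 20, ascorbic_slope = 0.45,
                                ascorbic_noise_sd = 15,
                                carotenoid_intercept = 0.5, carotenoid_slope = 0.003,
                                carotenoid_noise_sd = 0.45,
                                omega3_intercept = 4, omega3_slope = 0.025,
                                omega3_noise_sd = 1.2,
                                creatinine_noise_cv = 0.08
                              ),
                              missed_void_prob = 0.08,
                              low_volume_prob = 0.05,
                              supplement_user_frac = 0.3,
                              female_frac = 0.5,
                              weight_mean = c(male = 82, female = 68),
                              weight_sd = c(male = 11, female = 10)) {
  stopifnot(
    n_participants >= 1, n_recall_days >= 1, n_diary_days >= 1,
    all(nutrient_gm > 0), all(group_gm > 0),
    all(nutrient_gsd >= 1), all(group_gsd >= 1), within_cv >= 0,
    missed_void_prob >= 0, missed_void_prob <= 1,
    low_volume_prob >= 0, low_volume_prob <= 1,
    supplement_user_frac >= 0, supplement_user_frac <= 1,
    female_frac >= 0, female_frac <= 1
  )
  for (p in method_profiles) {
    stopifnot(all(p$bias > 0), p$noise_cv >= 0, p$shared_day_cv >= 0)
  }
  structure(
    list(
      n_participants = n_participants, n_recall_days = n_recall_days,
      n_diary_days = n_diary_days, nutrient_gm = nutrient_gm,
      nutrient_gsd = nutrient_gsd, group_gm = group_gm, group_gsd = group_gsd,
      within_cv = within_cv, method_profiles = method_profiles,
      biomarker = biomarker, missed_void_prob = missed_void_prob,
      low_volume_prob = low_volume_prob,
      supplement_user_frac = supplement_user_frac, female_frac = female_frac,
      weight_mean = weight_mean, weight_sd = weight_sd
    ),
    class = "simulation_config"
  )
}

as_simulation_config <- function(x) {
  if (inherits(x, "simulation_config")) return(x)
  if (is.null(x)) return(simulation_config())
  do.call(simulation_config, x)
}

#' Generate a synthetic food database
#'
#' Builds a loadable, internally consistent food/supplement database with the
#' structural features the recall engine exercises: every configured group
#' non-empty, configurable fractions of items carrying search tags, probe
#' questions (including substitution probes) and linked-food rules, a mix of
#' 3-image portion anchor sets and unit portions, and a supplement table with
#' categories. Identical `(arguments, seed)` give an identical database.
#'
#' @param n_items Number of food items (`>=` number of groups).
#' @param groups Food-group names (each receives at least one item).
#' @param seed Integer seed fixing all randomness.
#' @param frac_tagged,frac_probed,frac_linked,frac_image Fractions of items
#'   given tags, probes, linked rules and image (vs unit) portions.
#' @param n_supplements,n_supplement_categories Supplement table size.
#' @param schema Nutrient schema.
#' @return A validated `food_db`.
#' @export
generate_food_database <- function(n_items, groups = default_food_groups(), seed = 1,
                                   frac_tagged = 484 / 751, frac_probed = 123 / 751,
                                   frac_linked = 132 / 751, frac_image = 556 / 751,
                                   n_supplements = 30, n_supplement_categories = 6,
                                   schema = default_nutrient_schema()) {
  if (n_items < length(groups)) {
    stop("n_items must be at least the number of food groups", call. = FALSE)
  }
  ids <- nutrient_ids(schema)
  gm <- default_nutrient_gm()[ids]
  gm[is.na(gm)] <- 1
  with_seed(seed, {
    food_id <- sprintf("f%04d", seq_len(n_items))
    food_group <- c(groups, sample(groups, n_items - length(groups), replace = TRUE))
    description <- sprintf("synthetic %s item %03d", sub(",.*$", "", tolower(food_group)), seq_len(n_items))
    # per-100 g composition: daily geometric means scaled so ~2 kg of food a
    # day delivers them on average, with wide item-to-item spread
    comp <- vapply(ids, function(nid) {
      gm[[nid]] / 20 * stats::rlnorm(n_items, meanlog = -0.32, sdlog = 0.8)
    }, numeric(n_items))
    comp <- tibble::as_tibble(as.data.frame(comp))
    names(comp) <- ids

    portion_kind <- ifelse(stats::runif(n_items) < frac_image, "image", "unit")
    w2 <- stats::runif(n_items, 40, 300)
    w1 <- w2 * stats::runif(n_items, 0.4, 0.7)
    w3 <- w2 * stats::runif(n_items, 1.4, 2.0)
    unit_weight <- stats::runif(n_items, 5, 60)
    w1[portion_kind != "image"] <- NA
    w2[portion_kind != "image"] <- NA
    w3[portion_kind != "image"] <- NA
    unit_weight[portion_kind != "unit"] <- NA

    tags <- replicate(n_items, character(0), simplify = FALSE)
    tagged <- stats::runif(n_items) < frac_tagged
    tags[tagged] <- lapply(which(tagged), function(i) {
      paste0("alias-", food_id[i])
    })

    linked_ids <- replicate(n_items, character(0), simplify = FALSE)
    linked <- which(stats::runif(n_items) < frac_linked)
    for (i in linked) {
      k <- sample(1:3, 1)
      linked_ids[[i]] <- sample(setdiff(food_id, food_id[i]), k)
    }

    n_probes <- max(2, round(frac_probed * n_items / 4))
    probe_id <- sprintf("p%03d", seq_len(n_probes))
    probes <- tibble::tibble(
      probe_id = probe_id,
      prompt = sprintf("Was item %s homemade or retail?", probe_id),
      options = replicate(n_probes, c("homemade", "retail"), simplify = FALSE),
      effects = lapply(seq_len(n_probes), function(j) {
        # half the probes substitute a more specific item, half just annotate
        if (j %% 2 == 0) {
          list(
            homemade = list(kind = "tag", value = "homemade"),
            retail = list(kind = "substitute", value = sample(food_id, 1))
          )
        } else {
          list(
            homemade = list(kind = "tag", value = "homemade"),
            retail = list(kind = "tag", value = "retail")
          )
        }
      })
    )
    probe_ids <- replicate(n_items, character(0), simplify = FALSE)
    probed <- which(stats::runif(n_items) < frac_probed)
    for (i in probed) probe_ids[[i]] <- sample(probe_id, 1)

    foods <- tibble::tibble(
      food_id = food_id, description = description, food_group = food_group,
      category = food_group, tags = tags, linked_ids = linked_ids,
      probe_ids = probe_ids, portion_kind = portion_kind,
      w1 = w1, w2 = w2, w3 = w3, unit_weight = unit_weight
    )
    foods <- dplyr::bind_cols(foods, comp)

    cat_id <- sprintf("cat%02d", seq_len(n_supplement_categories))
    sup <- tibble::tibble(
      supplement_id = sprintf("s%03d", seq_len(n_supplements)),
      brand = sprintf("brand %03d", seq_len(n_supplements)),
      category_id = c(cat_id, sample(cat_id, n_supplements - n_supplement_categories, replace = TRUE))
    )
    supc <- vapply(ids, function(nid) {
      on <- stats::runif(n_supplements) < 0.3
      ifelse(on, gm[[nid]] * stats::runif(n_supplements, 0.1, 0.8), 0)
    }, numeric(n_supplements))
    sup <- dplyr::bind_cols(sup, tibble::as_tibble(as.data.frame(supc)))
    cats <- tibble::tibble(category_id = cat_id, name = paste("category", cat_id))

    food_db(
      foods = foods, probes = probes, supplements = sup,
      supplement_categories = cats, schema = schema, food_groups = groups
    )
  })
}

#' Simulate a cohort with log-normal usual intakes
#'
#' Draws each participant's usual (long-run true) daily intake of every
#' nutrient and food group from a log-normal distribution, plus sex and body
#' weight. Between-person spread is the geometric SD; a geometric SD of 1
#' makes all participants identical.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List of class `sim_cohort`: `participants` (tibble
#'   `participant_id`, `sex`, `weight_kg`) and `usual` (long tibble
#'   `participant_id`, `variable`, `kind`, `usual`).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  config <- as_simulation_config(config)
  n <- config$n_participants
  with_seed(seed, {
    pid <- sprintf("p%03d", seq_len(n))
    sex <- ifelse(stats::runif(n) < config$female_frac, "female", "male")
    weight <- ifelse(
      sex == "female",
      stats::rnorm(n, config$weight_mean[["female"]], config$weight_sd[["female"]]),
      stats::rnorm(n, config$weight_mean[["male"]], config$weight_sd[["male"]])
    )
    weight <- pmax(weight, 40)
    draw <- function(gm, gsd, kind) {
      gsd <- rep(gsd, length.out = length(gm))
      purrr::map2(names(gm), seq_along(gm), function(v, i) {
        tibble::tibble(
          participant_id = pid, variable = v, kind = kind,
          usual = stats::rlnorm(n, meanlog = log(gm[[i]]), sdlog = log(gsd[i]))
        )
      }) |> dplyr::bind_rows()
    }
    usual <- dplyr::bind_rows(
      draw(config$nutrient_gm, config$nutrient_gsd, "nutrient"),
      draw(config$group_gm, config$group_gsd, "food_group")
    )
    structure(
      list(
        participants = tibble::tibble(participant_id = pid, sex = sex, weight_kg = weight),
        usual = usual
      ),
      class = "sim_cohort"
    )
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d participants, %d variables\n",
    nrow(x$participants), dplyr::n_distinct(x$usual$variable)
  ))
  invisible(x)
}

#' Simulate replicate assessment days under a method's error profile
#'
#' Each day's reported value is
#' `usual x day-effect x shared-day factor x bias x noise`, all multiplicative
#' log-normal factors with mean 1 (except the bias), so reported intakes stay
#' positive and the long-run mean is `bias x usual`. The day-effect CV is the
#' true within-person variation; the shared-day factor applies to every
#' variable of one participant-day, correlating errors across nutrients the
#' way a portion-size misjudgement would.
#'
#' @param cohort A `sim_cohort`.
#' @param method Name of a profile in `config$method_profiles`.
#' @param n_days Number of replicate days (default: the config's recall or
#'   diary days, matched by profile name).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Daily-intake tibble (`participant_id`, `date`, `variable`, `kind`,
#'   `food_only`, `with_supplements`) directly consumable by
#'   [mean_daily_intake()] / [method_dataset()].
#' @export
simulate_method_days <- function(cohort, method, n_days = NULL,
                                 config = simulation_config(), seed = 1) {
  config <- as_simulation_config(config)
  profile <- config$method_profiles[[method]]
  if (is.null(profile)) stop(sprintf("no method profile '%s'", method), call. = FALSE)
  if (is.null(n_days)) {
    n_days <- if (method == "diary") config$n_diary_days else config$n_recall_days
  }
  usual <- cohort$usual
  vars <- dplyr::distinct(usual, .data$variable, .data$kind)
  bias <- profile$bias
  bias_for <- function(v) {
    if (is.null(names(bias))) {
      if (length(bias) == 1) bias else 1
    } else if (v %in% names(bias)) {
      bias[[v]]
    } else {
      1
    }
  }
  with_seed(seed, {
    out <- vector("list", n_days)
    pid <- cohort$participants$participant_id
    np <- length(pid)
    for (d in seq_len(n_days)) {
      shared <- setNames(rfactor(np, profile$shared_day_cv), pid)
      day <- usual
      day$date <- sprintf("%s-day%02d", method, d)
      day_effect <- rfactor(nrow(day), config$within_cv)
      noise <- rfactor(nrow(day), profile$noise_cv)
      b <- vapply(day$variable, bias_for, numeric(1))
      day$food_only <- as.numeric(
        day$usual * day_effect * shared[day$participant_id] * b * noise
      )
      day$with_supplements <- day$food_only
      out[[d]] <- day[, c(
        "participant_id", "date", "variable", "kind", "food_only", "with_supplements"
      )]
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate biomarker records for a cohort
#'
#' Recovery biomarkers (urinary urea, sodium, potassium) are a fixed fraction
#' or coefficient of recent intake with multiplicative noise; concentration
#' biomarkers (plasma ascorbic acid, carotenoids, omega-3 index) are linear
#' in usual intake with additive noise; creatinine is proportional to body
#' weight with sex-specific norms. Missed voids, low urine volumes and
#' supplement use are Bernoulli processes so the completeness screen and the
#' supplement-user exclusion have something to catch.
#'
#' @param cohort A `sim_cohort`.
#' @param recent_intakes Per-participant intake tibble used for the recovery
#'   markers (`participant_id`, `variable`, `kind`, `mean`), e.g.
#'   `mean_daily_intake()` output; defaults to the cohort's usual intakes.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Biomarker tibble matching the [biomarker_correlation()] schema.
#' @export
simulate_biomarkers <- function(cohort, recent_intakes = NULL,
                                config = simulation_config(), seed = 1) {
  config <- as_simulation_config(config)
  bm <- config$biomarker
  parts <- cohort$participants
  n <- nrow(parts)
  if (is.null(recent_intakes)) {
    recent_intakes <- cohort$usual |>
      dplyr::rename(mean = "usual")
  }
  getv <- function(v, knd) {
    x <- recent_intakes |>
      dplyr::filter(.data$variable %in% v, .data$kind == knd) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(val = sum(.data$mean), .groups = "drop")
    x$val[match(parts$participant_id, x$participant_id)]
  }
  with_seed(seed, {
    protein_g <- getv("protein", "nutrient")
    sodium_mg <- getv("sodium", "nutrient")
    potassium_mg <- getv("potassium", "nutrient")
    vitc_mg <- getv("vitamin_c", "nutrient")
    fruitveg_g <- getv(c("Fruit and fruit dishes", "Veg and veg dishes"), "food_group")
    fish_g <- getv("Fish and fish dishes", "food_group")
    cr_norm <- ifelse(parts$sex == "female", 18, 23)
    tibble::tibble(
      participant_id = parts$participant_id,
      sex = parts$sex,
      weight_kg = parts$weight_kg,
      urine_volume_l = ifelse(
        stats::runif(n) < config$low_volume_prob,
        stats::runif(n, 0.2, 0.45),
        stats::rlnorm(n, log(1.5), 0.25)
      ),
      missed_voids = ifelse(stats::runif(n) < config$missed_void_prob, 2L, 0L),
      urea_mmol_d = bm$urea_mmol_per_g_protein * protein_g * rfactor(n, bm$recovery_noise_cv),
      sodium_mmol_d = bm$sodium_fraction * (sodium_mg / 23) * rfactor(n, bm$recovery_noise_cv),
      potassium_mmol_d = bm$potassium_fraction * (potassium_mg / 39.1) *
        rfactor(n, bm$recovery_noise_cv),
      creatinine_mmol_d = cr_norm * parts$weight_kg / 113.12 *
        rfactor(n, bm$creatinine_noise_cv),
      ascorbic_acid_umol_l = pmax(
        bm$ascorbic_intercept + bm$ascorbic_slope * vitc_mg +
          stats::rnorm(n, 0, bm$ascorbic_noise_sd), 1
      ),
      carotenoids_umol_l = pmax(
        bm$carotenoid_intercept + bm$carotenoid_slope * fruitveg_g +
          stats::rnorm(n, 0, bm$carotenoid_noise_sd), 0.05
      ),
      omega3_index = pmax(
        bm$omega3_intercept + bm$omega3_slope * fish_g +
          stats::rnorm(n, 0, bm$omega3_noise_sd), 0.5
      ),
      supplement_user = stats::runif(n) < config$supplement_user_frac
    )
  })
}

# enumerate every portion option of a food row with its gram weight
portion_options <- function(row) {
  if (row$portion_kind == "image") {
    spec <- list(kind = "image", anchors = c(row$w1, row$w2, row$w3))
    grid <- expand.grid(
      image_index = 1:3,
      relation = c("less_than", "exactly", "greater_than"),
      stringsAsFactors = FALSE
    )
    grid$weight <- vapply(seq_len(nrow(grid)), function(i) {
      resolve_portion_weight(spec, portion_response(
        "image",
        image_index = grid$image_index[i], relation = grid$relation[i]
      ))
    }, numeric(1))
    grid$kind <- "image"
    grid$unit_count <- NA_real_
    grid
  } else {
    counts <- 1:3
    data.frame(
      image_index = NA_integer_, relation = NA_character_,
      weight = row$unit_weight * counts, kind = "unit", unit_count = counts
    )
  }
}

#' Compose finalized recall sessions hitting target energies
#'
#' Greedily assembles, for each requested participant-day, a finalized
#' session from the database whose computed energy lands within a tolerance
#' of the target: items are added with portion responses chosen from the
#' portion grid, never overshooting `(1 + tol)` times the target, until the
#' total reaches `(1 - tol)` of it. Probe questions are answered
#' deterministically with their first option (substitutions are resolved
#' before the item's energy is counted). Targets the database cannot span are
#' flagged rather than silently missed.
#'
#' @param db A `food_db`.
#' @param targets Tibble `participant_id`, `date`, `energy_kcal`.
#' @param seed Integer seed.
#' @param tol Relative energy tolerance (default 0.10).
#' @param max_items Safety cap on items per session.
#' @return List of finalized `recall_session`s, one per target row, with an
#'   `unreachable` attribute (logical vector) marking targets that could not
#'   be met; reaching them is also recorded per session in
#'   `attr(session, "achieved_kcal")`.
#' @export
simulate_recall_sessions <- function(db, targets, seed = 1, tol = 0.10, max_items = 60) {
  stopifnot(inherits(db, "food_db"), all(c("participant_id", "date", "energy_kcal") %in% names(targets)))
  foods <- db$foods
  # effective item after deterministic probe answering (first option)
  effective_id <- vapply(seq_len(nrow(foods)), function(i) {
    fid <- foods$food_id[i]
    for (pid in foods$probe_ids[[i]]) {
      p <- db$probes[db$probes$probe_id == pid, ]
      eff <- p$effects[[1]][[p$options[[1]][1]]]
      if (!is.null(eff) && identical(eff$kind, "substitute")) fid <- eff$value
    }
    fid
  }, character(1))
  opts <- purrr::map_dfr(seq_len(nrow(foods)), function(i) {
    g <- portion_options(foods[i, ])
    g$food_id <- foods$food_id[i]
    eff_row <- match(effective_id[i], foods$food_id)
    g$kcal <- g$weight / 100 * foods$energy[eff_row]
    g
  })
  opts <- opts[opts$kcal > 0, , drop = FALSE]
  min_kcal <- min(opts$kcal)

  unreachable <- logical(nrow(targets))
  sessions <- vector("list", nrow(targets))
  with_seed(seed, {
    for (r in seq_len(nrow(targets))) {
      target <- targets$energy_kcal[r]
      lo <- (1 - tol) * target
      hi <- (1 + tol) * target
      s <- start_session(targets$participant_id[r], targets$date[r])
      s <- add_meal(s, "breakfast", "08:00", "home")
      s <- add_meal(s, "lunch", "13:00", "workplace/other")
      s <- add_meal(s, "dinner", "19:00", "home")
      total <- 0
      n_items <- 0L
      while (total < lo && n_items < max_items) {
        feasible <- which(opts$kcal <= hi - total)
        if (length(feasible) == 0) break
        j <- feasible[sample.int(length(feasible), 1)]
        meal <- sample.int(3, 1)
        s <- add_food(s, meal, opts$food_id[j], db)
        ei <- length(s$meals[[meal]]$food_entries)
        entry <- s$meals[[meal]]$food_entries[[ei]]
        for (pid in entry$pending_probes) {
          p <- db$probes[db$probes$probe_id == pid, ]
          s <- answer_probe(s, meal, ei, pid, p$options[[1]][1], db)
        }
        resp <- if (opts$kind[j] == "image") {
          portion_response("image",
            image_index = opts$image_index[j],
            relation = opts$relation[j]
          )
        } else {
          portion_response("unit", unit_count = opts$unit_count[j])
        }
        s <- set_portion(s, meal, ei, resp, db)
        # recompute from the entry actually stored (substitution may have
        # changed the item, and with it the energy density)
        e2 <- s$meals[[meal]]$food_entries[[ei]]
        erow <- match(e2$food_id, foods$food_id)
        total <- total + e2$resolved_weight_g / 100 * foods$energy[erow]
        n_items <- n_items + 1L
      }
      s <- finalize_session(s, usual_intake_flag = "usual")
      attr(s, "achieved_kcal") <- total
      unreachable[r] <- total < lo || total > hi
      sessions[[r]] <- s
    }
  })
  if (min_kcal > 0 && any(unreachable)) {
    warning(sprintf("%d of %d targets unreachable within tolerance", sum(unreachable), length(unreachable)))
  }
  attr(sessions, "unreachable") <- unreachable
  sessions
}

#' Write a full synthetic study to a directory
#'
#' One-call generator for an end-to-end pipeline run: food database (CSV and
#' JSON), per-method daily intake CSVs, per-method means CSVs and a biomarker
#' CSV, all derived from one seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param n_db_items Food database size.
#' @return Invisibly, a list with the in-memory objects (`db`, `cohort`,
#'   `days` per method, `biomarkers`) and the file paths written.
#' @export
simulate_study <- function(out_dir, config = simulation_config(), seed = 1,
                           n_db_items = 120) {
  config <- as_simulation_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  db <- generate_food_database(n_db_items, seed = seed)
  cohort <- simulate_cohort(config, seed = seed + 1)
  methods <- names(config$method_profiles)
  days <- lapply(seq_along(methods), function(i) {
    simulate_method_days(cohort, methods[i], config = config, seed = seed + 1 + i)
  })
  names(days) <- methods
  first_means <- mean_daily_intake(days[[1]])
  biomarkers <- simulate_biomarkers(cohort, first_means, config, seed = seed + 100)
  paths <- list(
    db_csv = file.path(out_dir, "food_db.csv"),
    db_json = file.path(out_dir, "food_db.json"),
    biomarkers = file.path(out_dir, "biomarkers.csv")
  )
  write_food_db(db, paths$db_csv)
  write_food_db(db, paths$db_json)
  readr::write_csv(biomarkers, paths$biomarkers, progress = FALSE)
  for (m in methods) {
    paths[[paste0("days_", m)]] <- file.path(out_dir, sprintf("intakes_%s.csv", m))
    write_intakes(days[[m]], paths[[paste0("days_", m)]])
    paths[[paste0("means_", m)]] <- file.path(out_dir, sprintf("means_%s.csv", m))
    readr::write_csv(mean_daily_intake(days[[m]]), paths[[paste0("means_", m)]], progress = FALSE)
  }
  invisible(list(
    db = db, cohort = cohort, days = days, biomarkers = biomarkers, paths = paths
  ))
}
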