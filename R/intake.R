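#' Compute the daily intake of a finalized session
#'
#' Converts resolved gram weights into nutrient and food-group intake for the
#' recalled day. Food nutrients are `weight_g / 100` times the item's per-100 g
#' composition, summed over entries; supplements add `dose_count` times the
#' per-dose composition (generic entries use the category median from
#' [generic_supplement_composition()]). Food-group totals are the summed gram
#' weights of the entries in each configured group; every configured group is
#' reported, zero when nothing was consumed from it.
#'
#' @param session A finalized `recall_session`.
#' @param db The `food_db` the session was captured against.
#' @return A tibble in long "daily intake" form: `participant_id`, `date`,
#'   `variable`, `kind` (`"nutrient"` or `"food_group"`), `food_only` and
#'   `with_supplements` (supplements never reduce a nutrient, and food-group
#'   rows carry identical values in both columns).
#' @export
compute_daily_intake <- function(session, db) {
  stopifnot(inherits(session, "recall_session"), inherits(db, "food_db"))
  if (!identical(session$state, "finalized")) {
    stop("daily intake is only defined for finalized sessions", call. = FALSE)
  }
  ids <- nutrient_ids(db$schema)
  entries <- tidy(session)
  nut <- setNames(numeric(length(ids)), ids)
  grp <- setNames(numeric(length(db$food_groups)), db$food_groups)
  if (nrow(entries) > 0) {
    rows <- match(entries$food_id, db$foods$food_id)
    comp <- as.matrix(db$foods[rows, ids])
    scaled <- comp * (entries$resolved_weight_g / 100)
    nut <- nut + colSums(scaled)
    g <- tapply(entries$resolved_weight_g, db$foods$food_group[rows], sum)
    grp[names(g)] <- grp[names(g)] + as.numeric(g)
  }
  supp <- nut
  for (s in session$supplements) {
    dose <- if (isTRUE(s$generic)) {
      unlist(generic_supplement_composition(db, s$category_id))
    } else {
      row <- db$supplements[db$supplements$supplement_id == s$supplement_id, , drop = FALSE]
      if (nrow(row) == 0) stop(sprintf("unknown supplement_id '%s'", s$supplement_id), call. = FALSE)
      unlist(row[, ids])
    }
    supp <- supp + s$dose_count * dose[ids]
  }
  dplyr::bind_rows(
    tibble::tibble(
      participant_id = session$participant_id, date = session$recall_date,
      variable = ids, kind = "nutrient",
      food_only = as.numeric(nut), with_supplements = as.numeric(supp)
    ),
    tibble::tibble(
      participant_id = session$participant_id, date = session$recall_date,
      variable = names(grp), kind = "food_group",
      food_only = as.numeric(grp), with_supplements = as.numeric(grp)
    )
  )
}

#' Mean daily intake over replicate recall days
#'
#' Arithmetic mean and SD (n-1 denominator) per participant and variable over
#' the supplied daily-intake rows. A participant-variable observed on a single
#' day gets SD 0 with `single_day = TRUE` rather than an error, so single-day
#' pipelines still run.
#'
#' @param days Daily-intake tibble(s) as returned by [compute_daily_intake()]
#'   (rows from several days/participants may be bound together).
#' @param value `"food_only"` (default, used by all validation statistics) or
#'   `"with_supplements"`.
#' @return Tibble `participant_id`, `variable`, `kind`, `mean`, `sd`,
#'   `n_days`, `single_day`.
#' @export
mean_daily_intake <- function(days, value = c("food_only", "with_supplements")) {
  value <- match.arg(value)
  days <- dplyr::bind_rows(days)
  if (nrow(days) == 0) stop("no daily intakes supplied", call. = FALSE)
  days |>
    dplyr::group_by(.data$participant_id, .data$variable, .data$kind) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sd = if (dplyr::n() > 1) stats::sd(.data[[value]]) else 0,
      n_days = dplyr::n(),
      single_day = dplyr::n() == 1,
      .groups = "drop"
    )
}

#' Label a set of daily intakes as one assessment method
#'
#' @param days Daily-intake rows ([compute_daily_intake()] output, bound).
#' @param method Method label (e.g. `"recall"`, `"diary"`).
#' @return A `method_dataset`: list with `method`, `days` (per-day rows) and
#'   `means` (per-participant means from [mean_daily_intake()]).
#' @export
method_dataset <- function(days, method) {
  days <- dplyr::bind_rows(days)
  stopifnot(nrow(days) > 0, nzchar(method))
  structure(
    list(method = method, days = days, means = mean_daily_intake(days)),
    class = "method_dataset"
  )
}

#' @export
print.method_dataset <- function(x, ...) {
  cat(sprintf(
    "<method_dataset> '%s': %d participants, %d participant-days\n",
    x$method, dplyr::n_distinct(x$days$participant_id),
    nrow(dplyr::distinct(x$days, .data$participant_id, .data$date))
  ))
  invisible(x)
}

#' @export
tidy.method_dataset <- function(x, ...) x$means

macronutrient_factor_map <- function(config) {
  f <- config$energy_factors
  map <- c(
    protein = "protein", carbohydrate = "carbohydrate", fat = "fat",
    alcohol = "alcohol", fiber = "fiber",
    saturated_fat = "fat", monounsaturated_fat = "fat", polyunsaturated_fat = "fat",
    sugars = "carbohydrate", starch = "carbohydrate"
  )
  map[map %in% names(f)]
}

#' Energy-adjust intake values
#'
#' Removes energy-level confounding before correlation analysis: each
#' energy-bearing macronutrient (and its sub-fractions) is expressed as the
#' percentage of energy it supplies, `g x factor(kcal/g) / energy(kcal) x 100`;
#' every other nutrient is scaled to its amount per 10 MJ of energy intake,
#' `x * 10 / energy_MJ` with `energy_MJ = kcal * 4.184 / 1000`. The energy row
#' itself is passed through unadjusted.
#'
#' @param intakes Tibble with at least `variable` and a value column; rows for
#'   several participants may be present if `participant_id` identifies them.
#'   Must contain an `energy` row (kcal) per participant.
#' @param config An [analysis_config()].
#' @param value Name of the value column (default `"mean"`).
#' @return The input with an `adjusted` column and an `adjust_unit` column
#'   (`"%E"`, `"per_10MJ"` or `"kcal"`).
#' @export
energy_adjust <- function(intakes, config = analysis_config(), value = "mean") {
  config <- as_analysis_config(config)
  stopifnot(value %in% names(intakes), "variable" %in% names(intakes))
  map <- macronutrient_factor_map(config)
  grouping <- intersect(c("participant_id", "method"), names(intakes))
  adjust_one <- function(df) {
    en <- df[[value]][df$variable == "energy"]
    if (length(en) != 1) stop("energy_adjust needs exactly one energy row per participant", call. = FALSE)
    if (en <= 0) stop("energy intake must be positive for energy adjustment", call. = FALSE)
    mj <- en * config$kj_per_kcal / 1000
    df$adjusted <- NA_real_
    df$adjust_unit <- NA_character_
    has_kind <- "kind" %in% names(df)
    for (i in seq_len(nrow(df))) {
      v <- df$variable[i]
      x <- df[[value]][i]
      if (v == "energy") {
        df$adjusted[i] <- x
        df$adjust_unit[i] <- "kcal"
      } else if (has_kind && df$kind[i] == "food_group") {
        df$adjusted[i] <- x * 10 / mj
        df$adjust_unit[i] <- "per_10MJ"
      } else if (v %in% names(map)) {
        df$adjusted[i] <- x * config$energy_factors[[map[[v]]]] / en * 100
        df$adjust_unit[i] <- "%E"
      } else {
        df$adjusted[i] <- x * 10 / mj
        df$adjust_unit[i] <- "per_10MJ"
      }
    }
    df
  }
  if (length(grouping) == 0) {
    adjust_one(intakes)
  } else {
    intakes |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::group_modify(~ adjust_one(.x)) |>
      dplyr::ungroup()
  }
}
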