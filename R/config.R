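#' Analysis configuration
#'
#' Collects every constant the intake and validation computations depend on,
#' so nothing is hard-coded in the statistics themselves.
#'
#' Defaults: energy conversion factors follow the UK convention (protein 4,
#' carbohydrate 3.75 as monosaccharide equivalents, fat 9, alcohol 7, fiber 2
#' kcal/g); 1 kcal = 4.184 kJ; urinary sodium is assumed to represent 90% of
#' sodium consumed; expected creatinine excretion is 23 mg/kg/day for males
#' and 18 for females with a creatinine index accepted in [0.7, 1.3]; a
#' 24-hour urine collection is rejected below 0.5 L total volume or with more
#' than 1 missed void; Bland-Altman limits of agreement use k = 2 standard
#' deviations.
#'
#' @param energy_factors Named numeric, kcal per gram for energy-bearing
#'   macronutrients used for percentage-of-energy adjustment.
#' @param kj_per_kcal Energy unit conversion.
#' @param sodium_excretion_fraction Fraction of consumed sodium excreted in
#'   urine, used to back-calculate intake from 24-h urinary sodium.
#' @param creatinine_mg_per_kg Named numeric `c(male=, female=)`, expected
#'   urinary creatinine excretion in mg per kg body weight per day.
#' @param creatinine_mg_per_mmol Molar mass used to convert measured urinary
#'   creatinine (mmol/d) to mg/d for the creatinine index.
#' @param creatinine_index_bounds Inclusive inclusion bounds on
#'   observed/expected creatinine excretion.
#' @param urine_volume_min_l Minimum acceptable 24-h urine volume (litres).
#' @param missed_void_max Maximum acceptable number of missed voids.
#' @param ba_k Multiplier on the SD of differences for the limits of
#'   agreement (2 by convention here; 1.96 also accepted).
#' @param ba_comparable_pct Percent of points that must fall within the
#'   limits for two methods to be called comparable (strictly greater than).
#' @param normality_alpha Shapiro-Wilk significance level used to route
#'   between parametric and nonparametric difference tests.
#' @param welch Use Welch's correction in the independent-samples t-test
#'   (default equal-variance pooled test).
#' @param sb2_epsilon Floor for the between-person variance component when
#'   the ANOVA between mean square does not exceed the within mean square.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(energy_factors = c(
                              protein = 4, carbohydrate = 3.75, fat = 9,
                              alcohol = 7, fiber = 2
                            ),
                            kj_per_kcal = 4.184,
                            sodium_excretion_fraction = 0.90,
                            creatinine_mg_per_kg = c(male = 23, female = 18),
                            creatinine_mg_per_mmol = 113.12,
                            creatinine_index_bounds = c(0.7, 1.3),
                            urine_volume_min_l = 0.5,
                            missed_void_max = 1,
                            ba_k = 2,
                            ba_comparable_pct = 95,
                            normality_alpha = 0.05,
                            welch = FALSE,
                            sb2_epsilon = 1e-8) {
  stopifnot(
    all(energy_factors > 0), kj_per_kcal > 0,
    sodium_excretion_fraction > 0, sodium_excretion_fraction <= 1,
    all(creatinine_mg_per_kg > 0), creatinine_mg_per_mmol > 0,
    length(creatinine_index_bounds) == 2,
    creatinine_index_bounds[1] < creatinine_index_bounds[2],
    urine_volume_min_l > 0, missed_void_max >= 0,
    ba_k > 0, ba_comparable_pct > 0, normality_alpha > 0, sb2_epsilon > 0
  )
  structure(
    list(
      energy_factors = energy_factors,
      kj_per_kcal = kj_per_kcal,
      sodium_excretion_fraction = sodium_excretion_fraction,
      creatinine_mg_per_kg = creatinine_mg_per_kg,
      creatinine_mg_per_mmol = creatinine_mg_per_mmol,
      creatinine_index_bounds = creatinine_index_bounds,
      urine_volume_min_l = urine_volume_min_l,
      missed_void_max = missed_void_max,
      ba_k = ba_k,
      ba_comparable_pct = ba_comparable_pct,
      normality_alpha = normality_alpha,
      welch = welch,
      sb2_epsilon = sb2_epsilon
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  energy factors (kcal/g):",
      paste(names(x$energy_factors), x$energy_factors, sep = "=", collapse = ", "), "\n")
  cat("  sodium excretion fraction:", x$sodium_excretion_fraction, "\n")
  cat("  creatinine norms (mg/kg/d): male", x$creatinine_mg_per_kg[["male"]],
      ", female", x$creatinine_mg_per_kg[["female"]],
      "; index bounds [", x$creatinine_index_bounds[1], ",",
      x$creatinine_index_bounds[2], "]\n")
  cat("  urine: min volume", x$urine_volume_min_l, "L, max missed voids",
      x$missed_void_max, "\n")
  cat("  Bland-Altman k:", x$ba_k, " (comparable if >", x$ba_comparable_pct,
      "% within limits)\n")
  invisible(x)
}

as_analysis_config <- function(x) {
  if (inherits(x, "analysis_config")) return(x)
  if (is.null(x)) return(analysis_config())
  stopifnot(is.list(x))
  do.call(analysis_config, x)
}

#' Load a tool configuration from YAML or JSON
#'
#' Reads a configuration file holding any subset of the [analysis_config()]
#' and [simulation_config()] fields under top-level keys `analysis` and
#' `simulation`. Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `analysis` (class `analysis_config`) and
#'   `simulation` (class `simulation_config`).
#' @export
load_tool_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("analysis", "simulation")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown top-level config keys: ", paste(extra, collapse = ", "))
  }
  ana <- raw$analysis %||% list()
  sim <- raw$simulation %||% list()
  check_keys <- function(given, fn, label) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad) > 0) {
      stop("unknown ", label, " config keys: ", paste(bad, collapse = ", "))
    }
  }
  check_keys(ana, analysis_config, "analysis")
  check_keys(sim, simulation_config, "simulation")
  ana <- lapply(ana, function(v) if (is.list(v)) unlist(v) else v)
  sim <- lapply(sim, function(v) if (is.list(v) && !is.data.frame(v)) unlist(v) else v)
  list(
    analysis = do.call(analysis_config, ana),
    simulation = do.call(simulation_config, sim)
  )
}
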