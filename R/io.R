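#' Read and write daily-intake tables
#'
#' The interchange CSV carries one row per participant-day-variable:
#' `participant_id`, `date`, `variable`, `kind`, `food_only`,
#' `with_supplements` (UTF-8, comma separator, header mandatory). A headered
#' but empty file reads as an empty dataset without error.
#'
#' @param days Daily-intake tibble ([compute_daily_intake()] /
#'   [simulate_method_days()] output).
#' @param path CSV path.
#' @return `read_intakes()` the tibble; `write_intakes()` the path,
#'   invisibly.
#' @export
write_intakes <- function(days, path) {
  need <- c("participant_id", "date", "variable", "kind", "food_only", "with_supplements")
  stopifnot(all(need %in% names(days)))
  readr::write_csv(days[, need], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_intakes
#' @export
read_intakes <- function(path) {
  check_header(path, c("participant_id", "date", "variable", "kind", "food_only", "with_supplements"))
  readr::read_csv(path,
    col_types = readr::cols(
      participant_id = readr::col_character(), date = readr::col_character(),
      variable = readr::col_character(), kind = readr::col_character(),
      food_only = readr::col_double(), with_supplements = readr::col_double()
    ), progress = FALSE
  )
}

#' Read and write biomarker tables
#'
#' Columns follow the biomarker record schema used by
#' [biomarker_correlation()].
#'
#' @param biomarkers Biomarker tibble.
#' @param path CSV path.
#' @return `read_biomarkers()` the tibble; `write_biomarkers()` the path,
#'   invisibly.
#' @export
write_biomarkers <- function(biomarkers, path) {
  readr::write_csv(biomarkers, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_biomarkers
#' @export
read_biomarkers <- function(path) {
  check_header(path, "participant_id")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read evaluation-questionnaire counts
#'
#' @param path CSV with columns `question`, `category`, `count`.
#' @return Tibble.
#' @export
read_evaluation_counts <- function(path) {
  check_header(path, c("question", "category", "count"))
  readr::read_csv(path,
    col_types = readr::cols(
      question = readr::col_character(), category = readr::col_character(),
      count = readr::col_double()
    ), progress = FALSE
  )
}

check_header <- function(path, expected) {
  stopifnot(file.exists(path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE, progress = FALSE))
  missing <- setdiff(expected, hdr)
  if (length(missing) > 0) {
    stop(
      sprintf(
        "'%s' is missing expected column(s): %s", path,
        paste(missing, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(TRUE)
}
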