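#' @importFrom rlang %||% .data abort
#' @importFrom generics tidy glance augment
#' @importFrom stats cor cor.test sd var aov anova shapiro.test t.test
#'   wilcox.test rnorm rlnorm rbinom runif median quantile setNames
#' @importFrom utils head modifyList
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# round half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# fold diacritics to ASCII and lowercase, for search matching
fold_text <- function(x) {
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  out[is.na(out)] <- x[is.na(out)]
  tolower(out)
}

# split a ";"-separated CSV cell into a character vector (empty -> character(0))
split_semi <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

join_semi <- function(x) paste(x, collapse = ";")

# parse "HH:MM" into minutes since midnight; NA if malformed
parse_hhmm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3) return(NA_real_)
  h <- as.numeric(m[2]); mi <- as.numeric(m[3])
  if (h > 23 || mi > 59) return(NA_real_)
  h * 60 + mi
}
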