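#' Parse FAERS-style partial date tokens
#'
#' FAERS date fields are plain digit strings whose length encodes precision:
#' 8 digits = full date (`YYYYMMDD`), 6 = year-month (`YYYYMM`), 4 = year
#' (`YYYY`). Anything else (including empty strings and tokens containing
#' non-digits) is treated as missing and counted.
#'
#' @param tokens character vector of raw date tokens.
#' @return A `data.table` with one row per token and columns `year`, `month`,
#'   `day` (integer, `NA` where absent) and `precision`
#'   (`"day"`, `"month"`, `"year"` or `NA` for unparseable tokens), plus an
#'   attribute `n_invalid` giving the number of tokens that violated the
#'   dialect (non-empty but not a valid 4/6/8-digit date).
#' @examples
#' parse_partial_date(c("20220315", "202203", "2022", "", "15-03-2022"))
#' @export
parse_partial_date <- function(tokens) {
  tokens <- trimws(as.character(tokens))
  n <- length(tokens)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)

  digits <- grepl("^[0-9]+$", tokens)
  len <- nchar(tokens)

  y8 <- digits & len == 8L
  y6 <- digits & len == 6L
  y4 <- digits & len == 4L

  year[y8 | y6 | y4] <- as.integer(substr(tokens[y8 | y6 | y4], 1L, 4L))
  month[y8 | y6] <- as.integer(substr(tokens[y8 | y6], 5L, 6L))
  day[y8] <- as.integer(substr(tokens[y8], 7L, 8L))
  precision[y4] <- "year"
  precision[y6] <- "month"
  precision[y8] <- "day"

  # reject impossible months/days: demote to missing, count as invalid
  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  dim_days <- c(31L, 29L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  bad_day <- !is.na(day) & !bad_month &
    (day < 1L | day > dim_days[pmax(month, 1L)])
  bad <- bad_month | bad_day
  year[bad] <- month[bad] <- day[bad] <- NA_integer_
  precision[bad] <- NA_character_

  invalid <- (nzchar(tokens) & is.na(precision))
  out <- data.table::data.table(year = year, month = month, day = day,
                                precision = precision)
  data.table::setattr(out, "n_invalid", sum(invalid))
  out
}

#' Day-precision partial dates as calendar dates
#'
#' Tokens with less than day precision (or unparseable) return `NA`; only
#' full `YYYYMMDD` tokens yield a `Date`. Used for time-to-onset arithmetic,
#' where partial dates must be excluded rather than imputed.
#'
#' @param tokens character vector of FAERS date tokens.
#' @return `Date` vector with `NA` for non-day-precision tokens.
#' @export
partial_date_as_date <- function(tokens) {
  pd <- parse_partial_date(tokens)
  out <- rep(as.Date(NA), nrow(pd))
  full <- !is.na(pd$precision) & pd$precision == "day"
  if (any(full)) {
    out[full] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[full],
                                 pd$month[full], pd$day[full]))
  }
  out
}

#' Extract the year from FAERS date tokens
#'
#' @param tokens character vector of FAERS date tokens.
#' @return integer vector of years (`NA` when the token has no usable year).
#' @export
partial_date_year <- function(tokens) {
  parse_partial_date(tokens)$year
}

# Format a Date as a FAERS token truncated to the given precision.
# Vectorised over both arguments; NA dates give "".
format_faers_date <- function(dates, precision = "day") {
  precision <- rep_len(precision, length(dates))
  out <- character(length(dates))
  ok <- !is.na(dates)
  out[ok & precision == "day"] <-
    format(dates[ok & precision == "day"], "%Y%m%d")
  out[ok & precision == "month"] <-
    format(dates[ok & precision == "month"], "%Y%m")
  out[ok & precision == "year"] <-
    format(dates[ok & precision == "year"], "%Y")
  out
}
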