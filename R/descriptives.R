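#' Percentage at reporting precision
#'
#' The convention used throughout the descriptive tables: percent of a block
#' denominator, rounded to 2 decimals. `NA` when the denominator is zero.
#'
#' @param n count(s).
#' @param denom block denominator.
#' @param digits decimals (default 2).
#' @return numeric vector.
#' @export
pct <- function(n, denom, digits = 2) {
  out <- round(100 * n / denom, digits)
  out[rep_len(!(denom > 0), length(out))] <- NA_real_
  out
}

#' Descriptive profile of a report cohort
#'
#' Summarizes demographics, reporting provenance and outcomes with explicit
#' missing-data denominators: each categorical block is computed over its
#' non-missing denominator (spontaneous-report data lose about 82% of age
#' and sex), and `known + missing = cohort size` holds per block.
#'
#' A report is serious iff it carries at least one outcome code. By default
#' each serious report contributes one outcome category under the
#' precedence death > life-threatening > disability > hospitalization >
#' other, so the sub-shares form a partition of the serious count;
#' `multi_outcome = TRUE` instead counts every distinct code a report
#' carries (shares can then exceed 100%, as raw FAERS outcome tallies do).
#'
#' @param reports typed safety reports (deduplicated cohort), from
#'   [safety_reports()].
#' @param outcomes outcome mentions for the same reports, from
#'   [outcome_mentions()].
#' @param multi_outcome count all outcome codes per report (default FALSE).
#' @return object of class `cohort_summary`: `total`, named list `blocks`
#'   (each a `data.table` of `category`, `n`, `pct`), `denominators`
#'   (`block`, `known`, `missing`), `age_median`, `age_iqr`.
#' @export
summarize_cohort <- function(reports, outcomes, multi_outcome = FALSE) {
  rep_dt <- data.table::as.data.table(reports)
  out_dt <- data.table::as.data.table(outcomes)
  total <- nrow(rep_dt)
  blocks <- list()
  denoms <- list()

  block <- function(name, values, categories) {
    known <- !is.na(values) & values != "unknown"
    d <- sum(known)
    counts <- table(factor(values[known], levels = categories))
    blocks[[name]] <<- data.table::data.table(
      category = categories, n = as.integer(counts),
      pct = pct(as.integer(counts), d))
    denoms[[name]] <<- data.table::data.table(
      block = name, known = d, missing = total - d)
  }

  if (total == 0L) {
    empty <- structure(list(total = 0L, blocks = list(),
                            denominators = data.table::data.table(),
                            age_median = NA_real_,
                            age_iqr = c(NA_real_, NA_real_)),
                       class = "cohort_summary")
    return(empty)
  }

  block("sex", rep_dt$sex, c("F", "M"))

  age <- rep_dt$age_years
  age_grp <- ifelse(is.na(age), NA_character_,
                    ifelse(age < 18, "<18",
                           ifelse(age <= 65, "18-65", ">65")))
  block("age_group", age_grp, c("<18", "18-65", ">65"))
  age_median <- stats::median(age, na.rm = TRUE)
  age_iqr <- stats::quantile(age, c(0.25, 0.75), na.rm = TRUE, names = FALSE)

  country <- rep_dt$country
  top <- names(sort(table(country), decreasing = TRUE))
  top_keep <- utils::head(top, 5)
  country_cat <- ifelse(is.na(country), NA_character_,
                        ifelse(country %in% top_keep, country, "Other"))
  block("country", country_cat,
        c(top_keep, if (any(stats::na.omit(country_cat) == "Other")) "Other"))

  block("reporter", rep_dt$reporter_type,
        c("health professional", "consumer", "other"))

  yr <- as.character(rep_dt$report_year)
  block("year", yr, sort(unique(stats::na.omit(yr))))

  ## outcomes
  serious_ids <- unique(out_dt$primaryid)
  serious <- rep_dt$primaryid %in% serious_ids
  n_serious <- sum(serious)
  blocks[["seriousness"]] <- data.table::data.table(
    category = c("Non-serious", "Serious"),
    n = c(total - n_serious, n_serious),
    pct = pct(c(total - n_serious, n_serious), total))
  denoms[["seriousness"]] <- data.table::data.table(
    block = "seriousness", known = total, missing = 0L)

  out_levels <- c("Death", "Life-threatening", "Disability",
                  "Hospitalization", "Other serious outcome")
  code_map <- c(DE = "Death", LT = "Life-threatening", DS = "Disability",
                HO = "Hospitalization", CA = "Other serious outcome",
                RI = "Other serious outcome", OT = "Other serious outcome")
  if (nrow(out_dt)) {
    oc <- out_dt[, .(primaryid, category = code_map[outcome_code])]
    oc <- unique(oc)
    if (!multi_outcome) {
      oc[, rank := match(category, out_levels)]
      oc <- oc[oc[, .I[which.min(rank)], by = primaryid]$V1]
      oc[, rank := NULL]
    }
    counts <- table(factor(oc$category, levels = out_levels))
  } else {
    counts <- table(factor(character(0), levels = out_levels))
  }
  blocks[["serious_outcome"]] <- data.table::data.table(
    category = out_levels, n = as.integer(counts),
    pct = pct(as.integer(counts), n_serious))
  denoms[["serious_outcome"]] <- data.table::data.table(
    block = "serious_outcome", known = n_serious,
    missing = total - n_serious)

  structure(list(total = total, blocks = blocks,
                 denominators = data.table::rbindlist(denoms),
                 age_median = age_median, age_iqr = age_iqr),
            class = "cohort_summary")
}

#' Flatten a cohort summary to one long table
#'
#' @param summary a `cohort_summary`.
#' @return `data.table` with `block`, `category`, `n`, `pct`.
#' @export
descriptives_table <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (!length(summary$blocks)) {
    return(data.table::data.table(block = character(0),
                                  category = character(0),
                                  n = integer(0), pct = numeric(0)))
  }
  data.table::rbindlist(
    lapply(names(summary$blocks), function(b) {
      cbind(data.table::data.table(block = b), summary$blocks[[b]])
    }))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary:", x$total, "reports; age median",
      round(x$age_median, 1), "\n")
  print(descriptives_table(x))
  invisible(x)
}

#' Time-to-onset analysis
#'
#' Time-to-onset is the day count from the earliest therapy start of a
#' primary-suspect target drug row to the adverse event date. Pairs where
#' either date is missing, lacks day precision, or yields a negative
#' difference are excluded and counted by reason -- never imputed. Day-0
#' (same-day) onsets are retained. The median and quartiles use the linear
#' interpolation convention (`stats::quantile` type 7), and onsets are
#' binned into (0, 30], (30, 90], (90, 365] and (365, Inf) days, with day 0
#' assigned to the first bin.
#'
#' @param reports typed safety reports for the cohort.
#' @param mentions drug mentions for the cohort (with `start_dt`).
#' @param target_names,threshold,substring_match which drug rows count as
#'   the suspect therapy (see [match_drug_name()]).
#' @return object of class `onset_summary`: `n_evaluable`, `median_days`,
#'   `iqr_lo`, `iqr_hi`, `bins` (`bin`, `n`, `pct`), `excluded`
#'   (`reason`, `n`), `days` (the evaluable day counts).
#' @export
compute_tto <- function(reports, mentions, target_names, threshold = 0.1,
                        substring_match = TRUE) {
  rep_dt <- data.table::as.data.table(reports)
  men_dt <- data.table::as.data.table(mentions)

  m <- match_drug_name(men_dt$name_raw, target_names, threshold,
                       substring_match)
  ps <- m & !is.na(men_dt$role_code) & men_dt$role_code == 1L
  ther <- men_dt[ps, .(primaryid, start_dt)]

  start_pd <- parse_partial_date(ther$start_dt)
  ther[, start_date := partial_date_as_date(start_dt)]
  ther[, start_prec := start_pd$precision]
  starts <- ther[, .(
    start_date = if (any(!is.na(start_date))) min(start_date, na.rm = TRUE)
                 else as.Date(NA),
    has_token = any(!is.na(start_prec)),
    has_day = any(!is.na(start_date))
  ), by = primaryid]

  ev_pd <- parse_partial_date(rep_dt$event_dt)
  ev <- data.table::data.table(primaryid = rep_dt$primaryid,
                               event_date = partial_date_as_date(rep_dt$event_dt),
                               event_prec = ev_pd$precision)
  dt <- starts[ev, on = "primaryid"]

  reason <- rep(NA_character_, nrow(dt))
  reason[is.na(dt$event_prec)] <- "missing_event"
  reason[is.na(reason) & dt$event_prec != "day"] <- "partial_event"
  no_start <- is.na(dt$has_token) | !dt$has_token
  reason[is.na(reason) & no_start] <- "missing_start"
  reason[is.na(reason) & !no_start & !dt$has_day] <- "partial_start"
  days <- as.integer(dt$event_date - dt$start_date)
  reason[is.na(reason) & days < 0] <- "negative"

  ok <- is.na(reason)
  days_ok <- days[ok]
  reasons <- c("missing_event", "partial_event", "missing_start",
               "partial_start", "negative")
  excluded <- data.table::data.table(
    reason = reasons,
    n = as.integer(table(factor(reason, levels = reasons))))

  breaks <- c(-0.5, 30, 90, 365, Inf)
  labels <- c("0-30", "31-90", "91-365", ">365")
  binned <- cut(days_ok, breaks = breaks, labels = labels)
  bins <- data.table::data.table(
    bin = labels, n = as.integer(table(binned)),
    pct = pct(as.integer(table(binned)), length(days_ok)))

  qs <- if (length(days_ok)) stats::quantile(days_ok, c(0.25, 0.5, 0.75),
                                             type = 7, names = FALSE)
        else rep(NA_real_, 3)
  structure(list(n_evaluable = length(days_ok), median_days = qs[2],
                 iqr_lo = qs[1], iqr_hi = qs[3], bins = bins,
                 excluded = excluded, days = days_ok),
            class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("onset_summary: %d evaluable; median %.2f days (IQR %.2f-%.2f)\n",
              x$n_evaluable, x$median_days, x$iqr_lo, x$iqr_hi))
  print(x$bins)
  invisible(x)
}
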