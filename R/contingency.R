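#' Map raw reaction terms onto the vocabulary
#'
#' Normalizes reported terms to canonical PTs (through LLT synonyms) and
#' attaches the primary SOC. Unmapped terms are kept as-is under the
#' `"Unmapped"` SOC so they stay visible in counts.
#'
#' @param reac reaction mentions (`primaryid`, `pt_raw`).
#' @param vocab a `faers_vocabulary`.
#' @return `data.table` with `primaryid`, `pt`, `soc`, `mapped`.
#' @export
map_reactions <- function(reac, vocab) {
  dt <- data.table::as.data.table(reac)
  norm <- normalize_pt(dt$pt_raw, vocab)
  out <- data.table::data.table(primaryid = dt$primaryid, pt = norm$pt,
                                mapped = norm$mapped)
  out[, soc := pt_to_soc(pt, vocab)]
  out[]
}

#' Unique (report, term) pairs at a hierarchy level
#'
#' The counting unit of all disproportionality statistics. At the PT level a
#' report contributes at most once per PT (a PT listed twice in one report
#' counts once). At the SOC level the default counts unique (report, SOC)
#' pairs, so a report with three gastrointestinal PTs contributes one
#' gastrointestinal pair; `distinct_by_level = FALSE` instead sums the
#' member (report, PT) pairs into their SOC, making SOC counts an exact
#' partition of PT counts.
#'
#' @param mapped output of [map_reactions()].
#' @param level `"PT"` or `"SOC"`.
#' @param distinct_by_level see above.
#' @return `data.table` with `primaryid`, `term`.
#' @export
term_pairs <- function(mapped, level = c("PT", "SOC"),
                       distinct_by_level = TRUE) {
  level <- match.arg(level)
  dt <- data.table::as.data.table(mapped)
  pairs <- unique(dt[, .(primaryid, pt, soc)])  # PT-level dedup always
  if (level == "PT") {
    out <- pairs[, .(primaryid, term = pt)]
  } else if (distinct_by_level) {
    out <- unique(pairs[, .(primaryid, term = soc)])
  } else {
    out <- pairs[, .(primaryid, term = soc)]
  }
  out
}

#' Build 2x2 contingency tables per stratum
#'
#' For each term, counts against the background:
#' `a` target cohort with the term, `b` cohort pairs with other terms,
#' `c` background pairs with the term, `d` background pairs with other
#' terms; plus the expected count `E = (a+b)(a+c)/N` under independence.
#'
#' @param pairs (report, term) pairs from [term_pairs()], covering the whole
#'   deduplicated database.
#' @param cohort_primaryids reports forming the target cohort.
#' @return `data.table` with `stratum`, `a`, `b`, `c_`, `d`, `N`, `E`, one
#'   row per term occurring in the cohort (background-only terms carry no
#'   cohort signal and are omitted).
#' @export
build_contingency_tables <- function(pairs, cohort_primaryids) {
  dt <- data.table::as.data.table(pairs)
  in_cohort <- dt$primaryid %in% cohort_primaryids
  n_cohort_pairs <- sum(in_cohort)
  n_bg_pairs <- sum(!in_cohort)
  if (n_bg_pairs == 0L) {
    stop(errorCondition(
      "empty background: every report is in the target cohort",
      class = c("faers_dispro_error", "error", "condition")))
  }
  if (n_cohort_pairs == 0L) {
    stop(errorCondition("cohort has no reaction pairs",
                        class = c("faers_dispro_error", "error", "condition")))
  }
  a_tab <- dt[in_cohort, .(a = .N), by = .(stratum = term)]
  c_tab <- dt[!in_cohort, .(c_ = .N), by = .(stratum = term)]
  out <- merge(a_tab, c_tab, by = "stratum", all.x = TRUE)
  out[is.na(c_), c_ := 0L]
  out[, b := n_cohort_pairs - a]
  out[, d := n_bg_pairs - c_]
  out[, N := n_cohort_pairs + n_bg_pairs]
  out[, E := as.numeric(a + b) * (a + c_) / N]
  data.table::setorder(out, -a, stratum)
  data.table::setcolorder(out, c("stratum", "a", "b", "c_", "d", "N", "E"))
  out[]
}
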