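#' Run the full disproportionality pipeline on a FAERS-style package
#'
#' Wires the stages end to end: read the quarterly package, deduplicate and
#' remove deleted cases, select the primary-suspect cohort by fuzzy drug
#' name matching, map reaction terms to PT and SOC, build contingency
#' tables, fit the database-wide MGPS prior, compute the four
#' disproportionality statistics with their signal criteria at both
#' hierarchy levels, the descriptive cohort profile and the time-to-onset
#' summary, and write the result tables plus a run manifest recording the
#' record-count funnel at every stage.
#'
#' When `label_pts` is supplied, flagged PTs are partitioned into
#' label-listed and novel tables (no PT appears in both).
#'
#' @param input_dir FAERS-style package directory (real or generated).
#' @param output_dir where to write the TSV tables and `manifest.txt`;
#'   `NULL` computes without writing.
#' @param target_names drug name(s) defining the cohort.
#' @param vocab a `faers_vocabulary`; default the bundled one.
#' @param threshold,substring_match fuzzy-match settings.
#' @param ror_correction,chi2_correction,ic_variant statistic variants (see
#'   [ror_with_ci()], [prr_with_chi2()], [bcpnn_ic()]).
#' @param thresholds signal-criteria overrides
#'   (see [apply_signal_criteria()]).
#' @param soc_distinct count unique (report, SOC) pairs at the SOC level
#'   (default) rather than summing member PT pairs.
#' @param label_pts character vector of PTs listed on the product label, or
#'   a path to a one-PT-per-line file; `NULL` skips the split.
#' @param digits rounding for written tables.
#' @return invisibly, a list: `cohort`, `summary`, `onset`, `signals_pt`,
#'   `signals_soc`, `prior`, `manifest`, and when `label_pts` is given
#'   `signals_pt_label` / `signals_pt_novel`.
#' @export
run_pipeline <- function(input_dir, output_dir = NULL, target_names,
                         vocab = NULL, threshold = 0.1,
                         substring_match = TRUE,
                         ror_correction = "none",
                         chi2_correction = "yates",
                         ic_variant = "noren",
                         thresholds = list(),
                         soc_distinct = TRUE,
                         label_pts = NULL, digits = 4) {
  if (is.null(vocab)) vocab <- load_vocabulary()
  pkg <- read_faers_package(input_dir)
  cohort <- build_cohort(pkg, target_names, threshold, substring_match)
  if (length(cohort$cohort_primaryids) == 0L) {
    stop(errorCondition("no reports match the target drug as primary suspect",
                        class = c("faers_pipeline_error", "error",
                                  "condition")))
  }

  mapped <- map_reactions(cohort$reac, vocab)
  pt_pairs <- term_pairs(mapped, "PT")
  soc_pairs <- term_pairs(mapped, "SOC", distinct_by_level = soc_distinct)

  tab_pt <- build_contingency_tables(pt_pairs, cohort$cohort_primaryids)
  tab_soc <- build_contingency_tables(soc_pairs, cohort$cohort_primaryids)

  # database-wide prior: every (suspect drug, PT) cell of the dedup'd data
  prior <- mgps_fit_prior_db(cohort$drug, pt_pairs, target_names,
                             threshold, substring_match)

  sig_pt <- signal_stats(tab_pt, prior, ror_correction, chi2_correction,
                         ic_variant, thresholds)
  sig_soc <- signal_stats(tab_soc, prior, ror_correction, chi2_correction,
                          ic_variant, thresholds)

  in_cohort <- cohort$reports$primaryid %in% cohort$cohort_primaryids
  summary <- summarize_cohort(cohort$reports[in_cohort],
                              cohort$outc[primaryid %in%
                                            cohort$cohort_primaryids])
  onset <- compute_tto(cohort$reports[in_cohort],
                       cohort$drug[primaryid %in% cohort$cohort_primaryids],
                       target_names, threshold, substring_match)

  results <- list(cohort = cohort, summary = summary, onset = onset,
                  signals_pt = sig_pt, signals_soc = sig_soc, prior = prior)

  if (!is.null(label_pts)) {
    if (length(label_pts) == 1L && file.exists(label_pts)) {
      label_pts <- trimws(readLines(label_pts, warn = FALSE))
      label_pts <- label_pts[nzchar(label_pts)]
    }
    flagged <- sig_pt[flag_all == TRUE]
    results$signals_pt_label <- flagged[stratum %in% label_pts]
    results$signals_pt_novel <- flagged[!(stratum %in% label_pts)]
  }

  manifest <- c(
    cohort$funnel,
    quarantined_rows = nrow(pkg$skipped),
    pt_strata = nrow(sig_pt), soc_strata = nrow(sig_soc),
    flagged_all_four_pt = sum(sig_pt$flag_all),
    tto_evaluable = onset$n_evaluable)
  results$manifest <- manifest

  if (!is.null(output_dir)) {
    tabs <- list(descriptives = descriptives_table(summary),
                 signals_pt = sig_pt, signals_soc = sig_soc,
                 tto_bins = onset$bins,
                 tto_exclusions = onset$excluded)
    if (!is.null(results$signals_pt_label)) {
      tabs$signals_pt_label <- results$signals_pt_label
      tabs$signals_pt_novel <- results$signals_pt_novel
    }
    write_analysis_tables(tabs, output_dir, digits = digits)
    writeLines(c(
      "faersignal run manifest",
      paste0("package_version: ",
             as.character(utils::packageVersion("faersignal"))),
      paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      paste0("input_dir: ", input_dir),
      paste0("target_names: ", paste(target_names, collapse = ", ")),
      paste0("fuzzy_threshold: ", threshold),
      paste0("ic_variant: ", ic_variant),
      paste0("chi2_correction: ", chi2_correction),
      sprintf("%s: %s", names(manifest), manifest)),
      file.path(output_dir, "manifest.txt"))
  }
  invisible(results)
}

# Database-wide MGPS prior: one cell per (suspect drug, PT) pair. Reported
# drug names are free text, so they are canonicalized first (and every
# variant of the target collapses to one drug) -- without this the target's
# cells fragment across spelling variants and the shrinkage prior
# underestimates the database's real heterogeneity.
mgps_fit_prior_db <- function(drug, pt_pairs, target_names,
                              threshold = 0.1, substring_match = TRUE) {
  ps_rows <- drug[!is.na(role_code) & role_code == 1L,
                  .(primaryid, name_raw)]
  is_target <- match_drug_name(ps_rows$name_raw, target_names, threshold,
                               substring_match)
  ps_rows[, drugname := ifelse(is_target, "__target__",
                               normalize_drug_name(name_raw))]
  ps_rows[, name_raw := NULL]
  ps_rows <- unique(ps_rows)
  cells <- merge(ps_rows, pt_pairs, by = "primaryid",
                 allow.cartesian = TRUE)
  counts <- cells[, .N, by = .(drugname, term)]
  drug_margin <- cells[, .(nd = .N), by = drugname]
  event_margin <- cells[, .(ne = .N), by = term]
  total <- nrow(cells)
  counts <- merge(counts, drug_margin, by = "drugname")
  counts <- merge(counts, event_margin, by = "term")
  counts[, E := as.numeric(nd) * ne / total]
  mgps_fit_prior(counts$N, counts$E)
}
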