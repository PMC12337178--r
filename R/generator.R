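#' Configuration for the synthetic FAERS-dialect generator
#'
#' Defines a complete synthetic spontaneous-report world with known ground
#' truth: a target drug (generic + brand names, emulating a newly approved
#' agent), a Zipf-weighted background of other suspect drugs, a MedDRA-style
#' event vocabulary, planted drug-event dependencies of configurable
#' strength, duplicate and deleted cases, and the heavy missing-data regime
#' typical of consumer-reported data (about 82% missing age and sex, about
#' 76% of reports without a computable onset).
#'
#' @param n_reports number of distinct cases to generate.
#' @param quarters quarter labels (`"2022Q1"` style); reports are allocated
#'   across them with `quarter_weights`.
#' @param quarter_weights sampling weights per quarter; the default mirrors a
#'   post-approval ramp (about 19% of reports in the first year, 55% in the
#'   second, 25% in the first half of the third).
#' @param target_drug_names name variants of the drug of interest; the first
#'   is treated as the generic name.
#' @param n_background_drugs number of background suspect drugs.
#' @param vocab a `faers_vocabulary` (default: the bundled synthetic one).
#' @param planted_signals named numeric vector: per preferred term, the true
#'   relative reporting ratio (lambda) applied to that PT's background
#'   frequency in reports where the target drug is the primary suspect.
#'   Lambda 1 plants a null term.
#' @param target_share fraction of reports mentioning the target drug.
#' @param ps_role_share share of target-drug mentions carrying role code 1
#'   (primary suspect); the remainder are coded concomitant/interacting.
#' @param duplicate_rate fraction of cases re-emitted under a higher
#'   PRIMARYID with identical CASEID and content.
#' @param deleted_rate fraction of cases listed in the deleted-cases file
#'   (they remain present in the quarterly tables, as in real extracts).
#' @param missing_sex_rate,missing_age_rate fraction of reports with missing
#'   demographics.
#' @param missing_tto_rate total fraction of reports whose time-to-onset is
#'   not computable (blank or partial dates).
#' @param partial_date_rate among non-computable onsets, the share realized
#'   as truncated 4/6-digit date tokens rather than blank fields.
#' @param onset_median_days,onset_sdlog log-normal onset-time parameters
#'   (median on the day scale; sigma on the log scale).
#' @param mean_extra_reactions mean of the Poisson count of reactions beyond
#'   the first per report.
#' @param zipf_exponent,zipf_offset background event frequencies follow
#'   `1 / (offset + rank)^exponent` over the alphabetically ranked PT list
#'   (heavy-tailed term frequencies are the regime disproportionality
#'   methods face).
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   file set.
#' @return validated object of class `faers_gen_config`.
#' @export
faers_gen_config <- function(n_reports = 50000L,
                             quarters = c("2022Q1", "2022Q2", "2022Q3",
                                          "2022Q4", "2023Q1", "2023Q2",
                                          "2023Q3", "2023Q4", "2024Q1",
                                          "2024Q2"),
                             quarter_weights = NULL,
                             target_drug_names = c("PACRITINIB", "VONJO"),
                             n_background_drugs = 50L,
                             vocab = NULL,
                             planted_signals = c(Diarrhoea = 4),
                             target_share = 0.05,
                             ps_role_share = 0.9,
                             duplicate_rate = 0.05,
                             deleted_rate = 0.02,
                             missing_sex_rate = 0.8165,
                             missing_age_rate = 0.8258,
                             missing_tto_rate = 0.7578,
                             partial_date_rate = 0.3,
                             onset_median_days = 27,
                             onset_sdlog = 2.5,
                             mean_extra_reactions = 1.5,
                             zipf_exponent = 0.9,
                             zipf_offset = 10,
                             seed = 1L) {
  fail <- function(msg) {
    stop(errorCondition(msg,
                        class = c("faers_config_error", "error", "condition")))
  }
  if (is.null(vocab)) vocab <- load_vocabulary()
  if (!inherits(vocab, "faers_vocabulary")) fail("vocab must be a faers_vocabulary")
  n_reports <- as.integer(n_reports)
  if (is.na(n_reports) || n_reports < 1L) fail("n_reports must be >= 1")
  if (!length(quarters) || !all(grepl("^[0-9]{4}Q[1-4]$", quarters))) {
    fail("quarters must be labels like '2022Q1'")
  }
  if (is.null(quarter_weights)) {
    # year-level reporting ramp split evenly over that year's quarters
    yr <- substr(quarters, 1, 4)
    ramp <- stats::setNames(c(0.1933, 0.5531, 0.2536),
                            c("2022", "2023", "2024"))
    w <- ramp[yr]
    w[is.na(w)] <- mean(ramp)
    quarter_weights <- as.numeric(w / stats::ave(rep(1, length(w)), yr,
                                                 FUN = sum))
  }
  if (length(quarter_weights) != length(quarters) || any(quarter_weights < 0)) {
    fail("quarter_weights must be nonnegative, one per quarter")
  }
  rates <- c(target_share = target_share, ps_role_share = ps_role_share,
             duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
             missing_sex_rate = missing_sex_rate,
             missing_age_rate = missing_age_rate,
             missing_tto_rate = missing_tto_rate,
             partial_date_rate = partial_date_rate)
  bad <- rates < 0 | rates >= 1
  # ps_role_share and missing_tto_rate legitimately reach 1
  bad[c("ps_role_share", "missing_tto_rate")] <-
    rates[c("ps_role_share", "missing_tto_rate")] < 0 |
    rates[c("ps_role_share", "missing_tto_rate")] > 1
  if (any(bad)) fail(paste0("rate out of range: ",
                            paste(names(rates)[bad], collapse = ", ")))
  if (length(planted_signals)) {
    if (is.null(names(planted_signals)) || any(!nzchar(names(planted_signals)))) {
      fail("planted_signals must be a named numeric vector")
    }
    if (any(planted_signals <= 0)) fail("planted lambda must be > 0")
    missing_pt <- setdiff(names(planted_signals), vocab$pt)
    if (length(missing_pt)) {
      fail(paste0("planted PT not in vocabulary: ",
                  paste(missing_pt, collapse = ", ")))
    }
  }
  if (!length(target_drug_names) || any(!nzchar(target_drug_names))) {
    fail("target_drug_names must be nonempty strings")
  }
  if (n_background_drugs < 1L) fail("n_background_drugs must be >= 1")
  if (onset_median_days <= 0 || onset_sdlog <= 0) {
    fail("onset parameters must be positive")
  }
  structure(list(
    n_reports = n_reports, quarters = quarters,
    quarter_weights = quarter_weights / sum(quarter_weights),
    target_drug_names = toupper(target_drug_names),
    n_background_drugs = as.integer(n_background_drugs),
    vocab = vocab, planted_signals = planted_signals,
    target_share = target_share, ps_role_share = ps_role_share,
    duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
    missing_sex_rate = missing_sex_rate, missing_age_rate = missing_age_rate,
    missing_tto_rate = missing_tto_rate,
    partial_date_rate = partial_date_rate,
    onset_median_days = onset_median_days, onset_sdlog = onset_sdlog,
    mean_extra_reactions = mean_extra_reactions,
    zipf_exponent = zipf_exponent, zipf_offset = zipf_offset,
    seed = as.integer(seed)
  ), class = "faers_gen_config")
}

# Zipf-like background probability per PT, over alphabetical rank.
background_event_probs <- function(config) {
  npt <- length(config$vocab$pt)
  p <- 1 / (config$zipf_offset + seq_len(npt))^config$zipf_exponent
  stats::setNames(p / sum(p), config$vocab$pt)
}

#' Draw time-to-onset values under the generator's onset model
#'
#' Onsets are log-normal on the day scale (integer-floored, nonnegative);
#' a `missing_tto_rate` fraction is returned as `NA`, standing for reports
#' whose onset cannot be computed from the emitted dates.
#'
#' @param config a `faers_gen_config`.
#' @param n number of draws (default: `config$n_reports`).
#' @return integer vector of day counts with `NA` for non-computable onsets.
#' @export
sample_time_to_onset <- function(config, n = config$n_reports) {
  stopifnot(inherits(config, "faers_gen_config"))
  days <- as.integer(floor(stats::rlnorm(n,
                                         meanlog = log(config$onset_median_days),
                                         sdlog = config$onset_sdlog)))
  days[stats::runif(n) < config$missing_tto_rate] <- NA_integer_
  days
}

quarter_start <- function(q) {
  yr <- substr(q, 1, 4)
  qi <- as.integer(substr(q, 6, 6))
  as.Date(paste0(yr, c("-01-01", "-04-01", "-07-01", "-10-01")[qi]))
}

#' Generate a synthetic FAERS-dialect report set in memory
#'
#' The workhorse behind [generate_package()]. Reaction terms for reports
#' where the target drug is primary suspect are drawn from a multinomial
#' whose cell probabilities are the background event frequencies scaled by
#' the planted lambda for planted PTs (renormalized); all other reports draw
#' from the background frequencies. Under this scheme the reporting odds
#' ratio of a planted PT in the primary-suspect cohort against the rest of
#' the database equals lambda up to sampling noise, so planted strengths are
#' recoverable by the downstream statistics.
#'
#' @param config a `faers_gen_config`.
#' @return An object of class `faers_synthetic`: list of FAERS-shaped
#'   character `data.table`s (`demo`, `drug`, `reac`, `outc`, `rpsr`,
#'   `ther`, `indi`, each with a `quarter` column), `deleted_caseids`, and
#'   `ground_truth` (per-case flags and true onsets, `reactions` with
#'   canonical PTs, and the `planted` lambda table).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "faers_gen_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_reports
  caseid <- as.character(30000000L + seq_len(n))
  primaryid_v1 <- paste0(caseid, "1")

  quarter <- sample(config$quarters, n, replace = TRUE,
                    prob = config$quarter_weights)
  qstart <- quarter_start(quarter)

  is_target <- stats::runif(n) < config$target_share
  target_ps <- is_target & (stats::runif(n) < config$ps_role_share)

  ## --- drugs -----------------------------------------------------------
  nbg <- config$n_background_drugs
  bg_names <- sprintf("BKG%03d", seq_len(nbg))
  bg_p <- 1 / seq_len(nbg)^0.7
  bg_p <- bg_p / sum(bg_p)
  suspect_bg <- sample(bg_names, n, replace = TRUE, prob = bg_p)

  tg_variants <- c(config$target_drug_names,
                   paste0(config$target_drug_names[1], " CITRATE"),
                   paste0(config$target_drug_names[min(2, length(config$target_drug_names))],
                          " 200MG CAPSULE"))
  target_name <- sample(tg_variants, n, replace = TRUE,
                        prob = c(rep(0.85 / length(config$target_drug_names),
                                     length(config$target_drug_names)),
                                 0.075, 0.075))

  ## --- onsets and dates ------------------------------------------------
  onset_true <- as.integer(floor(stats::rlnorm(
    n, meanlog = log(config$onset_median_days), sdlog = config$onset_sdlog)))
  evaluable <- stats::runif(n) >= config$missing_tto_rate
  mech <- rep("full", n)
  ne <- which(!evaluable)
  u <- stats::runif(length(ne))
  mech[ne] <- ifelse(u < 1 - config$partial_date_rate, "blank_event",
                     ifelse(u < 1 - config$partial_date_rate / 2,
                            "partial_event", "partial_start"))

  start_date <- qstart + floor(stats::runif(n) * 89)
  event_date <- start_date + onset_true
  fda_date <- qstart + floor(stats::runif(n) * 89)

  event_tok <- format_faers_date(event_date, "day")
  start_tok <- format_faers_date(start_date, "day")
  event_tok[mech == "blank_event"] <- ""
  pe <- mech == "partial_event"
  event_tok[pe] <- format_faers_date(event_date[pe],
                                     sample(c("month", "year"), sum(pe),
                                            replace = TRUE, prob = c(.7, .3)))
  ps_ <- mech == "partial_start"
  start_tok[ps_] <- format_faers_date(start_date[ps_],
                                      sample(c("month", "year"), sum(ps_),
                                             replace = TRUE, prob = c(.7, .3)))
  fda_tok <- format_faers_date(fda_date, "day")

  ## --- demographics ----------------------------------------------------
  sex <- ifelse(stats::runif(n) < config$missing_sex_rate, "",
                ifelse(stats::runif(n) < 0.5618, "M", "F"))
  age_known <- stats::runif(n) >= config$missing_age_rate
  age_years <- pmin(pmax(round(stats::rnorm(n, 71.5, 9)), 18), 99)
  age_unit <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                     prob = c(0.9, 0.08, 0.02))
  age_val <- ifelse(age_unit == "YR", as.character(age_years),
                    ifelse(age_unit == "DEC",
                           formatC(age_years / 10, format = "f", digits = 1),
                           as.character(age_years * 12L)))
  age_val[!age_known] <- ""
  age_unit[!age_known] <- ""

  cu <- stats::runif(n)
  country <- ifelse(cu < 0.9907, "US",
                    ifelse(cu < 0.9928, "PL",
                           sample(c("CA", "GB", "DE", "FR", "JP"), n,
                                  replace = TRUE)))
  ou <- stats::runif(n)
  occp <- ifelse(ou < 0.0077, "",
                 ifelse(ou < 0.0077 + 0.9923 * 0.8478, "CN",
                        sample(c("MD", "PH", "OT"), n, replace = TRUE,
                               prob = c(.4, .3, .3))))

  ## --- outcomes --------------------------------------------------------
  serious <- stats::runif(n) < 0.3268
  out_codes <- c("DE", "LT", "HO", "OT")
  out_p <- c(0.347, 0.0032, 0.5284, 0.2918)
  primary_out <- sample(out_codes, n, replace = TRUE, prob = out_p / sum(out_p))
  extra_flag <- serious & stats::runif(n) < 0.3
  extra_out <- sample(out_codes, n, replace = TRUE)

  ## --- reactions -------------------------------------------------------
  vocab <- config$vocab
  base_p <- background_event_probs(config)
  lam <- rep(1, length(base_p))
  names(lam) <- names(base_p)
  if (length(config$planted_signals)) {
    lam[names(config$planted_signals)] <- config$planted_signals
  }
  scaled_p <- base_p * lam
  scaled_p <- scaled_p / sum(scaled_p)

  k <- 1L + pmin(stats::rpois(n, config$mean_extra_reactions), 7L)
  rep_idx <- rep(seq_len(n), k)
  is_scaled <- rep(target_ps, k)
  pts <- character(length(rep_idx))
  n_sc <- sum(is_scaled)
  if (n_sc) pts[is_scaled] <- sample(names(base_p), n_sc, replace = TRUE,
                                     prob = scaled_p)
  pts[!is_scaled] <- sample(names(base_p), length(rep_idx) - n_sc,
                            replace = TRUE, prob = base_p)

  # emit some reactions as LLT synonyms / case variants
  syn_tab <- vocab$terms[vocab$terms$llt_or_pt != vocab$terms$pt, ]
  syn_by_pt <- split(syn_tab$llt_or_pt, syn_tab$pt)
  emitted <- pts
  use_syn <- stats::runif(length(pts)) < 0.10 & pts %in% names(syn_by_pt)
  if (any(use_syn)) {
    emitted[use_syn] <- vapply(pts[use_syn], function(p) {
      s <- syn_by_pt[[p]]
      s[sample.int(length(s), 1L)]
    }, character(1))
  }
  shout <- stats::runif(length(pts)) < 0.10
  emitted[shout] <- toupper(emitted[shout])

  ## --- assemble tables -------------------------------------------------
  demo <- data.table::data.table(
    primaryid = primaryid_v1, caseid = caseid, event_dt = event_tok,
    fda_dt = fda_tok, sex = sex, age = age_val, age_cod = age_unit,
    occp_cod = occp, reporter_country = country, quarter = quarter)

  # suspect row (drug_seq 1) + optional target-as-concomitant + extras
  drug_rows <- list(data.table::data.table(
    primaryid = primaryid_v1, caseid = caseid, drug_seq = "1",
    role_cod = "1",
    drugname = ifelse(target_ps, target_name, suspect_bg),
    quarter = quarter))
  conc <- is_target & !target_ps
  if (any(conc)) {
    drug_rows <- c(drug_rows, list(data.table::data.table(
      primaryid = primaryid_v1[conc], caseid = caseid[conc], drug_seq = "2",
      role_cod = as.character(sample(2:3, sum(conc), replace = TRUE)),
      drugname = target_name[conc], quarter = quarter[conc])))
  }
  n_extra <- pmin(stats::rpois(n, 0.8), 3L)
  if (any(n_extra > 0)) {
    eidx <- rep(seq_len(n), n_extra)
    seq_off <- sequence(n_extra) + 1L + conc[eidx]
    drug_rows <- c(drug_rows, list(data.table::data.table(
      primaryid = primaryid_v1[eidx], caseid = caseid[eidx],
      drug_seq = as.character(seq_off),
      role_cod = as.character(sample(2:3, length(eidx), replace = TRUE)),
      drugname = sample(bg_names, length(eidx), replace = TRUE, prob = bg_p),
      quarter = quarter[eidx])))
  }
  drug <- data.table::rbindlist(drug_rows)
  data.table::setorder(drug, caseid, drug_seq)

  reac <- data.table::data.table(
    primaryid = primaryid_v1[rep_idx], caseid = caseid[rep_idx],
    pt = emitted, quarter = quarter[rep_idx])

  outc <- data.table::data.table(
    primaryid = primaryid_v1[serious], caseid = caseid[serious],
    outc_cod = primary_out[serious], quarter = quarter[serious])
  if (any(extra_flag & extra_out != primary_out)) {
    keep <- extra_flag & extra_out != primary_out
    outc <- rbind(outc, data.table::data.table(
      primaryid = primaryid_v1[keep], caseid = caseid[keep],
      outc_cod = extra_out[keep], quarter = quarter[keep]))
  }
  data.table::setorder(outc, caseid, outc_cod)

  rpsr <- data.table::data.table(
    primaryid = primaryid_v1, caseid = caseid,
    rpsr_cod = ifelse(occp == "CN", "CSM",
                      ifelse(occp == "", "FGN", "HP")),
    quarter = quarter)

  ther <- data.table::data.table(
    primaryid = primaryid_v1, caseid = caseid, dsg_drug_seq = "1",
    start_dt = start_tok, end_dt = "", quarter = quarter)

  indi <- data.table::data.table(
    primaryid = primaryid_v1, caseid = caseid, indi_drug_seq = "1",
    indi_pt = ifelse(target_ps, "Myelofibrosis",
                     sample(c("Hypertension", "Product used for unknown indication",
                              "Rheumatoid arthritis", "Atrial fibrillation"),
                            n, replace = TRUE)),
    quarter = quarter)

  ## --- duplicates and deleted cases ------------------------------------
  n_dup <- floor(config$duplicate_rate * n)
  dup_case <- if (n_dup) sample(caseid, n_dup) else character(0)
  n_del <- floor(config$deleted_rate * n)
  del_case <- if (n_del) sample(caseid, n_del) else character(0)

  dup_copy <- function(dt) {
    if (!length(dup_case)) return(dt)
    cp <- dt[dt$caseid %in% dup_case]
    if (nrow(cp)) {
      cp <- data.table::copy(cp)
      cp[, primaryid := paste0(caseid, "2")]
      dt <- rbind(dt, cp)
      data.table::setorder(dt, caseid, primaryid)
    }
    dt
  }
  demo <- dup_copy(demo); drug <- dup_copy(drug); reac <- dup_copy(reac)
  outc <- dup_copy(outc); rpsr <- dup_copy(rpsr); ther <- dup_copy(ther)
  indi <- dup_copy(indi)

  duplicated_flag <- caseid %in% dup_case
  gt_reports <- data.table::data.table(
    caseid = caseid,
    primaryid = ifelse(duplicated_flag, paste0(caseid, "2"), primaryid_v1),
    duplicated = duplicated_flag,
    deleted = caseid %in% del_case,
    is_target = is_target, target_ps = target_ps,
    onset_days = onset_true, tto_evaluable = evaluable,
    serious = serious, quarter = quarter)

  gt_reactions <- data.table::data.table(caseid = caseid[rep_idx], pt = pts)

  structure(list(
    demo = demo, drug = drug, reac = reac, outc = outc, rpsr = rpsr,
    ther = ther, indi = indi, deleted_caseids = sort(del_case),
    ground_truth = list(
      reports = gt_reports, reactions = gt_reactions,
      planted = data.table::data.table(
        pt = names(config$planted_signals),
        lambda = as.numeric(config$planted_signals))),
    config = config
  ), class = "faers_synthetic")
}

#' Write a synthetic report set as a FAERS-dialect quarterly package
#'
#' Emits one directory per quarter containing "$"-delimited
#' `DEMO/DRUG/REAC/OUTC/RPSR/THER/INDI.txt` tables plus a top-level
#' `DELETED.txt` (one CASEID per line), readable by [read_faers_package()].
#' The same config and seed always produce a byte-identical file set.
#'
#' @param config a `faers_gen_config`.
#' @param directory output directory.
#' @param synth optionally, a pre-generated `faers_synthetic` to write
#'   (skips regeneration).
#' @return invisibly, the `faers_synthetic` object (with ground truth).
#' @export
generate_package <- function(config, directory, synth = NULL) {
  if (is.null(synth)) synth <- generate_reports(config)
  stopifnot(inherits(synth, "faers_synthetic"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tables <- c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")
  for (q in synth$config$quarters) {
    qdir <- file.path(directory, q)
    dir.create(qdir, showWarnings = FALSE)
    for (tb in tables) {
      dt <- synth[[tb]]
      slice <- dt[dt$quarter == q, !"quarter"]
      path <- file.path(qdir, paste0(toupper(tb), ".txt"))
      lines <- c(paste(names(slice), collapse = "$"),
                 if (nrow(slice)) do.call(paste,
                                          c(as.list(slice), sep = "$")))
      writeLines(lines, path)
    }
  }
  writeLines(synth$deleted_caseids, file.path(directory, "DELETED.txt"))
  invisible(synth)
}
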