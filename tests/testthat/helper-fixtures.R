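library(data.table)

# Small generator config for fast tests.
small_config <- function(n = 2000, seed = 7, ...) {
  faers_gen_config(n_reports = n, seed = seed, ...)
}

# Hand-written miniature FAERS package: 3 demo rows (one malformed line in
# DEMO), 4 drug rows, 3 reaction rows, one deleted case.
write_tiny_package <- function(dir) {
  q <- file.path(dir, "2022Q1")
  dir.create(q, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    "primaryid$caseid$event_dt$fda_dt$sex$age$age_cod$occp_cod$reporter_country",
    "1001$100$20220315$20220320$F$72$YR$CN$US",
    "1011$101$202203$20220321$M$7.2$DEC$MD$US",
    "1021$102$$20220322$$$$$US",
    "badline-without-dollars"
  ), file.path(q, "DEMO.txt"))
  writeLines(c(
    "primaryid$caseid$drug_seq$role_cod$drugname",
    "1001$100$1$1$VONJO 200MG CAPSULE",
    "1011$101$1$1$BKG001",
    "1011$101$2$2$PACRITINIB",
    "1021$102$1$1$pacritinib citrate"
  ), file.path(q, "DRUG.txt"))
  writeLines(c(
    "primaryid$caseid$pt",
    "1001$100$Diarrhea",
    "1011$101$Headache",
    "1021$102$Nausea"
  ), file.path(q, "REAC.txt"))
  writeLines(c(
    "primaryid$caseid$outc_cod",
    "1001$100$HO",
    "1001$100$DE"
  ), file.path(q, "OUTC.txt"))
  writeLines(c(
    "primaryid$caseid$dsg_drug_seq$start_dt$end_dt",
    "1001$100$1$20220216$",
    "1021$102$1$20220101$"
  ), file.path(q, "THER.txt"))
  writeLines("102", file.path(dir, "DELETED.txt"))
  invisible(dir)
}

# A cohort of typed safety reports + outcome mentions reproducing the
# marginal counts of a published descriptive table: 1940 reports, 356 known
# sex (200 M / 156 F), 338 known age (92 aged 18-65, 246 over 65), 1922 US /
# 4 PL / 14 other, 1925 known reporters (293 HP / 1632 consumers),
# years 375 / 1073 / 492, 634 serious (220 death, 2 life-threatening,
# 335 hospitalization, 77 other), 470 with computable onset.
printed_counts_cohort <- function() {
  n <- 1940
  ids <- sprintf("%07d", seq_len(n))
  sex <- c(rep("M", 200), rep("F", 156), rep("unknown", n - 356))
  age <- c(rep(40, 92), rep(75, 246), rep(NA_real_, n - 338))
  country <- c(rep("US", 1922), rep("PL", 4), rep("GB", 14))
  reporter <- c(rep("health professional", 293), rep("consumer", 1632),
                rep("unknown", n - 1925))
  year <- c(rep(2022L, 375), rep(2023L, 1073), rep(2024L, 492))
  reports <- data.table(
    primaryid = ids, caseid = ids, sex = sex, age_years = age,
    country = country, reporter_type = reporter,
    event_dt = "", fda_dt = paste0(year, "0601"),
    report_year = year, quarter = NA_character_)
  outcomes <- data.table(
    primaryid = c(ids[1:220], ids[221:222], ids[223:557], ids[558:634]),
    outcome_code = c(rep("DE", 220), rep("LT", 2), rep("HO", 335),
                     rep("OT", 77)))
  list(reports = reports, outcomes = outcomes)
}

# Suspect-drug x PT cells over the whole synthetic database, built straight
# from generator ground truth (bypasses the package's own counting).
synth_db_cells <- function(synth) {
  gt <- synth$ground_truth$reports
  kept <- gt[deleted == FALSE]
  drug <- as.data.table(synth$drug)[role_cod == "1" & caseid %in% kept$caseid,
                                    .(caseid, drugname)]
  # collapse the target's name variants to one drug (background drugs are
  # the BKG### pool)
  drug[, drugname := ifelse(startsWith(drugname, "BKG"), drugname,
                            "TARGET")]
  drug <- unique(drug, by = "caseid")
  rx <- unique(as.data.table(synth$ground_truth$reactions))
  cells <- merge(drug, rx, by = "caseid", allow.cartesian = TRUE)
  counts <- cells[, .(a = .N), by = .(drugname, pt)]
  nd <- cells[, .(nd = .N), by = drugname]
  ne <- cells[, .(ne = .N), by = pt]
  counts <- merge(merge(counts, nd, by = "drugname"), ne, by = "pt")
  counts[, E := as.numeric(nd) * ne / nrow(cells)]
  counts[]
}

# 2x2 counts for one PT, cohort (target primary-suspect, non-deleted cases)
# versus everything else, from generator ground truth.
gt_contingency <- function(synth, pt_name) {
  gt <- synth$ground_truth$reports
  del <- gt[deleted == TRUE, caseid]
  rx <- unique(as.data.table(synth$ground_truth$reactions))
  rx <- rx[!(caseid %in% del)]
  cohort <- gt[target_ps == TRUE & deleted == FALSE, caseid]
  inco <- rx$caseid %in% cohort
  a <- sum(inco & rx$pt == pt_name)
  b <- sum(inco) - a
  cc <- sum(!inco & rx$pt == pt_name)
  d <- sum(!inco) - cc
  list(a = a, b = b, c_ = cc, d = d)
}
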