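test_that("descriptive shares recompute from printed marginal counts", {
  fix <- printed_counts_cohort()
  s <- summarize_cohort(fix$reports, fix$outcomes)
  expect_equal(s$total, 1940L)

  sex <- s$blocks$sex
  expect_equal(sex[category == "M", pct], 56.18)
  expect_equal(sex[category == "F", pct], 43.82)
  expect_equal(s$denominators[block == "sex", known], 356L)
  expect_equal(pct(356, 1940), 18.35)

  age <- s$blocks$age_group
  expect_equal(age[category == ">65", pct], 72.78)
  expect_equal(age[category == "18-65", pct], 27.22)
  expect_equal(age[category == "<18", pct], 0)

  expect_equal(s$blocks$country[category == "US", pct], 99.07)
  expect_equal(s$blocks$reporter[category == "consumer", pct], 84.78)
  expect_equal(s$blocks$year[category == "2023", pct], 55.31)

  ser <- s$blocks$seriousness
  expect_equal(ser[category == "Serious", n], 634L)
  expect_equal(ser[category == "Serious", pct], 32.68)
  expect_equal(ser[category == "Non-serious", pct], 67.32)

  oc <- s$blocks$serious_outcome
  expect_equal(oc[category == "Death", pct], 34.70)
  expect_equal(oc[category == "Life-threatening", pct], 0.32)
  expect_equal(oc[category == "Hospitalization", pct], 52.84)
  # precedence partition: categories sum to the serious count,
  # shares to 100 within rounding
  expect_equal(sum(oc$n), 634L)
  expect_lt(abs(sum(oc$pct) - 100), 0.05)

  # denominator bookkeeping: known + missing = cohort size, per block
  expect_true(all(s$denominators$known + s$denominators$missing == 1940L))
})

test_that("outcome precedence takes the most severe code per report", {
  rep1 <- printed_counts_cohort()$reports[1:2]
  out <- data.table::data.table(
    primaryid = c(rep1$primaryid[1], rep1$primaryid[1], rep1$primaryid[2]),
    outcome_code = c("HO", "DE", "HO"))
  s <- summarize_cohort(rep1, out)
  oc <- s$blocks$serious_outcome
  expect_equal(oc[category == "Death", n], 1L)
  expect_equal(oc[category == "Hospitalization", n], 1L)
  # multi-outcome mode counts every code a report carries
  sm <- summarize_cohort(rep1, out, multi_outcome = TRUE)
  expect_equal(sm$blocks$serious_outcome[category == "Hospitalization", n],
               2L)
})

test_that("all-missing blocks report zero denominators, empty cohorts zero", {
  fix <- printed_counts_cohort()
  fix$reports[, sex := "unknown"]
  s <- summarize_cohort(fix$reports, fix$outcomes)
  expect_equal(s$denominators[block == "sex", known], 0L)
  expect_true(all(is.na(s$blocks$sex$pct)))

  e <- summarize_cohort(fix$reports[0], fix$outcomes[0])
  expect_equal(e$total, 0L)
})

test_that("time-to-onset arithmetic, exclusion reasons and bin boundaries", {
  mk_rep <- function(id, event) data.table::data.table(
    primaryid = id, caseid = id, sex = "unknown", age_years = NA_real_,
    country = "US", reporter_type = "consumer", event_dt = event,
    fda_dt = "20220601", report_year = 2022L, quarter = "2022Q1")
  mk_men <- function(id, start) data.table::data.table(
    primaryid = id, caseid = id, drug_seq = 1L, name_raw = "PACRITINIB",
    role_code = 1L, start_dt = start)
  reports <- rbind(mk_rep("1", "20220128"),   # 27 days
                   mk_rep("2", "20220101"),   # negative
                   mk_rep("3", "202203"),     # partial event
                   mk_rep("4", ""),           # missing event
                   mk_rep("5", "20220131"),   # 30 days -> first bin
                   mk_rep("6", "20220201"),   # 31 days -> second bin
                   mk_rep("7", "20220101"),   # 0 days, same-day
                   mk_rep("8", "20220301"))   # partial start
  mentions <- rbind(mk_men("1", "20220101"), mk_men("2", "20220110"),
                    mk_men("3", "20220101"), mk_men("4", "20220101"),
                    mk_men("5", "20220101"), mk_men("6", "20220101"),
                    mk_men("7", "20220101"), mk_men("8", "202201"))
  tto <- compute_tto(reports, mentions, c("pacritinib", "Vonjo"))
  expect_equal(tto$n_evaluable, 4L)
  expect_setequal(tto$days, c(27L, 30L, 31L, 0L))
  expect_equal(tto$bins[bin == "0-30", n], 3L)   # 27, 30 and day-0
  expect_equal(tto$bins[bin == "31-90", n], 1L)
  ex <- tto$excluded
  expect_equal(ex[reason == "negative", n], 1L)
  expect_equal(ex[reason == "partial_event", n], 1L)
  expect_equal(ex[reason == "missing_event", n], 1L)
  expect_equal(ex[reason == "partial_start", n], 1L)
  # linear-interpolation quartiles (type 7)
  expect_equal(c(tto$iqr_lo, tto$median_days, tto$iqr_hi),
               unname(quantile(c(27, 30, 31, 0), c(.25, .5, .75), type = 7)))
})

test_that("earliest therapy start of the suspect rows is used", {
  rep1 <- data.table::data.table(
    primaryid = "9", caseid = "9", sex = "unknown", age_years = NA_real_,
    country = "US", reporter_type = "consumer", event_dt = "20220301",
    fda_dt = "20220601", report_year = 2022L, quarter = "2022Q1")
  men <- data.table::data.table(
    primaryid = "9", caseid = "9", drug_seq = c(1L, 2L),
    name_raw = "PACRITINIB", role_code = 1L,
    start_dt = c("20220215", "20220101"))
  tto <- compute_tto(rep1, men, "pacritinib")
  expect_equal(tto$days, 59L)  # from 2022-01-01, not 2022-02-15
})

test_that("synthetic onsets reconcile with generator ground truth", {
  cfg <- small_config(n = 4000, seed = 9, duplicate_rate = 0.05,
                      deleted_rate = 0.02)
  dir <- withr::local_tempdir()
  synth <- generate_package(cfg, dir)
  pkg <- read_faers_package(dir)
  cohort <- build_cohort(pkg, cfg$target_drug_names)
  inco <- cohort$reports$primaryid %in% cohort$cohort_primaryids
  tto <- compute_tto(cohort$reports[inco],
                     cohort$drug[primaryid %in% cohort$cohort_primaryids],
                     cfg$target_drug_names)
  gt <- synth$ground_truth$reports[target_ps == TRUE & deleted == FALSE]
  expect_equal(tto$n_evaluable, gt[tto_evaluable == TRUE, .N])
  expect_equal(sort(tto$days),
               sort(gt[tto_evaluable == TRUE, onset_days]))
  # evaluable fraction tracks 1 - missing rate within binomial error
  phat <- tto$n_evaluable / nrow(gt)
  se <- sqrt(0.2422 * 0.7578 / nrow(gt))
  expect_lt(abs(phat - (1 - cfg$missing_tto_rate)), 4 * se)
})
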