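test_that("a tiny package loads with typed records and quarantine counts", {
  dir <- withr::local_tempdir()
  write_tiny_package(dir)
  pkg <- read_faers_package(dir)

  # row conservation: 3 parsed + 1 quarantined in DEMO
  expect_equal(nrow(pkg$demo), 3L)
  expect_equal(nrow(pkg$skipped), 1L)
  expect_equal(pkg$skipped$table, "DEMO")
  expect_equal(pkg$skipped$line, 5L)
  expect_equal(pkg$deleted_caseids, "102")

  rep <- safety_reports(pkg)
  expect_equal(rep$sex, c("F", "M", "unknown"))
  # DEC age unit: 7.2 decades = 72 years
  expect_equal(rep$age_years, c(72, 72, NA))
  expect_equal(rep$reporter_type,
               c("consumer", "health professional", "unknown"))
  expect_equal(rep$report_year, rep(2022L, 3))

  dm <- drug_mentions(pkg)
  expect_equal(dm[primaryid == "1001", role_code], 1L)
  expect_equal(dm[primaryid == "1011" & drug_seq == 2L, role_code], 2L)
  # THER start date joined onto the drug row
  expect_equal(dm[primaryid == "1001", start_dt], "20220216")

  rm_ <- reaction_mentions(pkg)
  expect_equal(nrow(rm_), 3L)
})

test_that("missing mandatory files and bad directories raise named errors", {
  expect_error(read_faers_package(tempfile()), class = "faers_io_error")
  dir <- withr::local_tempdir()
  q <- file.path(dir, "2022Q1")
  dir.create(q)
  writeLines("primaryid$caseid", file.path(q, "DEMO.txt"))
  expect_error(read_faers_package(dir), class = "faers_io_error")
})

test_that("age units convert to years and implausible ages are dropped", {
  dir <- withr::local_tempdir()
  q <- file.path(dir, "2022Q1")
  dir.create(q, recursive = TRUE)
  writeLines(c(
    "primaryid$caseid$event_dt$fda_dt$sex$age$age_cod$occp_cod$reporter_country",
    "11$1$$20220101$M$780$MON$CN$US",
    "21$2$$20220101$M$104$WK$CN$US",
    "31$3$$20220101$M$730$DY$CN$US",
    "41$4$$20220101$M$200$YR$CN$US",
    "51$5$$20220101$M$60$XX$CN$US"
  ), file.path(q, "DEMO.txt"))
  writeLines("primaryid$caseid$drug_seq$role_cod$drugname",
             file.path(q, "DRUG.txt"))
  writeLines("primaryid$caseid$pt", file.path(q, "REAC.txt"))
  rep <- safety_reports(read_faers_package(dir))
  expect_equal(rep$age_years, c(65, 2, 2, NA, NA))
})

test_that("analysis tables round-trip through disk at printed precision", {
  dir <- withr::local_tempdir()
  sig <- data.table::data.table(
    stratum = "Gastrointestinal disorders", n = 659L,
    ror = 2.6177, ror_lo = 2.4101, ror_hi = 2.8432, prr = 2.3640,
    chi2 = 554.7012, ic = 1.2412, ic025 = 1.1399, ebgm = 2.3638,
    ebgm05 = 2.1702, flag_ror = TRUE, flag_prr = TRUE, flag_ic = TRUE,
    flag_ebgm = TRUE, flag_all = TRUE)
  write_analysis_tables(list(signals_soc = sig), dir, digits = 4)
  back <- read_analysis_table(file.path(dir, "signals_soc.tsv"))
  expect_equal(nrow(back), 1L)
  num <- names(sig)[vapply(sig, is.double, logical(1))]
  expect_length(num, 9L)  # n plus these make the ten statistic columns
  expect_true("n" %in% names(back))
  for (cn in num) expect_equal(back[[cn]], round(sig[[cn]], 4))
  expect_true(back$flag_all)

  # empty result set: header-only file
  write_analysis_tables(list(empty = sig[0]), dir)
  lines <- readLines(file.path(dir, "empty.tsv"))
  expect_length(lines, 1L)
})

test_that("generator output survives a disk round-trip field-for-field", {
  cfg <- small_config(n = 300, seed = 11, duplicate_rate = 0.1,
                      deleted_rate = 0.05)
  dir <- withr::local_tempdir()
  synth <- generate_package(cfg, dir)
  pkg <- read_faers_package(dir)
  expect_equal(nrow(pkg$skipped), 0L)
  expect_equal(pkg$deleted_caseids, synth$deleted_caseids)
  for (tb in c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")) {
    orig <- data.table::setorderv(data.table::copy(synth[[tb]]),
                                  c("caseid", "primaryid"))
    got <- data.table::setorderv(data.table::copy(pkg[[tb]]),
                                 c("caseid", "primaryid"))
    data.table::setcolorder(got, names(orig))
    expect_equal(as.data.frame(got), as.data.frame(orig),
                 ignore_attr = TRUE, info = tb)
  }
})
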