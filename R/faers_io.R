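#' Read one FAERS-dialect ASCII table
#'
#' FAERS quarterly tables are "$"-delimited ASCII files, first line a header.
#' Real extracts contain stray bytes and occasional malformed rows, so the
#' reader decodes as UTF-8 (replacing undecodable bytes), and quarantines any
#' row whose field count disagrees with the header instead of aborting or
#' silently dropping it.
#'
#' @param path file path.
#' @return `data.table` of character columns named by the header, with
#'   attribute `quarantine`: a `data.table` of `line` numbers and raw `text`
#'   for rows that could not be parsed.
#' @export
read_faers_table <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("missing FAERS table: ", path),
                        class = c("faers_io_error", "error", "condition")))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "")
  if (length(lines) == 0L) {
    stop(errorCondition(paste0("empty FAERS table: ", path),
                        class = c("faers_io_error", "error", "condition")))
  }
  header <- strsplit(lines[1L], "$", fixed = TRUE)[[1L]]
  ncol <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops trailing empty fields ("a$b$" -> c("a","b")), so the
  # field count is judged on separator count, then short rows are padded.
  nsep <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE))
  ok <- (nsep + 1L) == ncol
  rows <- fields[ok]
  rows <- lapply(rows, function(f) c(f, rep("", ncol - length(f))))
  if (length(rows)) {
    mat <- matrix(unlist(rows, use.names = FALSE), ncol = ncol, byrow = TRUE)
    out <- data.table::as.data.table(mat)
  } else {
    out <- data.table::as.data.table(
      stats::setNames(replicate(ncol, character(0), simplify = FALSE), header))
  }
  data.table::setnames(out, header)
  q_idx <- which(!ok)
  quarantine <- data.table::data.table(line = q_idx + 1L, text = body[!ok])
  data.table::setattr(out, "quarantine", quarantine)
  out
}

#' Read a FAERS-style quarterly data package
#'
#' Loads every quarter subdirectory (names like `2022Q1`) of `directory`, or
#' `directory` itself when it directly contains the tables. DEMO, DRUG and
#' REAC are mandatory; OUTC, RPSR, THER and INDI are optional. A top-level
#' `DELETED.txt` (one CASEID per line) supplies the deleted-cases list.
#' Malformed rows are quarantined and counted per file, never silently
#' dropped.
#'
#' @param directory package root.
#' @return An object of class `faers_package`: list with `data.table`s
#'   `demo`, `drug`, `reac`, `outc`, `rpsr`, `ther`, `indi` (each with a
#'   `quarter` column), `deleted_caseids` (character), and `skipped`
#'   (per-file quarantined row counts and line numbers).
#' @export
read_faers_package <- function(directory) {
  if (!dir.exists(directory)) {
    stop(errorCondition(paste0("no such directory: ", directory),
                        class = c("faers_io_error", "error", "condition")))
  }
  subs <- list.dirs(directory, recursive = FALSE, full.names = FALSE)
  quarters <- subs[grepl("^[0-9]{4}Q[1-4]$", subs)]
  if (length(quarters) == 0L) quarters <- "."
  quarters <- sort(quarters)

  tables <- c("DEMO", "DRUG", "REAC", "OUTC", "RPSR", "THER", "INDI")
  mandatory <- c("DEMO", "DRUG", "REAC")
  acc <- stats::setNames(vector("list", length(tables)), tolower(tables))
  skipped <- list()

  for (q in quarters) {
    qdir <- if (q == ".") directory else file.path(directory, q)
    for (tb in tables) {
      path <- file.path(qdir, paste0(tb, ".txt"))
      if (!file.exists(path)) {
        if (tb %in% mandatory) {
          stop(errorCondition(
            paste0("mandatory table ", tb, " missing in ", qdir),
            class = c("faers_io_error", "error", "condition")))
        }
        next
      }
      dt <- read_faers_table(path)
      quar <- attr(dt, "quarantine")
      if (nrow(quar)) {
        skipped[[paste(q, tb, sep = "/")]] <-
          data.table::data.table(quarter = q, table = tb, quar)
      }
      dt[, quarter := if (q == ".") NA_character_ else q]
      acc[[tolower(tb)]] <- c(acc[[tolower(tb)]], list(dt))
    }
  }
  out <- lapply(acc, function(lst) {
    if (is.null(lst)) data.table::data.table() else data.table::rbindlist(lst)
  })

  del_path <- file.path(directory, "DELETED.txt")
  deleted <- if (file.exists(del_path)) {
    x <- readLines(del_path, warn = FALSE)
    trimws(x[nzchar(trimws(x))])
  } else character(0)

  out$deleted_caseids <- deleted
  out$skipped <- if (length(skipped)) data.table::rbindlist(skipped) else
    data.table::data.table(quarter = character(0), table = character(0),
                           line = integer(0), text = character(0))
  out$quarters <- setdiff(quarters, ".")
  structure(out, class = "faers_package")
}

#' @export
print.faers_package <- function(x, ...) {
  cat("faers_package:", nrow(x$demo), "demo rows,", nrow(x$drug),
      "drug rows,", nrow(x$reac), "reaction rows across",
      max(1L, length(x$quarters)), "quarter(s);",
      length(x$deleted_caseids), "deleted CASEIDs;",
      nrow(x$skipped), "quarantined rows\n")
  invisible(x)
}

# FAERS age-unit codes -> multiplier to years
.age_unit_factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52,
                      DY = 1 / 365)

#' Typed safety reports from a loaded package
#'
#' Normalizes the raw DEMO table: sex to `F`/`M`/`unknown`, age to years via
#' the FAERS age-unit code (`DEC` deciades, `MON`, `WK`, `DY`; unknown units
#' give missing), reporter occupation to
#' health professional / consumer / other / unknown, and a `report_year`
#' taken from the FDA receipt date (falling back to the event date year when
#' the receipt date is unusable). Ages of 150 years or more are treated as
#' data errors and set missing.
#'
#' @param pkg a `faers_package`.
#' @return `data.table` with columns `primaryid`, `caseid`, `sex`,
#'   `age_years`, `country`, `reporter_type`, `event_dt`, `fda_dt`,
#'   `report_year`, `quarter`.
#' @export
safety_reports <- function(pkg) {
  stopifnot(inherits(pkg, "faers_package"))
  d <- pkg$demo
  sex <- toupper(trimws(if ("sex" %in% names(d)) d$sex else
                          rep("", nrow(d))))
  sex[!(sex %in% c("F", "M"))] <- "unknown"
  age_num <- suppressWarnings(as.numeric(d$age))
  unit <- toupper(trimws(d$age_cod))
  fac <- .age_unit_factor[unit]
  age_years <- age_num * as.numeric(fac)
  age_years[!is.na(age_years) & age_years >= 150] <- NA_real_

  occ <- toupper(trimws(if ("occp_cod" %in% names(d)) d$occp_cod else
                          rep("", nrow(d))))
  reporter <- rep("unknown", nrow(d))
  reporter[occ %in% c("MD", "PH", "OT", "HP", "RN")] <- "health professional"
  reporter[occ == "CN"] <- "consumer"
  reporter[occ == "LW"] <- "other"

  fda_year <- partial_date_year(d$fda_dt)
  event_year <- partial_date_year(d$event_dt)
  report_year <- ifelse(is.na(fda_year), event_year, fda_year)

  country <- trimws(if ("reporter_country" %in% names(d)) d$reporter_country
                    else rep("", nrow(d)))
  country[!nzchar(country)] <- NA_character_

  data.table::data.table(
    primaryid = d$primaryid, caseid = d$caseid, sex = sex,
    age_years = age_years, country = country, reporter_type = reporter,
    event_dt = d$event_dt, fda_dt = d$fda_dt,
    report_year = as.integer(report_year), quarter = d$quarter)
}

#' Typed drug mentions from a loaded package
#'
#' Joins therapy start dates from THER onto DRUG rows by
#' (`primaryid`, `drug_seq`). Role codes outside `{1,2,3}` become `NA` and
#' are counted in the `n_bad_role` attribute.
#'
#' @param pkg a `faers_package`.
#' @return `data.table` with `primaryid`, `caseid`, `drug_seq`, `name_raw`,
#'   `role_code` (integer), `start_dt` (raw token, may be empty).
#' @export
drug_mentions <- function(pkg) {
  stopifnot(inherits(pkg, "faers_package"))
  d <- data.table::copy(pkg$drug)
  role <- suppressWarnings(as.integer(trimws(d$role_cod)))
  bad <- !is.na(d$role_cod) & nzchar(trimws(d$role_cod)) &
    (is.na(role) | !(role %in% 1:3))
  role[!(role %in% 1:3)] <- NA_integer_
  out <- data.table::data.table(
    primaryid = d$primaryid, caseid = d$caseid,
    drug_seq = suppressWarnings(as.integer(d$drug_seq)),
    name_raw = d$drugname, role_code = role)
  if (nrow(pkg$ther)) {
    th <- pkg$ther[, .(primaryid, drug_seq = suppressWarnings(
      as.integer(dsg_drug_seq)), start_dt)]
    th <- unique(th, by = c("primaryid", "drug_seq"))
    out <- th[out, on = c("primaryid", "drug_seq")]
    data.table::setcolorder(out, c("primaryid", "caseid", "drug_seq",
                                   "name_raw", "role_code", "start_dt"))
  } else {
    out[, start_dt := ""]
  }
  out[is.na(start_dt), start_dt := ""]
  data.table::setattr(out, "n_bad_role", sum(bad))
  out[]
}

#' Typed reaction mentions from a loaded package
#'
#' @param pkg a `faers_package`.
#' @return `data.table` with `primaryid`, `pt_raw` (trimmed, empty rows
#'   dropped and counted in attribute `n_empty`).
#' @export
reaction_mentions <- function(pkg) {
  stopifnot(inherits(pkg, "faers_package"))
  r <- pkg$reac
  pt <- trimws(r$pt)
  keep <- nzchar(pt)
  out <- data.table::data.table(primaryid = r$primaryid[keep],
                                pt_raw = pt[keep])
  data.table::setattr(out, "n_empty", sum(!keep))
  out
}

#' Typed outcome mentions from a loaded package
#'
#' @param pkg a `faers_package`.
#' @return `data.table` with `primaryid`, `outcome_code` restricted to the
#'   FAERS closed set (DE, LT, HO, DS, CA, RI, OT); other codes are dropped
#'   and counted in attribute `n_bad_code`.
#' @export
outcome_mentions <- function(pkg) {
  stopifnot(inherits(pkg, "faers_package"))
  if (!nrow(pkg$outc)) {
    out <- data.table::data.table(primaryid = character(0),
                                  outcome_code = character(0))
    data.table::setattr(out, "n_bad_code", 0L)
    return(out)
  }
  code <- toupper(trimws(pkg$outc$outc_cod))
  ok <- code %in% c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  out <- data.table::data.table(primaryid = pkg$outc$primaryid[ok],
                                outcome_code = code[ok])
  data.table::setattr(out, "n_bad_code", sum(!ok))
  out
}

#' Write analysis result tables
#'
#' Writes each element of a named list as `<name>.tsv` under `directory`,
#' rounding numeric columns to `digits` decimals (the signal tables are
#' conventionally reported at 2 decimals; the default of 4 keeps enough
#' precision for round-tripping).
#'
#' @param results named list of data.frames/data.tables.
#' @param directory output directory (created if needed).
#' @param digits decimal places for numeric columns; `NULL` writes full
#'   precision.
#' @return invisibly, the paths written.
#' @export
write_analysis_tables <- function(results, directory, digits = 4) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) {
    stop(errorCondition(paste0("cannot create directory: ", directory),
                        class = c("faers_io_error", "error", "condition")))
  }
  paths <- character(0)
  for (nm in names(results)) {
    dt <- data.table::as.data.table(data.table::copy(results[[nm]]))
    if (!is.null(digits)) {
      num <- names(dt)[vapply(dt, is.double, logical(1))]
      for (cn in num) data.table::set(dt, j = cn, value = round(dt[[cn]],
                                                                digits))
    }
    path <- file.path(directory, paste0(nm, ".tsv"))
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back an analysis result table
#'
#' @param path a TSV written by [write_analysis_tables()].
#' @return `data.table`.
#' @export
read_analysis_table <- function(path) {
  data.table::fread(path, sep = "\t")
}
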