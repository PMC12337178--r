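#' Deduplicate safety reports and drop deleted cases
#'
#' Spontaneous-report databases re-submit the same case across quarters under
#' new PRIMARYIDs. Following FDA practice, exactly one report per CASEID is
#' kept -- the one with the largest PRIMARYID (the most recent version) --
#' and any CASEID on the deleted-cases list is removed entirely. PRIMARYIDs
#' are compared numerically when both parse as integers, otherwise
#' lexicographically on zero-padded strings.
#'
#' The operation is idempotent and independent of input row order.
#'
#' @param reports `data.table` with at least `caseid` and `primaryid`.
#' @param deleted_caseids character vector of CASEIDs to remove.
#' @return the retained rows, with attribute `removed`: a named integer
#'   vector counting removals by reason (`duplicate`, `deleted`).
#' @export
deduplicate_reports <- function(reports, deleted_caseids = character(0)) {
  dt <- data.table::as.data.table(reports)
  if (nrow(dt) == 0L) {
    data.table::setattr(dt, "removed", c(duplicate = 0L, deleted = 0L))
    return(dt)
  }
  stopifnot(all(c("caseid", "primaryid") %in% names(dt)))
  n0 <- nrow(dt)
  del <- dt$caseid %in% deleted_caseids
  dt <- dt[!del]
  n_deleted <- sum(del)

  pid <- suppressWarnings(as.numeric(dt$primaryid))
  if (anyNA(pid)) {
    # non-numeric IDs: compare as zero-padded strings
    w <- max(nchar(dt$primaryid))
    key <- formatC(dt$primaryid, width = w, flag = "0")
  } else {
    key <- pid
  }
  ord <- order(dt$caseid, key)
  dt <- dt[ord]
  keep <- !base::duplicated(dt$caseid, fromLast = TRUE)
  out <- dt[keep]
  data.table::setattr(out, "removed",
                      c(duplicate = as.integer(sum(!keep)),
                        deleted = as.integer(n_deleted)))
  out[]
}

# strip dose/form suffixes, fold case, collapse whitespace
normalize_drug_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  form_tokens <- c("tablet[s]?", "capsule[s]?", "injection", "solution",
                   "oral", "cream", "syrup", "film.?coated")
  dose_re <- "[0-9]+(\\.[0-9]+)?\\s*(mg|mcg|g|ml|iu|%)"
  repeat {
    new <- sub(paste0("\\s+(", paste(form_tokens, collapse = "|"), ")$"),
               "", x)
    new <- sub(paste0("\\s+", dose_re, "$"), "", new)
    if (identical(new, x)) break
    x <- new
  }
  x
}

#' Fuzzy match a reported drug name against target names
#'
#' Reported drug names are free text ("VONJO 200MG CAPSULE",
#' "pacritinib citrate", typos). A name matches when, after normalization
#' (case-fold, trim, whitespace collapse, stripping trailing dose/form
#' tokens), any target name is a substring, or the normalized Levenshtein
#' distance (edit distance divided by the longer length) to a target is at
#' most `threshold`.
#'
#' @param name_raw character vector of reported names.
#' @param names target name(s), e.g. generic and brand name.
#' @param threshold normalized edit-distance threshold (default 0.1).
#' @param substring_match also accept substring containment (default TRUE).
#' @return logical vector.
#' @export
match_drug_name <- function(name_raw, names,
                            threshold = 0.1, substring_match = TRUE) {
  stopifnot(length(names) >= 1, threshold >= 0, threshold <= 1)
  x <- normalize_drug_name(name_raw)
  tg <- normalize_drug_name(names)
  hit <- rep(FALSE, length(x))
  for (t in tg) {
    if (substring_match) hit <- hit | grepl(t, x, fixed = TRUE)
    d <- utils::adist(x, t)[, 1]
    nd <- d / pmax(nchar(x), nchar(t))
    hit <- hit | (nd <= threshold)
  }
  hit
}

#' Select the primary-suspect cohort for a target drug
#'
#' A report enters the cohort when at least one of its drug rows both
#' matches the target name rule and carries role code 1 (primary suspect) on
#' that same row. Rows where the target appears only as concomitant (2) or
#' interacting (3) never qualify a report.
#'
#' @param mentions drug mentions (`primaryid`, `name_raw`, `role_code`),
#'   e.g. from [drug_mentions()].
#' @param names,threshold,substring_match passed to [match_drug_name()].
#' @return character vector of qualifying `primaryid`s (unique, sorted).
#' @export
select_primary_suspect <- function(mentions, names, threshold = 0.1,
                                   substring_match = TRUE) {
  dt <- data.table::as.data.table(mentions)
  if (!nrow(dt)) return(character(0))
  m <- match_drug_name(dt$name_raw, names, threshold, substring_match)
  ps <- !is.na(dt$role_code) & dt$role_code == 1L
  sort(unique(dt$primaryid[m & ps]))
}

#' Build the analysis cohort from a loaded package
#'
#' Runs the full filter chain: deduplicate by CASEID (keeping the largest
#' PRIMARYID), remove deleted cases, then select reports naming the target
#' drug as primary suspect. Deduplication runs before drug filtering, so a
#' case is judged on its most recent version.
#'
#' @param pkg a `faers_package`.
#' @param target_names target drug name(s).
#' @param threshold,substring_match fuzzy-match settings
#'   (see [match_drug_name()]).
#' @return list with `reports` (deduplicated typed safety reports, all
#'   drugs), `cohort_primaryids`, `drug` / `reac` / `outc` typed mention
#'   tables restricted to deduplicated reports, and `funnel`: named counts
#'   at each stage (loaded, after-dedup, deleted-removed, cohort).
#' @export
build_cohort <- function(pkg, target_names, threshold = 0.1,
                         substring_match = TRUE) {
  stopifnot(inherits(pkg, "faers_package"))
  reports <- safety_reports(pkg)
  n_loaded <- nrow(reports)
  reports <- deduplicate_reports(reports, pkg$deleted_caseids)
  removed <- attr(reports, "removed")

  keep_ids <- reports$primaryid
  drug <- drug_mentions(pkg)[primaryid %in% keep_ids]
  reac <- reaction_mentions(pkg)[primaryid %in% keep_ids]
  outc <- outcome_mentions(pkg)[primaryid %in% keep_ids]

  cohort <- select_primary_suspect(drug, target_names, threshold,
                                   substring_match)
  list(reports = reports, cohort_primaryids = cohort,
       drug = drug, reac = reac, outc = outc,
       funnel = c(loaded = n_loaded,
                  duplicates_removed = unname(removed["duplicate"]),
                  deleted_removed = unname(removed["deleted"]),
                  after_dedup = nrow(reports),
                  cohort = length(cohort)))
}
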