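#' Load a MedDRA-style vocabulary
#'
#' Reads a delimiter-separated vocabulary with columns `llt_or_pt`, `pt`,
#' `soc`: one row per preferred term (identity row) plus one row per
#' lowest-level-term synonym. Real MedDRA is licensed and cannot be bundled;
#' the package ships a small synthetic vocabulary
#' (`system.file("extdata", "mock_meddra.tsv", package = "faersignal")`)
#' covering the system organ classes and preferred terms a myelofibrosis
#' pharmacovigilance analysis touches. A user-supplied MedDRA export in the
#' same two-level format can be loaded instead.
#'
#' Lookups are case-insensitive and whitespace-collapsed. Every PT maps to
#' exactly one primary SOC (multi-axial secondary SOCs are out of scope).
#'
#' @param path vocabulary file; defaults to the bundled synthetic vocabulary.
#' @param sep field separator (tab by default).
#' @return An object of class `faers_vocabulary`: a list with `terms`
#'   (the raw table), `pt` (canonical PT vector) and internal lookup tables.
#' @export
load_vocabulary <- function(path = NULL, sep = "\t") {
  if (is.null(path)) {
    path <- system.file("extdata", "mock_meddra.tsv", package = "faersignal")
  }
  if (!file.exists(path)) {
    stop(errorCondition(paste0("vocabulary file not found: ", path),
                        class = c("faers_io_error", "error", "condition")))
  }
  tab <- data.table::fread(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "")
  need <- c("llt_or_pt", "pt", "soc")
  if (!all(need %in% names(tab))) {
    stop(errorCondition(
      paste0("vocabulary must have columns: ", paste(need, collapse = ", ")),
      class = c("faers_vocab_error", "error", "condition")))
  }
  key <- vocab_key(tab$llt_or_pt)
  if (anyDuplicated(key)) {
    stop(errorCondition("duplicate llt_or_pt entries in vocabulary",
                        class = c("faers_vocab_error", "error", "condition")))
  }
  pts <- sort(unique(tab$pt))
  pt_soc <- unique(tab[, c("pt", "soc")])
  if (anyDuplicated(pt_soc$pt)) {
    stop(errorCondition("a PT maps to more than one SOC",
                        class = c("faers_vocab_error", "error", "condition")))
  }
  structure(list(
    terms = tab,
    pt = pts,
    soc = sort(unique(tab$soc)),
    lookup_pt = stats::setNames(tab$pt, key),
    lookup_soc = stats::setNames(pt_soc$soc, vocab_key(pt_soc$pt))
  ), class = "faers_vocabulary")
}

vocab_key <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Normalize reported reaction terms to canonical preferred terms
#'
#' Case-insensitive, whitespace-collapsed lookup through the LLT synonym
#' table to the canonical PT. Terms absent from the vocabulary are returned
#' as-is (trimmed) with `mapped = FALSE` so that unmapped terms stay visible
#' downstream rather than being dropped.
#'
#' @param pt_raw character vector of reported reaction terms.
#' @param vocab a `faers_vocabulary`.
#' @return `data.table` with columns `pt` (canonical or as-reported) and
#'   `mapped` (logical); attribute `n_unmapped` counts misses.
#' @export
normalize_pt <- function(pt_raw, vocab) {
  stopifnot(inherits(vocab, "faers_vocabulary"))
  raw <- trimws(as.character(pt_raw))
  hit <- vocab$lookup_pt[vocab_key(raw)]
  mapped <- !is.na(hit)
  out <- data.table::data.table(pt = ifelse(mapped, hit, raw),
                                mapped = mapped)
  data.table::setattr(out, "n_unmapped", sum(!mapped))
  out
}

#' Map canonical preferred terms to their primary system organ class
#'
#' @param pt character vector of canonical PTs.
#' @param vocab a `faers_vocabulary`.
#' @return character vector of SOC names; PTs absent from the vocabulary get
#'   the explicit `"Unmapped"` bucket rather than `NA`, so SOC-level counts
#'   remain a partition of the PT-level counts.
#' @export
pt_to_soc <- function(pt, vocab) {
  stopifnot(inherits(vocab, "faers_vocabulary"))
  soc <- vocab$lookup_soc[vocab_key(pt)]
  soc[is.na(soc)] <- "Unmapped"
  unname(soc)
}

#' @export
print.faers_vocabulary <- function(x, ...) {
  cat("faers_vocabulary:", length(x$pt), "PTs,", length(x$soc), "SOCs,",
      nrow(x$terms) - length(x$pt), "LLT synonyms\n")
  invisible(x)
}
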