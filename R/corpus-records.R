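# Bibliographic record handling: DOI normalisation, within-source
# deduplication and precision-first cross-source record linkage.

#' Canonicalise DOIs
#'
#' Lower-cases, trims surrounding whitespace and removes a leading
#' `doi:` prefix (case-insensitive). Empty results become `NA`.
#'
#' @param raw character vector of raw DOI strings (may contain NA).
#' @return character vector of canonical DOIs, `NA` where empty/missing.
#' @export
#' @examples
#' normalize_doi(c("DOI:10.1000/ABC", "  10.1/x ", "", NA))
normalize_doi <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- tolower(trimws(as.character(raw)))
  x <- sub("^doi:\\s*", "", x)
  x <- trimws(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  x
}

.record_columns <- c("record_id", "source", "doi", "title", "abstract", "year")

.check_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(c("record_id", "source", "title", "year"), names(records))
  if (length(missing)) {
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"doi" %in% names(records)) records$doi <- NA_character_
  if (!"abstract" %in% names(records)) records$abstract <- ""
  if (any(!nzchar(records$record_id) | is.na(records$record_id))) {
    stop("every record needs a non-empty record_id")
  }
  yr <- records$year
  bad <- !is.na(yr) & (yr < 1900 | yr > 2100)
  if (any(bad)) stop("year outside [1900, 2100] for ", sum(bad), " record(s)")
  records
}

#' Read bibliographic export records from CSV
#'
#' Reads a UTF-8 CSV with a header row; `col_map` renames the export's
#' columns onto the canonical names `record_id`, `source`, `doi`, `title`,
#' `abstract`, `year`, `doc_type`, `language`, `country_text`.
#'
#' @param path path to a CSV file.
#' @param col_map named character vector, `canonical = file_column`.
#' @return data.frame of source records.
#' @export
read_source_records <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      from <- col_map[[canonical]]
      if (!from %in% names(df)) stop("column '", from, "' not found in ", path)
      names(df)[names(df) == from] <- canonical
    }
  }
  df$year <- suppressWarnings(as.integer(df$year))
  .check_records(df)
}

#' Remove duplicate records within one bibliographic source
#'
#' Keeps the first record per native identifier (UT / EID), then -- among the
#' survivors -- the first record per non-missing canonical DOI. Input order is
#' otherwise preserved and the operation is idempotent.
#'
#' @param records data.frame of records sharing one `source` tag.
#' @return deduplicated data.frame.
#' @export
dedup_within_source <- function(records) {
  records <- .check_records(records)
  if (length(unique(records$source)) > 1L) {
    stop("dedup_within_source() expects records from a single source, got: ",
         paste(unique(records$source), collapse = ", "))
  }
  records <- records[!duplicated(records$record_id), , drop = FALSE]
  doi <- normalize_doi(records$doi)
  records$doi <- doi
  dup_doi <- duplicated(doi, incomparables = NA)
  records <- records[!dup_doi, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Token-set title similarity
#'
#' Similarity between two titles as the number of shared lower-case tokens
#' divided by the size of the smaller token set (token-set ratio). Used for
#' the title-and-year step of cross-source matching.
#'
#' @param a,b character strings.
#' @return similarity in `[0, 1]` (0 when either title has no tokens).
#' @export
title_similarity <- function(a, b) {
  ta <- unique(.title_tokens(a))
  tb <- unique(.title_tokens(b))
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  length(intersect(ta, tb)) / min(length(ta), length(tb))
}

.title_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  x <- tolower(gsub("[^a-z0-9]+", " ", tolower(x)))
  toks <- strsplit(trimws(x), " +")[[1]]
  toks[nzchar(toks)]
}

#' Link records across two bibliographic sources
#'
#' Two-step precision-first matcher: records are first merged exactly on
#' canonical DOI; the remainder are grouped by identical publication year and
#' linked greedily (best similarity first, ties by input order) when the
#' token-set title similarity reaches `sim_threshold`, each record being
#' linked at most once. The result partitions the union into matched,
#' WoS-only and Scopus-only sets and carries one unified document per match.
#'
#' @param wos,scopus data.frames of within-source deduplicated records.
#' @param sim_threshold similarity threshold in `(0, 1]` (default 0.9).
#' @return object of class `cross_source_match`: list with `documents` (one
#'   row per unified document: `doc_id`, `provenance`, `year`, `title`,
#'   `abstract`, `doi`), `n_intersection`, `n_wos_only`, `n_scopus_only`,
#'   `n_union` and the matched id `pairs`.
#' @export
match_cross_source <- function(wos, scopus, sim_threshold = 0.9) {
  if (!is.numeric(sim_threshold) || length(sim_threshold) != 1L ||
      sim_threshold <= 0 || sim_threshold > 1) {
    stop("sim_threshold must lie in (0, 1]")
  }
  wos <- .check_records(wos)
  scopus <- .check_records(scopus)
  wos$doi <- normalize_doi(wos$doi)
  scopus$doi <- normalize_doi(scopus$doi)

  w_match <- integer(0)  # row indices in wos
  s_match <- integer(0)  # matching row indices in scopus

  # step 1: exact merge on canonical DOI
  shared <- intersect(wos$doi[!is.na(wos$doi)], scopus$doi[!is.na(scopus$doi)])
  if (length(shared)) {
    w_match <- match(shared, wos$doi)
    s_match <- match(shared, scopus$doi)
  }

  # step 2: title similarity within identical publication year
  w_rest <- setdiff(seq_len(nrow(wos)), w_match)
  s_rest <- setdiff(seq_len(nrow(scopus)), s_match)
  years <- intersect(unique(wos$year[w_rest]), unique(scopus$year[s_rest]))
  years <- years[!is.na(years)]
  for (yr in years) {
    wi <- w_rest[!is.na(wos$year[w_rest]) & wos$year[w_rest] == yr]
    si <- s_rest[!is.na(scopus$year[s_rest]) & scopus$year[s_rest] == yr]
    if (!length(wi) || !length(si)) next
    cand <- expand.grid(w = wi, s = si, KEEP.OUT.ATTRS = FALSE)
    cand$sim <- mapply(function(i, j) title_similarity(wos$title[i], scopus$title[j]),
                       cand$w, cand$s)
    cand <- cand[cand$sim >= sim_threshold, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$sim, cand$w, cand$s), , drop = FALSE]
    used_w <- logical(nrow(wos)); used_s <- logical(nrow(scopus))
    for (r in seq_len(nrow(cand))) {
      i <- cand$w[r]; j <- cand$s[r]
      if (!used_w[i] && !used_s[j]) {
        used_w[i] <- TRUE; used_s[j] <- TRUE
        w_match <- c(w_match, i); s_match <- c(s_match, j)
      }
    }
  }

  w_only <- setdiff(seq_len(nrow(wos)), w_match)
  s_only <- setdiff(seq_len(nrow(scopus)), s_match)

  doc_row <- function(id, provenance, rec, doi) {
    data.frame(doc_id = id, provenance = provenance, year = rec$year,
               title = rec$title, abstract = rec$abstract, doi = doi,
               stringsAsFactors = FALSE)
  }
  docs <- rbind(
    if (length(w_match)) data.frame(
      doc_id = wos$record_id[w_match], provenance = "both",
      year = wos$year[w_match], title = wos$title[w_match],
      abstract = wos$abstract[w_match],
      doi = ifelse(is.na(wos$doi[w_match]), scopus$doi[s_match], wos$doi[w_match]),
      stringsAsFactors = FALSE),
    if (length(w_only)) data.frame(
      doc_id = wos$record_id[w_only], provenance = "wos_only",
      year = wos$year[w_only], title = wos$title[w_only],
      abstract = wos$abstract[w_only], doi = wos$doi[w_only],
      stringsAsFactors = FALSE),
    if (length(s_only)) data.frame(
      doc_id = scopus$record_id[s_only], provenance = "scopus_only",
      year = scopus$year[s_only], title = scopus$title[s_only],
      abstract = scopus$abstract[s_only], doi = scopus$doi[s_only],
      stringsAsFactors = FALSE)
  )
  if (anyDuplicated(docs$doc_id)) {
    docs$doc_id <- make.unique(docs$doc_id, sep = "#")
  }
  rownames(docs) <- NULL
  out <- list(
    documents = docs,
    n_intersection = length(w_match),
    n_wos_only = length(w_only),
    n_scopus_only = length(s_only),
    n_union = nrow(docs),
    pairs = data.frame(wos_id = wos$record_id[w_match],
                       scopus_id = scopus$record_id[s_match],
                       stringsAsFactors = FALSE),
    sim_threshold = sim_threshold
  )
  class(out) <- "cross_source_match"
  out
}

#' @export
print.cross_source_match <- function(x, ...) {
  cat("Cross-source match:", x$n_union, "unique documents\n")
  cat("  intersection:", x$n_intersection,
      " wos-only:", x$n_wos_only,
      " scopus-only:", x$n_scopus_only, "\n")
  invisible(x)
}
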