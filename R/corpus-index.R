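# Porter-stemmed inverted index with token positions, and the genus
# mention counter built on top of it.

#' Build a Porter-stemmed inverted index over documents
#'
#' Concatenates title and abstract per document, tokenises and stems, and
#' maps every stemmed token to the documents (and token positions) where it
#' appears. Positions make consecutive-token phrase matching possible, which
#' keeps multi-word aliases ("honey bee") from firing on scattered tokens.
#'
#' @param docs data.frame with `doc_id`, `title`, `abstract` (or a single
#'   `text` column) and optionally `year`.
#' @return object of class `inverted_index`: list with `postings`
#'   (environment: token -> list(doc = integer, pos = integer)), `doc_ids`,
#'   `years`, `n_tokens`.
#' @export
build_inverted_index <- function(docs) {
  stopifnot(is.data.frame(docs), "doc_id" %in% names(docs))
  if (anyDuplicated(docs$doc_id)) {
    stop("duplicate doc_id: ",
         paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "))
  }
  text <- if ("text" %in% names(docs)) {
    docs$text
  } else {
    paste(ifelse(is.na(docs$title), "", docs$title),
          ifelse(is.na(docs$abstract), "", docs$abstract))
  }
  n <- nrow(docs)
  tok_doc <- vector("list", n)
  for (i in seq_len(n)) tok_doc[[i]] <- tokenize_and_stem(text[[i]])
  lens <- lengths(tok_doc)
  long_tok <- unlist(tok_doc, use.names = FALSE)
  long_doc <- rep.int(seq_len(n), lens)
  long_pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  postings <- new.env(parent = emptyenv(), size = max(16L, length(unique(long_tok))))
  if (length(long_tok)) {
    split_idx <- split(seq_along(long_tok), long_tok)
    for (tok in names(split_idx)) {
      idx <- split_idx[[tok]]
      assign(tok, list(doc = long_doc[idx], pos = long_pos[idx]), envir = postings)
    }
  }
  out <- list(
    postings = postings,
    doc_ids = docs$doc_id,
    years = if ("year" %in% names(docs)) docs$year else rep(NA_integer_, n),
    n_tokens = sum(lens)
  )
  class(out) <- "inverted_index"
  out
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("Inverted index:", length(x$doc_ids), "documents,",
      length(ls(x$postings)), "distinct stemmed tokens\n")
  invisible(x)
}

#' Look up the documents containing a stemmed token
#'
#' @param index an `inverted_index`.
#' @param token a single stemmed token.
#' @return character vector of doc_ids (empty for unseen tokens),
#'   duplicate-free and in document order.
#' @export
index_lookup <- function(index, token) {
  stopifnot(inherits(index, "inverted_index"), length(token) == 1L)
  p <- get0(token, envir = index$postings, ifnotfound = NULL)
  if (is.null(p)) return(character(0))
  index$doc_ids[sort(unique(p$doc))]
}

# internal: integer doc indices where the stemmed token sequence occurs
# consecutively
.phrase_doc_idx <- function(index, tokens) {
  if (length(tokens) == 0L) return(integer(0))
  p <- get0(tokens[[1L]], envir = index$postings, ifnotfound = NULL)
  if (is.null(p)) return(integer(0))
  # key encodes (doc, start position of the would-be phrase)
  keys <- p$doc * 1e7 + p$pos
  for (k in seq_along(tokens)[-1L]) {
    pk <- get0(tokens[[k]], envir = index$postings, ifnotfound = NULL)
    if (is.null(pk)) return(integer(0))
    keys <- keys[keys %in% (pk$doc * 1e7 + pk$pos - (k - 1L))]
    if (!length(keys)) return(integer(0))
  }
  sort(unique(keys %/% 1e7))
}

#' Count genus mentions per publication year
#'
#' A document mentions a genus iff any alias phrase of that genus occurs as
#' consecutive stemmed tokens in its indexed text; each document then
#' contributes at most one count to each mentioned genus, whatever the number
#' of occurrences. Mode `"high_confidence"` excludes the inherently ambiguous
#' binomial-abbreviation aliases. Documents without a year are kept under a
#' sentinel `NA` year bucket (and reported via a message) so no mention is
#' silently lost; year-indexed models drop that bucket downstream.
#'
#' @param index an `inverted_index` built with [build_inverted_index()].
#' @param lib an `alias_library` built with [build_alias_library()]
#'   (sharing the same stemming convention, which both do by construction).
#' @param mode `"full"` (all aliases) or `"high_confidence"` (no
#'   abbreviations).
#' @return object of class `genus_year_counts`: list with `counts`
#'   (data.frame `genus`, `year`, `count`), `cooccurrence` (data.frame
#'   `genus_a < genus_b`, `count`), and `doc_genus` (data.frame `doc_id`,
#'   `genus`).
#' @export
count_genus_mentions <- function(index, lib, mode = c("full", "high_confidence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "inverted_index"), inherits(lib, "alias_library"))
  aliases <- lib$aliases
  if (mode == "high_confidence") {
    aliases <- aliases[aliases$alias_class != "abbreviation", , drop = FALSE]
  }
  hits <- vector("list", nrow(aliases))
  for (r in seq_len(nrow(aliases))) {
    toks <- strsplit(aliases$stemmed[r], " ", fixed = TRUE)[[1]]
    idx <- .phrase_doc_idx(index, toks)
    if (length(idx)) {
      hits[[r]] <- data.frame(doc = idx, genus = aliases$genus[r],
                              stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(doc = integer(0), genus = character(0),
                       stringsAsFactors = FALSE)
  }
  hits <- unique(hits)
  hits <- hits[order(hits$doc, hits$genus), , drop = FALSE]
  hits$year <- index$years[hits$doc]
  n_noyear <- length(unique(hits$doc[is.na(hits$year)]))
  if (n_noyear > 0L) {
    message(n_noyear, " document(s) without a year counted under the NA-year bucket")
  }
  if (nrow(hits)) {
    key <- split(seq_len(nrow(hits)), paste(hits$genus, hits$year, sep = "\r"))
    counts <- data.frame(
      genus = vapply(key, function(i) hits$genus[i[1L]], character(1)),
      year = vapply(key, function(i) hits$year[i[1L]], integer(1)),
      count = lengths(key), stringsAsFactors = FALSE)
    counts <- counts[order(counts$genus, counts$year), , drop = FALSE]
  } else {
    counts <- data.frame(genus = character(0), year = integer(0),
                         count = integer(0), stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL

  co <- list()
  for (d in unique(hits$doc)) {
    gs <- sort(unique(hits$genus[hits$doc == d]))
    if (length(gs) >= 2L) {
      prs <- utils::combn(gs, 2L)
      co[[length(co) + 1L]] <- data.frame(genus_a = prs[1L, ], genus_b = prs[2L, ],
                                          stringsAsFactors = FALSE)
    }
  }
  co <- do.call(rbind, co)
  if (is.null(co)) {
    cooc <- data.frame(genus_a = character(0), genus_b = character(0),
                       count = integer(0), stringsAsFactors = FALSE)
  } else {
    cooc <- aggregate(list(count = rep(1L, nrow(co))),
                      by = co[c("genus_a", "genus_b")], FUN = sum)
    cooc <- cooc[order(cooc$genus_a, cooc$genus_b), , drop = FALSE]
    rownames(cooc) <- NULL
  }
  out <- list(
    counts = counts,
    cooccurrence = cooc,
    doc_genus = data.frame(doc_id = index$doc_ids[hits$doc], genus = hits$genus,
                           year = hits$year, stringsAsFactors = FALSE),
    mode = mode
  )
  class(out) <- "genus_year_counts"
  out
}

#' @export
print.genus_year_counts <- function(x, ...) {
  cat("Genus-year counts (mode =", x$mode, "):",
      length(unique(x$counts$genus)), "genera,",
      sum(x$counts$count), "genus-document mentions\n")
  invisible(x)
}

#' Total papers per genus across years
#'
#' @param gyc a `genus_year_counts` object.
#' @param drop_unknown_year drop the sentinel NA-year bucket (default FALSE).
#' @return named integer vector, genus -> total count.
#' @export
genus_totals <- function(gyc, drop_unknown_year = FALSE) {
  stopifnot(inherits(gyc, "genus_year_counts"))
  cc <- gyc$counts
  if (drop_unknown_year) cc <- cc[!is.na(cc$year), , drop = FALSE]
  tapply(cc$count, cc$genus, sum)[unique(cc$genus)]
}

#' Exact-match country extraction
#'
#' Conservative geographic assignment: only case-insensitive whole-phrase
#' matches against the gazetteer count; no fuzzy matching. Used on
#' affiliation / country text fields.
#'
#' @param text a single character string.
#' @param gazetteer named character vector, country name (canonical or
#'   alternative) -> ISO3 code.
#' @return sorted character vector of unique ISO3 codes (possibly empty).
#' @export
#' @examples
#' match_countries("sampled in Brazil and the USA",
#'                 c(Brazil = "BRA", USA = "USA"))
match_countries <- function(text, gazetteer) {
  stopifnot(length(text) == 1L, is.character(gazetteer), !is.null(names(gazetteer)))
  if (is.na(text) || !nzchar(text)) return(character(0))
  txt <- tolower(text)
  hit <- vapply(names(gazetteer), function(nm) {
    pat <- paste0("(?<![a-z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tolower(nm)),
                  "(?![a-z0-9])")
    grepl(pat, txt, perl = TRUE)
  }, logical(1))
  sort(unique(unname(gazetteer[hit])))
}

#' Compare automated genus counts with manual reference counts
#'
#' Validation harness for the counting engine: Spearman rank correlation
#' (average ranks on ties), Pearson correlation, mean absolute error, root
#' mean squared error, and the OLS slope of manual on automated counts. When
#' a labelled precision sample is supplied (logical vector: detection
#' correct?), precision and its Wilson score interval are added.
#'
#' @param auto named numeric vector of automated counts per genus.
#' @param manual named numeric vector of manual counts; names must overlap
#'   `auto` in at least 3 genera.
#' @param labelled_sample optional logical vector of manually checked
#'   detections.
#' @param conf confidence level for the Wilson interval (default 0.95).
#' @return object of class `validation_report`.
#' @export
validate_counts <- function(auto, manual, labelled_sample = NULL, conf = 0.95) {
  shared <- intersect(names(auto), names(manual))
  if (length(shared) < 3L) stop("need at least 3 shared genus keys")
  a <- as.numeric(auto[shared])
  m <- as.numeric(manual[shared])
  sp <- spearman_cor(a, m)
  fit <- stats::lm(m ~ a)
  out <- list(
    n_genera = length(shared),
    spearman_rho = sp$rho,
    pearson_r = stats::cor(a, m),
    mae = mean(abs(a - m)),
    rmse = sqrt(mean((a - m)^2)),
    ols_slope = unname(stats::coef(fit)[2L]),
    ols_intercept = unname(stats::coef(fit)[1L])
  )
  if (!is.null(labelled_sample)) {
    stopifnot(is.logical(labelled_sample), length(labelled_sample) > 0L)
    x <- sum(labelled_sample); n <- length(labelled_sample)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ph <- x / n
    centre <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    out$precision <- ph
    out$precision_ci <- c(lower = max(0, centre - half),
                          upper = min(1, centre + half))
  }
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Count validation over", x$n_genera, "genera\n")
  cat(sprintf("  Spearman rho %.3f | Pearson r %.3f\n", x$spearman_rho, x$pearson_r))
  cat(sprintf("  MAE %.1f papers | RMSE %.1f papers | OLS slope %.3f\n",
              x$mae, x$rmse, x$ols_slope))
  if (!is.null(x$precision)) {
    cat(sprintf("  precision %.3f (%.3f-%.3f)\n", x$precision,
                x$precision_ci[1], x$precision_ci[2]))
  }
  invisible(x)
}
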