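# Text normalisation: tokenisation and Porter stemming.
#
# The stemmer is the original Porter (1980) algorithm. It is implemented here
# because the matching convention of the whole counting pipeline -- alias
# phrases and document text must be reduced identically -- is part of the
# method, and the environment ships no stemming library.

.vowels <- c("a", "e", "i", "o", "u")

# consonant/vowel pattern of a word; 'y' is a vowel iff preceded by a consonant
.cv_pattern <- function(chars) {
  n <- length(chars)
  out <- character(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% .vowels) {
      out[i] <- "v"
    } else if (ch == "y") {
      out[i] <- if (i > 1L && out[i - 1L] == "v") "c" else if (i > 1L) "v" else "c"
    } else {
      out[i] <- "c"
    }
  }
  out
}

# Porter's measure m: number of vc sequences in [c](vc)^m[v]
.measure <- function(word) {
  if (!nzchar(word)) return(0L)
  pat <- paste(.cv_pattern(strsplit(word, "", fixed = TRUE)[[1]]), collapse = "")
  runs <- gsub("(.)\\1+", "\\1", pat)
  length(gregexpr("vc", runs, fixed = TRUE)[[1]][gregexpr("vc", runs, fixed = TRUE)[[1]] > 0])
}

.contains_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(.cv_pattern(strsplit(word, "", fixed = TRUE)[[1]]) == "v")
}

.ends_double_consonant <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  a == b && !(b %in% .vowels)
}

# *o condition: stem ends cvc where the final c is not w, x or y
.ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  pat <- .cv_pattern(chars)
  last <- chars[n]
  pat[n] == "c" && pat[n - 1L] == "v" && pat[n - 2L] == "c" && !(last %in% c("w", "x", "y"))
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

.step1a <- function(w) {
  if (endsWith(w, "sses")) return(.chop(w, 2L))
  if (endsWith(w, "ies")) return(.chop(w, 2L))
  if (endsWith(w, "ss")) return(w)
  if (endsWith(w, "s")) return(.chop(w, 1L))
  w
}

.step1b <- function(w) {
  if (endsWith(w, "eed")) {
    stem <- .chop(w, 3L)
    if (.measure(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  fixed <- FALSE
  if (endsWith(w, "ed")) {
    stem <- .chop(w, 2L)
    if (.contains_vowel(stem)) { w <- stem; fixed <- TRUE }
  } else if (endsWith(w, "ing")) {
    stem <- .chop(w, 3L)
    if (.contains_vowel(stem)) { w <- stem; fixed <- TRUE }
  }
  if (fixed) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.ends_double_consonant(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- .chop(w, 1L)
    } else if (.measure(w) == 1L && .ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.step1c <- function(w) {
  if (endsWith(w, "y") && .contains_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }
  w
}

.step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

.step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.apply_rule_set <- function(w, rules, min_m) {
  # longest matching suffix decides; its condition is then tested once
  lens <- vapply(rules, function(r) nchar(r[[1L]]), integer(1))
  for (i in order(lens, decreasing = TRUE)) {
    suf <- rules[[i]][[1L]]
    if (endsWith(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.measure(stem) > min_m - 1L) w <- paste0(stem, rules[[i]][[2L]])
      return(w)
    }
  }
  w
}

.step4_suffixes <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                     "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                     "ous", "ive", "ize")

.step4 <- function(w) {
  for (suf in .step4_suffixes[order(nchar(.step4_suffixes), decreasing = TRUE)]) {
    if (endsWith(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (suf == "ion" &&
          !(endsWith(stem, "s") || endsWith(stem, "t"))) {
        return(w)
      }
      if (.measure(stem) > 1L) return(stem)
      return(w)
    }
  }
  w
}

.step5a <- function(w) {
  if (endsWith(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) return(stem)
  }
  w
}

.step5b <- function(w) {
  if (.measure(w) > 1L && .ends_double_consonant(w) && endsWith(w, "l")) {
    return(.chop(w, 1L))
  }
  w
}

.porter_one <- function(w) {
  if (nchar(w) <= 2L) return(w)
  w <- .step1a(w)
  w <- .step1b(w)
  w <- .step1c(w)
  w <- .apply_rule_set(w, .step2_rules, min_m = 1L)
  w <- .apply_rule_set(w, .step3_rules, min_m = 1L)
  w <- .step4(w)
  w <- .step5a(w)
  .step5b(w)
}

#' Porter-stem a vector of lower-case words
#'
#' Applies the original Porter (1980) suffix-stripping algorithm, e.g.
#' `"pollinating"` becomes `"pollin"` and `"bees"` becomes `"bee"`. Words of
#' one or two characters are returned unchanged, as are tokens containing
#' digits.
#'
#' @param words character vector of tokens (assumed lower-case).
#' @return character vector of stems, same length as `words`.
#' @export
#' @examples
#' porter_stem(c("pollinating", "bees", "generalization"))
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  stopifnot(is.character(words))
  uw <- unique(words)
  stems <- vapply(uw, function(w) {
    if (grepl("[0-9]", w)) w else .porter_one(w)
  }, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}

#' Tokenise text and Porter-stem every token
#'
#' Lower-cases the input, strips punctuation (any character that is neither a
#' letter nor a digit becomes a separator), splits on whitespace and stems
#' each token. The convention is shared by document indexing and alias
#' preparation, so phrase matching happens in one common reduced vocabulary.
#'
#' @param text a single character string (NA is treated as empty).
#' @return character vector of stemmed tokens (possibly empty).
#' @export
#' @examples
#' tokenize_and_stem("Pollinating bees!")
tokenize_and_stem <- function(text) {
  if (length(text) != 1L) stop("tokenize_and_stem() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " +", perl = FALSE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(character(0))
  porter_stem(toks)
}
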