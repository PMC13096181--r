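# Alias library: per-genus search phrases (canonical names, binomial
# abbreviations, common names), stored both raw and Porter-stemmed.

#' Default common-name expansions
#'
#' The unambiguous vernacular names routinely used in the bee literature,
#' mapped to their genus: honey bee(s)/honeybee(s) for *Apis*, bumble
#' bee(s)/bumblebee(s) for *Bombus*, carpenter bee(s) for *Xylocopa*, mason
#' bee(s) for *Osmia*, leafcutter/leaf-cutting bee(s) for *Megachile* and
#' mining bee(s) for *Andrena*. Plurals need no separate entry: stemming
#' reduces "bees" to "bee".
#'
#' @return named list, genus -> character vector of common-name phrases.
#' @export
default_common_names <- function() {
  list(
    Apis      = c("honey bee", "honeybee"),
    Bombus    = c("bumble bee", "bumblebee"),
    Xylocopa  = c("carpenter bee"),
    Osmia     = c("mason bee"),
    Megachile = c("leafcutter bee", "leaf-cutting bee"),
    Andrena   = c("mining bee")
  )
}

.alias_delimiters <- "[;,/|]"

.split_multivalued <- function(x) {
  parts <- unlist(strsplit(x, .alias_delimiters))
  parts <- trimws(tolower(parts))
  parts[nzchar(parts)]
}

#' Build a genus alias library
#'
#' Assembles, for every genus in `genus_table`, the set of alias phrases used
#' by the counting engine: the canonical genus name itself, binomial
#' abbreviations generated from species names ("Apis mellifera" ->
#' "a. mellifera"), and configured common-name expansions. All text is
#' lower-cased and trimmed, multi-valued cells are split on the common
#' delimiters `; , / |`, and every alias is additionally stored as its
#' Porter-stemmed token sequence, the form actually matched against the
#' inverted index.
#'
#' A stemmed alias claimed by two genera is an error, except for binomial
#' abbreviations (inherently ambiguous, e.g. "a. ..."), which are dropped
#' from all claimants with a warning.
#'
#' @param genus_table data.frame with one row per genus; must contain
#'   `genus`, and typically `family`, `species_richness`, `managed`,
#'   `sociality`, `nesting`.
#' @param common_names named list genus -> character vector of phrases
#'   (cells may themselves be delimiter-joined); default
#'   [default_common_names()].
#' @param species_names named list genus -> character vector of species
#'   (either full binomials or bare epithets) used to generate
#'   abbreviations; `NULL` for none.
#' @return object of class `alias_library`: list with `aliases` (data.frame
#'   `genus`, `alias`, `alias_class`, `stemmed`) and `attributes`
#'   (the genus table).
#' @export
build_alias_library <- function(genus_table,
                                common_names = default_common_names(),
                                species_names = NULL) {
  stopifnot(is.data.frame(genus_table), "genus" %in% names(genus_table))
  if (anyDuplicated(genus_table$genus)) {
    stop("duplicate genus rows: ",
         paste(unique(genus_table$genus[duplicated(genus_table$genus)]),
               collapse = ", "))
  }
  rows <- list()
  add <- function(genus, alias, class) {
    alias <- trimws(tolower(alias))
    alias <- alias[nzchar(alias)]
    if (!length(alias)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      genus = genus, alias = alias, alias_class = class,
      stringsAsFactors = FALSE)
  }
  for (g in genus_table$genus) {
    add(g, g, "genus_name")
    cn <- common_names[[g]]
    if (!is.null(cn)) add(g, unlist(lapply(cn, .split_multivalued)), "common_name")
    sp <- species_names[[g]]
    if (!is.null(sp)) {
      sp <- unlist(lapply(sp, .split_multivalued))
      epithet <- vapply(strsplit(sp, "\\s+"), function(p) p[length(p)], character(1))
      abbr <- paste0(tolower(substr(g, 1L, 1L)), ". ", epithet)
      add(g, abbr, "abbreviation")
    }
  }
  aliases <- do.call(rbind, rows)
  aliases <- aliases[!duplicated(aliases[c("genus", "alias")]), , drop = FALSE]
  aliases$stemmed <- vapply(aliases$alias,
                            function(a) paste(tokenize_and_stem(a), collapse = " "),
                            character(1), USE.NAMES = FALSE)
  if (any(!nzchar(aliases$stemmed))) {
    stop("alias empty after normalisation: ",
         paste(aliases$alias[!nzchar(aliases$stemmed)], collapse = ", "))
  }
  # cross-genus collisions on the stemmed form
  tab <- unique(aliases[c("genus", "stemmed", "alias_class")])
  dup <- tab$stemmed[duplicated(tab$stemmed)]
  for (s in unique(dup)) {
    claimants <- tab[tab$stemmed == s, , drop = FALSE]
    if (length(unique(claimants$genus)) < 2L) next
    if (all(claimants$alias_class == "abbreviation")) {
      warning("ambiguous abbreviation '", s, "' claimed by ",
              paste(unique(claimants$genus), collapse = ", "),
              "; dropped from all", call. = FALSE)
      aliases <- aliases[!(aliases$stemmed == s &
                             aliases$alias_class == "abbreviation"), , drop = FALSE]
    } else {
      stop("alias '", s, "' maps to multiple genera: ",
           paste(unique(claimants$genus), collapse = ", "))
    }
  }
  rownames(aliases) <- NULL
  out <- list(aliases = aliases, attributes = genus_table)
  class(out) <- "alias_library"
  out
}

#' @export
print.alias_library <- function(x, ...) {
  cat("Alias library:", length(unique(x$aliases$genus)), "genera,",
      nrow(x$aliases), "aliases\n")
  print(table(x$aliases$alias_class))
  invisible(x)
}

#' Illustrative genus attribute table
#'
#' A small built-in table of well-known bee genera with family, approximate
#' species richness, managed status, sociality and nesting type, plus one or
#' two representative species per genus. It exists so examples, synthetic
#' corpora and tests have realistic-looking inputs; the attribute values are
#' illustrative, not a curated checklist.
#'
#' @param n number of genera to return (up to 20).
#' @return list with `genus_table` (data.frame) and `species_names`
#'   (named list genus -> binomials).
#' @export
example_genus_table <- function(n = 20) {
  tbl <- data.frame(
    genus = c("Apis", "Bombus", "Lasioglossum", "Andrena", "Megachile",
              "Osmia", "Xylocopa", "Melipona", "Trigona", "Tetragonula",
              "Halictus", "Colletes", "Hylaeus", "Ceratina", "Nomada",
              "Anthophora", "Eucera", "Anthidium", "Augochlora", "Perdita"),
    family = c("Apidae", "Apidae", "Halictidae", "Andrenidae", "Megachilidae",
               "Megachilidae", "Apidae", "Apidae", "Apidae", "Apidae",
               "Halictidae", "Colletidae", "Colletidae", "Apidae", "Apidae",
               "Apidae", "Apidae", "Megachilidae", "Halictidae", "Andrenidae"),
    species_richness = c(8L, 250L, 1700L, 1500L, 1500L, 350L, 400L, 70L, 30L,
                         30L, 200L, 450L, 700L, 350L, 850L, 450L, 390L, 160L,
                         110L, 600L),
    managed = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
                TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE),
    sociality = c("social", "social", "social", "solitary", "solitary",
                  "solitary", "solitary", "social", "social", "social",
                  "social", "solitary", "solitary", "solitary", "solitary",
                  "solitary", "solitary", "solitary", "social", "solitary"),
    nesting = c("large_colony_cavity", "large_colony_cavity", "ground",
                "ground", "cavity", "cavity", "wood_excavating",
                "large_colony_cavity", "large_colony_cavity",
                "large_colony_cavity", "ground", "ground", "cavity",
                "wood_excavating", "ground", "ground", "ground", "cavity",
                "ground", "ground"),
    stringsAsFactors = FALSE
  )
  species <- list(
    Apis = c("Apis mellifera", "Apis cerana"),
    Bombus = c("Bombus terrestris", "Bombus impatiens"),
    Lasioglossum = "Lasioglossum malachurum",
    Andrena = "Andrena fulva",
    Megachile = "Megachile rotundata",
    Osmia = c("Osmia bicornis", "Osmia lignaria"),
    Xylocopa = "Xylocopa violacea",
    Melipona = "Melipona beecheii",
    Trigona = "Trigona spinipes",
    Tetragonula = "Tetragonula carbonaria",
    Halictus = "Halictus rubicundus",
    Colletes = "Colletes hederae",
    Hylaeus = "Hylaeus communis",
    Ceratina = "Ceratina cyanea",
    Nomada = "Nomada goodeniana",
    Anthophora = "Anthophora plumipes",
    Eucera = "Eucera longicornis",
    Anthidium = "Anthidium manicatum",
    Augochlora = "Augochlora pura",
    Perdita = "Perdita minima"
  )
  n <- min(n, nrow(tbl))
  list(genus_table = tbl[seq_len(n), , drop = FALSE],
       species_names = species[tbl$genus[seq_len(n)]])
}
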