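# Seeded synthetic-data generators. Every generator is a pure function of
# its spec (seed included), and each returns the planted ground truth next
# to the data so downstream stages can be tested for exact recovery.

#' Specification for a synthetic bibliographic corpus
#'
#' @param genus_table,species_names as produced by [example_genus_table()].
#' @param n_docs number of base documents.
#' @param years candidate publication years.
#' @param mention_rate per-genus, per-document probability of a planted
#'   mention.
#' @param abbreviation_rate probability that a planted mention uses the
#'   binomial abbreviation ("a. mellifera") instead of the full genus name.
#' @param common_name_rate probability that it uses a common name, when the
#'   genus has one (checked before the abbreviation draw).
#' @param duplicate_rate probability a base document is exported by both
#'   pseudo-sources.
#' @param doi_missing_rate probability a document carries no DOI (such
#'   duplicates are only recoverable by title-year matching).
#' @param vocab_size distractor vocabulary size.
#' @param doc_length distractor tokens per abstract.
#' @param year_missing_rate probability the year field is missing.
#' @param seed integer seed.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(genus_table = NULL, species_names = NULL,
                        n_docs = 400L, years = 1990:2020,
                        mention_rate = 0.08, abbreviation_rate = 0.15,
                        common_name_rate = 0.10, duplicate_rate = 0.30,
                        doi_missing_rate = 0.10, vocab_size = 200L,
                        doc_length = 40L, year_missing_rate = 0,
                        seed = 1L) {
  if (is.null(genus_table)) {
    ex <- example_genus_table()
    genus_table <- ex$genus_table
    if (is.null(species_names)) species_names <- ex$species_names
  }
  probs <- c(mention_rate, abbreviation_rate, common_name_rate,
             duplicate_rate, doi_missing_rate, year_missing_rate)
  stopifnot(all(probs >= 0 & probs <= 1), n_docs >= 1L)
  structure(list(genus_table = genus_table, species_names = species_names,
                 n_docs = as.integer(n_docs), years = years,
                 mention_rate = mention_rate,
                 abbreviation_rate = abbreviation_rate,
                 common_name_rate = common_name_rate,
                 duplicate_rate = duplicate_rate,
                 doi_missing_rate = doi_missing_rate,
                 vocab_size = as.integer(vocab_size),
                 doc_length = as.integer(doc_length),
                 year_missing_rate = year_missing_rate,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a synthetic two-source corpus with planted genus mentions
#'
#' Builds documents of distractor tokens (a synthetic vocabulary that cannot
#' collide with any alias stem), plants alias phrases per genus at the
#' configured rates, and exports each base document to one or both
#' pseudo-sources with or without a shared DOI. The planted truth (which
#' document mentions which genus, through which alias class) is returned.
#'
#' @param spec a [corpus_spec()].
#' @return list with `wos`, `scopus` (source-record data.frames), `truth`
#'   (data.frame `base_id`, `genus`, `alias_class`, `year`), `library`
#'   (the matching [build_alias_library()] result) and `spec`.
#' @export
gen_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  lib <- build_alias_library(spec$genus_table,
                             species_names = spec$species_names)
  genera <- spec$genus_table$genus
  vocab <- sprintf("w%04dq", seq_len(spec$vocab_size))
  abbr <- lapply(genera, function(g) {
    a <- lib$aliases[lib$aliases$genus == g & lib$aliases$alias_class == "abbreviation", ]
    a$alias
  })
  names(abbr) <- genera
  common <- lapply(genera, function(g) {
    a <- lib$aliases[lib$aliases$genus == g & lib$aliases$alias_class == "common_name", ]
    a$alias
  })
  names(common) <- genera

  docs <- vector("list", spec$n_docs)
  truth <- vector("list", spec$n_docs)
  for (i in seq_len(spec$n_docs)) {
    year <- sample(spec$years, 1L)
    if (stats::runif(1) < spec$year_missing_rate) year <- NA_integer_
    body <- sample(vocab, spec$doc_length, replace = TRUE)
    mentioned <- genera[stats::runif(length(genera)) < spec$mention_rate]
    classes <- character(0)
    phrases <- character(0)
    for (g in mentioned) {
      u <- stats::runif(1)
      cls <- if (u < spec$common_name_rate) "common_name"
             else if (u < spec$common_name_rate + spec$abbreviation_rate) "abbreviation"
             else "genus_name"
      if (cls == "common_name" && !length(common[[g]])) cls <- "genus_name"
      if (cls == "abbreviation" && !length(abbr[[g]])) cls <- "genus_name"
      phrase <- switch(cls,
                       common_name = sample(common[[g]], 1L),
                       abbreviation = sample(abbr[[g]], 1L),
                       genus_name = tolower(g))
      phrases <- c(phrases, phrase)
      classes <- c(classes, cls)
    }
    if (length(phrases)) {
      # every phrase goes into a gap of the *original* body so no planted
      # phrase can be split by a later insertion
      gaps <- sample(length(body) + 1L, length(phrases), replace = TRUE)
      pieces <- split(phrases, gaps)
      for (gp in sort(as.integer(names(pieces)), decreasing = TRUE)) {
        ins <- unlist(strsplit(pieces[[as.character(gp)]], " ", fixed = TRUE))
        body <- append(body, ins, after = gp - 1L)
      }
    }
    docs[[i]] <- data.frame(
      base_id = sprintf("D%05d", i), year = year,
      title = paste(sample(vocab, 6L, replace = TRUE), collapse = " "),
      abstract = paste(body, collapse = " "),
      stringsAsFactors = FALSE)
    if (length(mentioned)) {
      truth[[i]] <- data.frame(base_id = sprintf("D%05d", i), genus = mentioned,
                               alias_class = classes, year = year,
                               stringsAsFactors = FALSE)
    }
  }
  docs <- do.call(rbind, docs)
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(base_id = character(0), genus = character(0),
                        alias_class = character(0), year = integer(0),
                        stringsAsFactors = FALSE)
  }

  has_doi <- stats::runif(spec$n_docs) >= spec$doi_missing_rate
  doi <- ifelse(has_doi, sprintf("10.9999/synth.%05d", seq_len(spec$n_docs)),
                NA_character_)
  dup <- stats::runif(spec$n_docs) < spec$duplicate_rate
  primary_wos <- stats::runif(spec$n_docs) < 0.5
  in_wos <- primary_wos | dup
  in_scopus <- !primary_wos | dup

  mk <- function(sel, source, prefix) {
    data.frame(record_id = paste0(prefix, docs$base_id[sel]),
               source = source, doi = doi[sel], title = docs$title[sel],
               abstract = docs$abstract[sel], year = docs$year[sel],
               base_id = docs$base_id[sel], stringsAsFactors = FALSE)
  }
  list(wos = mk(in_wos, "wos", "UT"),
       scopus = mk(in_scopus, "scopus", "EID"),
       truth = truth, library = lib, spec = spec)
}

#' Specification for synthetic interaction networks
#'
#' @param genera pollinator genus names.
#' @param attractiveness named positive vector of latent genus
#'   attractiveness (cell probabilities are proportional to plant weight x
#'   attractiveness); default all 1.
#' @param n_networks number of networks.
#' @param n_plants plants per network.
#' @param interactions_per_network multinomial total per network.
#' @param regions region labels recycled over networks (`NA` allowed).
#' @param weighted keep counts (`TRUE`) or reduce to presence/absence.
#' @param seed integer seed.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(genera, attractiveness = NULL, n_networks = 8L,
                         n_plants = 12L, interactions_per_network = 500L,
                         regions = c("AF", "EU", "NA", "SA"), weighted = TRUE,
                         seed = 1L) {
  if (length(genera) < 3L) stop("need at least 3 pollinator genera")
  if (is.null(attractiveness)) {
    attractiveness <- stats::setNames(rep(1, length(genera)), genera)
  }
  stopifnot(all(attractiveness > 0), setequal(names(attractiveness), genera))
  structure(list(genera = genera,
                 attractiveness = attractiveness[genera],
                 n_networks = as.integer(n_networks),
                 n_plants = as.integer(n_plants),
                 interactions_per_network = as.integer(interactions_per_network),
                 regions = regions, weighted = isTRUE(weighted),
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate synthetic interaction networks with latent genus attractiveness
#'
#' Per network, plant weights are drawn log-normally and interaction counts
#' are allocated by one multinomial draw with cell probabilities
#' proportional to plant weight times genus attractiveness. Region labels
#' are attached in rotation.
#'
#' @param spec a [network_spec()].
#' @return list with `networks` (list of [interaction_network()]) and
#'   `attractiveness` (the planted truth).
#' @export
gen_networks <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  regions <- rep_len(spec$regions, spec$n_networks)
  nets <- vector("list", spec$n_networks)
  for (k in seq_len(spec$n_networks)) {
    pw <- stats::rlnorm(spec$n_plants, meanlog = 0, sdlog = 0.6)
    probs <- outer(pw, spec$attractiveness)
    cnt <- stats::rmultinom(1L, spec$interactions_per_network,
                            as.vector(probs / sum(probs)))
    m <- matrix(as.numeric(cnt), nrow = spec$n_plants,
                dimnames = list(sprintf("Plant %02d", seq_len(spec$n_plants)),
                                paste(spec$genera, "sp.")))
    if (!spec$weighted) m <- (m > 0) * 1
    nets[[k]] <- interaction_network(m, network_id = sprintf("net%02d", k),
                                     region = regions[k],
                                     weighted = spec$weighted)
  }
  list(networks = nets, attractiveness = spec$attractiveness)
}

#' Specification for synthetic trait clouds
#'
#' Each group is a bivariate normal cloud in (log ITD, log tongue) space;
#' genus labels are assigned within group with their own mean offsets so
#' genus-PC residualisation has structure to remove.
#'
#' @param groups data.frame with one row per group: `group`, `n`,
#'   `mean_itd`, `mean_tongue` (log-mm), `sd` (isotropic component),
#'   `rho` (trait correlation), `managed` (logical).
#' @param genera_per_group genera assigned per group.
#' @param genus_sd standard deviation of genus mean offsets (log-mm).
#' @param seed integer seed.
#' @return list of class `trait_spec`.
#' @export
trait_spec <- function(groups = NULL, genera_per_group = 4L, genus_sd = 0.15,
                       seed = 1L) {
  if (is.null(groups)) {
    groups <- data.frame(
      group = c("wild", "managed"),
      n = c(400L, 100L),
      mean_itd = c(0.8, 1.1), mean_tongue = c(1.5, 1.8),
      sd = c(0.35, 0.35), rho = c(0.5, 0.5),
      managed = c(FALSE, TRUE), stringsAsFactors = FALSE)
  }
  stopifnot(all(groups$sd > 0), all(abs(groups$rho) < 1))
  structure(list(groups = groups,
                 genera_per_group = as.integer(genera_per_group),
                 genus_sd = genus_sd, seed = as.integer(seed)),
            class = "trait_spec")
}

#' Generate synthetic species trait records
#'
#' Species are drawn from the per-group bivariate normals on the log scale
#' and exponentiated, so intertegular distance and tongue length are
#' strictly positive millimetre values with realistic right skew.
#'
#' @param spec a [trait_spec()].
#' @return data.frame `species`, `genus`, `itd`, `tongue`, `managed`,
#'   `group`, with the per-group parameters in `attr(, "truth")`.
#' @export
gen_traits <- function(spec) {
  stopifnot(inherits(spec, "trait_spec"))
  set.seed(spec$seed)
  out <- list()
  sp_counter <- 0L
  for (r in seq_len(nrow(spec$groups))) {
    g <- spec$groups[r, ]
    Sigma <- matrix(c(g$sd^2, g$rho * g$sd^2, g$rho * g$sd^2, g$sd^2), 2L)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariance not positive definite for group ", g$group)
    genera <- sprintf("%sGenus%02d", toupper(substr(g$group, 1L, 1L)),
                      seq_len(spec$genera_per_group))
    offsets <- MASS::mvrnorm(spec$genera_per_group, mu = c(0, 0),
                             Sigma = diag(spec$genus_sd^2, 2L))
    assign_g <- sample(rep_len(seq_len(spec$genera_per_group), g$n))
    pts <- MASS::mvrnorm(g$n, mu = c(g$mean_itd, g$mean_tongue), Sigma = Sigma)
    pts <- pts + offsets[assign_g, , drop = FALSE]
    out[[r]] <- data.frame(
      species = sprintf("sp%05d", sp_counter + seq_len(g$n)),
      genus = genera[assign_g],
      itd = exp(pts[, 1L]), tongue = exp(pts[, 2L]),
      managed = g$managed, group = g$group, stringsAsFactors = FALSE)
    sp_counter <- sp_counter + g$n
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- spec$groups
  res
}

#' Specification for synthetic genus-year count tables
#'
#' Defaults mirror the headline magnitudes this kind of audit reports (a
#' managed premium around 2.9-fold on the count scale, growing with time)
#' so scaled-down reproductions behave like the real phenomenon; they are an
#' emulation with known truth, not a reproduction of any licensed dataset.
#'
#' @param beta0 intercept on the log scale (relative to exposure).
#' @param beta_managed log incidence-rate ratio for managed genera
#'   (default `log(2.86)`).
#' @param beta_managed_x_year managed x scaled-year interaction
#'   (default `log(1.78)`).
#' @param beta_log_richness coefficient of z-scaled `log1p` species richness.
#' @param theta NB dispersion (> 0).
#' @param years modelled years.
#' @param exposure0 total bee-genus papers in the first year.
#' @param exposure_growth multiplicative yearly growth of the total.
#' @param seed integer seed.
#' @return list of class `counts_spec`.
#' @export
counts_spec <- function(beta0 = -4, beta_managed = log(2.86),
                        beta_managed_x_year = log(1.78),
                        beta_log_richness = log(1.5), theta = 2,
                        years = 1990:2019, exposure0 = 400,
                        exposure_growth = 1.05, seed = 1L) {
  stopifnot(theta > 0, exposure0 > 0, exposure_growth > 0)
  structure(list(beta0 = beta0, beta_managed = beta_managed,
                 beta_managed_x_year = beta_managed_x_year,
                 beta_log_richness = beta_log_richness, theta = theta,
                 years = years, exposure0 = exposure0,
                 exposure_growth = exposure_growth, seed = as.integer(seed)),
            class = "counts_spec")
}

#' Generate a synthetic genus-year effort table
#'
#' Counts are negative-binomially distributed around
#' `exposure_year * exp(linear predictor)` with dispersion `theta`; the
#' linear predictor holds the managed premium, its interaction with scaled
#' year, and the richness term. True coefficients are attached as
#' `attr(, "truth")`.
#'
#' @param spec a [counts_spec()].
#' @param attributes genus attribute data.frame with `genus`,
#'   `species_richness`, `managed` (default [example_genus_table()]).
#' @return data.frame `genus`, `year`, `papers`, `exposure`, `managed`,
#'   `year_scaled`, `log_richness_scaled` plus the attribute columns.
#' @export
gen_counts <- function(spec, attributes = NULL) {
  stopifnot(inherits(spec, "counts_spec"))
  if (is.null(attributes)) attributes <- example_genus_table()$genus_table
  set.seed(spec$seed)
  years <- spec$years
  exposure <- spec$exposure0 * spec$exposure_growth^(seq_along(years) - 1L)
  ys <- as.numeric(scale(years))
  lr <- as.numeric(scale(log1p(attributes$species_richness)))
  grid <- expand.grid(gi = seq_len(nrow(attributes)), yi = seq_along(years),
                      KEEP.OUT.ATTRS = FALSE)
  managed <- as.numeric(attributes$managed[grid$gi])
  eta <- spec$beta0 + spec$beta_managed * managed +
    spec$beta_managed_x_year * managed * ys[grid$yi] +
    spec$beta_log_richness * lr[grid$gi]
  mu <- exposure[grid$yi] * exp(eta)
  papers <- stats::rnbinom(nrow(grid), size = spec$theta, mu = mu)
  out <- data.frame(
    genus = attributes$genus[grid$gi],
    year = years[grid$yi],
    papers = papers,
    exposure = exposure[grid$yi],
    managed = attributes$managed[grid$gi],
    year_scaled = ys[grid$yi],
    log_richness_scaled = lr[grid$gi],
    family = if ("family" %in% names(attributes)) attributes$family[grid$gi] else NA,
    sociality = if ("sociality" %in% names(attributes)) attributes$sociality[grid$gi] else NA,
    nesting = if ("nesting" %in% names(attributes)) attributes$nesting[grid$gi] else NA,
    species_richness = attributes$species_richness[grid$gi],
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(beta0 = spec$beta0,
                             beta_managed = spec$beta_managed,
                             beta_managed_x_year = spec$beta_managed_x_year,
                             beta_log_richness = spec$beta_log_richness,
                             theta = spec$theta)
  out
}
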