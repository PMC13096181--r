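# Genus-level centrality from bipartite plant-pollinator matrices:
# species strength, Bluethgen's d/d', within-network z-scores,
# region-balanced aggregation and sensitivity analyses.

#' Construct an interaction network
#'
#' Thin container for a plants-by-pollinators interaction matrix with its
#' metadata. Rows are plants, columns pollinators; entries are non-negative
#' visitation weights (0/1 for binary networks).
#'
#' @param matrix numeric matrix, plants on rows, pollinators on columns;
#'   column names are pollinator labels.
#' @param network_id identifier string.
#' @param region region label or `NA`.
#' @param weighted logical; `FALSE` for presence/absence networks.
#' @return object of class `interaction_network`.
#' @export
interaction_network <- function(matrix, network_id, region = NA_character_,
                                weighted = TRUE) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (any(matrix < 0)) stop("interaction weights must be non-negative")
  structure(list(matrix = matrix, network_id = as.character(network_id),
                 region = as.character(region), weighted = isTRUE(weighted)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network", x$network_id, ":", nrow(x$matrix), "plants x",
      ncol(x$matrix), "pollinators",
      if (!is.na(x$region)) paste0("(region ", x$region, ")"), "\n")
  invisible(x)
}

#' Read a labelled interaction matrix from CSV
#'
#' Web-of-Life-style layout: first column plant labels, header row pollinator
#' labels, cells interaction weights.
#'
#' @param path CSV file path.
#' @param network_id identifier (defaults to the file name).
#' @param region,weighted metadata, see [interaction_network()].
#' @return an `interaction_network`.
#' @export
read_interaction_network <- function(path, network_id = basename(path),
                                     region = NA_character_, weighted = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  interaction_network(m, network_id = network_id, region = region,
                      weighted = weighted)
}

#' Clean an interaction matrix
#'
#' Drops all-zero rows and columns and, if `orientation` says pollinators are
#' on rows, transposes so pollinators end up on columns. Idempotent on
#' already-clean matrices.
#'
#' @param mat numeric non-negative matrix.
#' @param orientation `"pollinators_cols"` (default) or `"pollinators_rows"`.
#' @return cleaned matrix (plants x pollinators).
#' @export
clean_network <- function(mat, orientation = c("pollinators_cols", "pollinators_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(is.na(mat))) stop("matrix contains NA entries")
  if (any(mat < 0)) stop("negative interaction weights")
  if (orientation == "pollinators_rows") mat <- t(mat)
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("matrix empty after cleaning")
  mat
}

#' Parse pollinator labels to genus
#'
#' Takes the first whitespace-delimited token, capitalises it, and maps it
#' through an optional synonym table. Empty labels give `NA` (the caller is
#' expected to drop and log them).
#'
#' @param labels character vector of pollinator labels.
#' @param synonym_map named character vector, old genus -> accepted genus.
#' @return character vector of genus names (NA where unparseable).
#' @export
#' @examples
#' parse_genus(c("Apis mellifera L. 1758", "apis cf. mellifera"))
parse_genus <- function(labels, synonym_map = NULL) {
  out <- vapply(as.character(labels), function(lab) {
    if (is.na(lab) || !nzchar(trimws(lab))) return(NA_character_)
    tok <- strsplit(trimws(lab), "\\s+")[[1]][1L]
    tok <- tolower(tok)
    paste0(toupper(substr(tok, 1L, 1L)), substr(tok, 2L, nchar(tok)))
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(synonym_map)) {
    hit <- out %in% names(synonym_map)
    out[hit] <- unname(synonym_map[out[hit]])
  }
  out
}

#' Collapse pollinator columns to genus
#'
#' Columns whose labels parse to the same genus are summed, so each genus is
#' one node. Columns with unparseable labels are dropped with a message.
#'
#' @param mat cleaned plants x pollinators matrix with column names.
#' @param synonym_map passed to [parse_genus()].
#' @return matrix with one column per genus.
#' @export
collapse_to_genus <- function(mat, synonym_map = NULL) {
  stopifnot(!is.null(colnames(mat)))
  gen <- parse_genus(colnames(mat), synonym_map)
  if (anyNA(gen)) {
    message("dropping ", sum(is.na(gen)), " column(s) with unparseable labels")
    mat <- mat[, !is.na(gen), drop = FALSE]
    gen <- gen[!is.na(gen)]
  }
  if (ncol(mat) == 0L) stop("no parseable pollinator columns")
  out <- sapply(unique(gen), function(g) {
    rowSums(mat[, gen == g, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), unique(gen)))
  out
}

#' Species strength per pollinator
#'
#' For pollinator j, the sum over plants of the plant's proportional
#' dependence on j: `s_j = sum_i a_ij / r_i` with `r_i` the row total. The
#' strengths of all pollinators sum to the number of plant rows.
#'
#' @param mat cleaned plants x pollinators matrix (no zero rows).
#' @return named numeric vector of strengths, one per column.
#' @export
species_strength <- function(mat) {
  r <- rowSums(mat)
  if (any(r == 0)) stop("zero row total: clean the matrix first")
  colSums(mat / r)
}

# increments of the column-KL objective for one extra unit on each row;
# g_i(k) = (k/A) * log(k / (A * q_i)), g_i(0) = 0
.d_of_alloc <- function(x, A, q) {
  nz <- x > 0
  sum((x[nz] / A) * log((x[nz] / A) / q[nz]))
}

# exact integer d_min via greedy unit allocation: the objective is separable
# convex in the allocation, so adding one unit at a time where the marginal
# increase is smallest reaches the global minimum over integer allocations
.d_min_integer <- function(A, q) {
  m <- length(q)
  x <- integer(m)
  g <- function(k, qi) if (k == 0L) 0 else (k / A) * log((k / A) / qi)
  marg <- vapply(seq_len(m), function(i) g(1L, q[i]) - g(0L, q[i]), numeric(1))
  for (step in seq_len(A)) {
    i <- which.min(marg)
    x[i] <- x[i] + 1L
    marg[i] <- g(x[i] + 1L, q[i]) - g(x[i], q[i])
  }
  .d_of_alloc(x, A, q)
}

#' Bluethgen specialisation index d and d' per pollinator
#'
#' For column j with entries `a_ij`, let `p'_ij = a_ij / A_j` (A_j the column
#' total) and `q_i = r_i / m` (row total over grand total). Then
#' `d_j = sum_i p'_ij log(p'_ij / q_i)` (Kullback-Leibler divergence from the
#' availability distribution, in nats) and `d'_j = (d_j - d_min) / (d_max -
#' d_min)` in `[0, 1]`. The maximum concentrates the column total on the
#' plant with smallest availability, `d_max = log(1/min(q))`; for
#' integer-valued column totals the minimum is computed exactly over integer
#' allocations by a greedy that is provably optimal for this separable convex
#' objective, and for non-integer totals the continuous minimum 0 is used.
#'
#' @param mat cleaned plants x pollinators matrix.
#' @return data.frame with one row per column: `d`, `d_min`, `d_max`,
#'   `dprime`.
#' @export
bluethgen_d <- function(mat) {
  r <- rowSums(mat)
  A <- colSums(mat)
  if (any(r == 0) || any(A == 0)) stop("zero marginal: clean the matrix first")
  total <- sum(mat)
  q <- r / total
  d <- numeric(ncol(mat))
  dmin <- numeric(ncol(mat))
  dmax <- log(1 / min(q))
  integer_total <- all(abs(mat - round(mat)) < 1e-9)
  for (j in seq_len(ncol(mat))) {
    p <- mat[, j] / A[j]
    nz <- p > 0
    d[j] <- sum(p[nz] * log(p[nz] / q[nz]))
    dmin[j] <- if (integer_total) .d_min_integer(as.integer(round(A[j])), q) else 0
  }
  if (!all(is.finite(d))) stop("non-finite specialisation value")
  denom <- dmax - dmin
  # degenerate columns (d_min == d_max): a column whose total admits only
  # maximally specialised allocations (e.g. a single interaction) scores 1,
  # a column with no room for specialisation at all (d = 0) scores 0
  dprime <- ifelse(denom > 1e-12, pmax(0, pmin(1, (d - dmin) / denom)),
                   ifelse(d > 1e-12, 1, 0))
  data.frame(pollinator = colnames(mat) %||% as.character(seq_len(ncol(mat))),
             d = d, d_min = dmin, d_max = dmax, dprime = dprime,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' z-score a metric within one network
#'
#' Centres and scales to sample standard deviation 1; an all-equal vector
#' (sd 0) maps to all zeros rather than infinities so degenerate networks
#' stay usable.
#'
#' @param values numeric vector, length >= 2.
#' @return numeric vector of z-scores.
#' @export
zscore_within_network <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to z-score")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(0, length(values)))
  (values - mean(values)) / s
}

#' Per-network genus metric rows
#'
#' Runs the per-network part of the centrality workflow on a list of
#' networks: clean, collapse pollinators to genus, compute species strength
#' and d/d', z-score within the network, and record interaction counts.
#' Networks with fewer than `min_genera` matched pollinator genera are
#' dropped (with a message), mirroring the filtering rule of the analysis.
#'
#' @param networks list of `interaction_network` objects.
#' @param synonym_map passed to [collapse_to_genus()].
#' @param min_genera minimum pollinator genera per retained network
#'   (default 3).
#' @return data.frame with columns `network_id`, `region`, `genus`,
#'   `strength`, `d`, `dprime`, `z_strength`, `z_dprime`, `interactions`.
#' @export
network_metric_table <- function(networks, synonym_map = NULL, min_genera = 3L) {
  rows <- list()
  dropped <- character(0)
  for (nw in networks) {
    stopifnot(inherits(nw, "interaction_network"))
    m <- clean_network(nw$matrix)
    m <- collapse_to_genus(m, synonym_map)
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) < min_genera) {
      dropped <- c(dropped, nw$network_id)
      next
    }
    s <- species_strength(m)
    dd <- bluethgen_d(m)
    rows[[length(rows) + 1L]] <- data.frame(
      network_id = nw$network_id, region = nw$region,
      genus = colnames(m),
      strength = unname(s), d = dd$d, dprime = dd$dprime,
      z_strength = zscore_within_network(unname(s)),
      z_dprime = zscore_within_network(dd$dprime),
      interactions = unname(colSums(m)),
      stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    message("dropped ", length(dropped), " network(s) with < ", min_genera,
            " matched pollinator genera: ", paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(network_id = character(0), region = character(0),
                      genus = character(0), strength = numeric(0),
                      d = numeric(0), dprime = numeric(0),
                      z_strength = numeric(0), z_dprime = numeric(0),
                      interactions = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "dropped_networks") <- dropped
  out
}

#' Filter out networks with too few matched genera
#'
#' Standalone form of the `< min_genera` rule for metric rows that were
#' computed elsewhere.
#'
#' @param rows data.frame with `network_id` and `genus`.
#' @param min_genera minimum genera per retained network (default 3).
#' @return filtered data.frame, with dropped ids in
#'   `attr(, "dropped_networks")`.
#' @export
filter_small_networks <- function(rows, min_genera = 3L) {
  if (nrow(rows) == 0L) {
    attr(rows, "dropped_networks") <- character(0)
    return(rows)
  }
  n_gen <- tapply(rows$genus, rows$network_id, function(g) length(unique(g)))
  keep_ids <- names(n_gen)[n_gen >= min_genera]
  dropped <- setdiff(names(n_gen), keep_ids)
  if (length(dropped)) {
    message("dropped ", length(dropped), " network(s) with < ", min_genera,
            " matched pollinator genera: ", paste(dropped, collapse = ", "))
  }
  out <- rows[rows$network_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_networks") <- dropped
  out
}

#' Region-balanced genus centrality
#'
#' Aggregates per-network z-strengths to one value per genus: when the genus
#' has at least one region-labelled row, z-scores are averaged within region
#' and the region means are then averaged unweighted (so well-sampled regions
#' do not dominate); otherwise an interaction-weighted pooled mean is used.
#'
#' @param rows metric rows from [network_metric_table()].
#' @return data.frame `genus`, `mean_z_strength`, `n_networks`, `n_regions`.
#' @export
aggregate_region_balanced <- function(rows) {
  stopifnot(all(c("genus", "z_strength", "interactions") %in% names(rows)))
  region <- if ("region" %in% names(rows)) rows$region else rep(NA_character_, nrow(rows))
  region[!is.na(region) & region == "NA"] <- NA_character_
  out <- lapply(split(seq_len(nrow(rows)), rows$genus), function(idx) {
    z <- rows$z_strength[idx]
    reg <- region[idx]
    w <- rows$interactions[idx]
    labelled <- !is.na(reg)
    if (any(labelled)) {
      reg_means <- tapply(z[labelled], reg[labelled], mean)
      mz <- mean(reg_means)
      nr <- length(reg_means)
    } else {
      mz <- sum(z * w) / sum(w)
      nr <- 0L
    }
    data.frame(genus = rows$genus[idx[1L]], mean_z_strength = mz,
               n_networks = length(idx), n_regions = nr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$genus), , drop = FALSE]
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties get their mean rank), with a
#' p-value from the t approximation by default or from a seeded permutation
#' test. A constant input yields `NA` with a warning rather than an error so
#' sensitivity loops can proceed.
#'
#' @param x,y paired numeric vectors, `n >= 3`, no NAs.
#' @param p_method `"asymptotic"` (t approximation) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param seed optional seed for the permutation p-value.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y, p_method = c("asymptotic", "permutation"),
                         n_perm = 999L, seed = NULL) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (anyNA(x) || anyNA(y)) stop("NA values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (p_method == "asymptotic") {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- replicate(n_perm, stats::cor(rx, sample(ry)))
    p <- (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  }
  list(rho = rho, p_value = min(1, p), n = n)
}

#' Leave-one-region-out sensitivity of the centrality-effort correlation
#'
#' Recomputes the region-balanced aggregation and the Spearman correlation
#' with research effort after excluding all networks of each region in turn.
#'
#' @param rows metric rows (with `region`).
#' @param effort_by_genus named numeric vector, genus -> total papers.
#' @return data.frame `excluded_region`, `rho`, `p_value`, `n_genera`,
#'   `computed` (FALSE when fewer than 3 genera remained).
#' @export
leave_one_region_out <- function(rows, effort_by_genus) {
  regions <- unique(rows$region[!is.na(rows$region)])
  if (length(regions) < 2L) stop("need at least 2 labelled regions")
  res <- lapply(regions, function(rg) {
    sub <- rows[is.na(rows$region) | rows$region != rg, , drop = FALSE]
    agg <- if (nrow(sub)) aggregate_region_balanced(sub) else NULL
    genera <- if (is.null(agg)) character(0) else
      intersect(agg$genus, names(effort_by_genus))
    if (length(genera) < 3L) {
      return(data.frame(excluded_region = rg, rho = NA_real_,
                        p_value = NA_real_, n_genera = length(genera),
                        computed = FALSE, stringsAsFactors = FALSE))
    }
    sp <- spearman_cor(agg$mean_z_strength[match(genera, agg$genus)],
                       as.numeric(effort_by_genus[genera]))
    data.frame(excluded_region = rg, rho = sp$rho, p_value = sp$p_value,
               n_genera = length(genera), computed = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bootstrap the centrality-effort correlation over networks
#'
#' Resamples networks with replacement, rebuilds the region-balanced genus
#' centrality each time, and recomputes the Spearman correlation with
#' research effort; reports the estimate and the percentile confidence
#' interval. Degenerate resamples (constant vectors or fewer than 3 shared
#' genera) are skipped and counted.
#'
#' @param rows metric rows from [network_metric_table()].
#' @param effort_by_genus named numeric vector, genus -> total papers.
#' @param B number of bootstrap iterations (>= 100; default 1000).
#' @param seed seed for reproducibility.
#' @param conf confidence level (default 0.95).
#' @return list with `rho` (point estimate), `ci`, `boot_rho` (vector),
#'   `n_skipped`.
#' @export
bootstrap_centrality_correlation <- function(rows, effort_by_genus, B = 1000L,
                                             seed = NULL, conf = 0.95) {
  if (B < 100L) stop("B must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(rows$network_id)
  agg <- aggregate_region_balanced(rows)
  shared <- intersect(agg$genus, names(effort_by_genus))
  if (length(shared) < 3L) stop("fewer than 3 genera shared with effort table")
  point <- spearman_cor(agg$mean_z_strength[match(shared, agg$genus)],
                        as.numeric(effort_by_genus[shared]))$rho
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pick <- sample(ids, length(ids), replace = TRUE)
    sub <- do.call(rbind, lapply(seq_along(pick), function(k) {
      r <- rows[rows$network_id == pick[k], , drop = FALSE]
      r$network_id <- paste0(r$network_id, "#", k)  # copies stay distinct
      r
    }))
    a <- aggregate_region_balanced(sub)
    g <- intersect(a$genus, names(effort_by_genus))
    if (length(g) < 3L) next
    z <- a$mean_z_strength[match(g, a$genus)]
    e <- as.numeric(effort_by_genus[g])
    if (stats::sd(z) == 0 || stats::sd(e) == 0) next
    boot[b] <- suppressWarnings(spearman_cor(z, e)$rho)
  }
  ok <- boot[!is.na(boot)]
  alpha <- (1 - conf) / 2
  list(rho = point,
       ci = unname(stats::quantile(ok, c(alpha, 1 - alpha))),
       boot_rho = boot,
       n_skipped = B - length(ok))
}
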