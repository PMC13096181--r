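# Trait-space coverage: genus-PC residualisation, 2-D kernel densities,
# isopleth regions, overlap/unique mass and permutation nulls.

#' Residualise traits on genus principal components
#'
#' Removes genus-mean structure from species traits so trait-space analyses
#' are not dominated by taxonomic clustering: each trait is z-scored over
#' species, genus mean vectors are computed and decomposed into principal
#' components, every species inherits its genus' first `n_pcs` PC scores,
#' and the least-squares residuals of each z-scored trait on those scores
#' are returned as the species' coordinates.
#'
#' @param traits data.frame with `species`, `genus`, `itd`, `tongue`
#'   (millimetres); rows with missing traits are dropped with a message.
#' @param n_pcs number of genus principal components to regress out
#'   (1 or 2, default 2).
#' @return data.frame `species`, `genus`, `x`, `y` (residualised z-units);
#'   other columns of `traits` (e.g. `managed`, `group`) are carried along.
#' @export
residualize_on_genus_pcs <- function(traits, n_pcs = 2L) {
  stopifnot(all(c("species", "genus", "itd", "tongue") %in% names(traits)),
            n_pcs %in% c(1L, 2L))
  ok <- is.finite(traits$itd) & is.finite(traits$tongue)
  if (any(!ok)) {
    message("dropping ", sum(!ok), " species with incomplete traits")
    traits <- traits[ok, , drop = FALSE]
  }
  if (any(traits$itd <= 0 | traits$tongue <= 0)) {
    stop("traits must be positive where present")
  }
  genera <- unique(traits$genus)
  if (length(genera) < n_pcs + 1L) {
    stop("need more genera (", length(genera), ") than n_pcs + 1 = ", n_pcs + 1L)
  }
  z <- scale(as.matrix(traits[, c("itd", "tongue")]))
  gm <- matrix(c(tapply(z[, 1L], traits$genus, mean),
                 tapply(z[, 2L], traits$genus, mean)),
               ncol = 2L, dimnames = list(sort(unique(traits$genus)), c("itd", "tongue")))
  pc <- stats::prcomp(gm, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  X <- cbind(1, scores[traits$genus, , drop = FALSE])
  res <- apply(z, 2L, function(col) stats::lm.fit(X, col)$residuals)
  out <- traits
  out$x <- unname(res[, 1L])
  out$y <- unname(res[, 2L])
  out
}

#' Bivariate kernel density on a regular grid
#'
#' Gaussian product-kernel density estimate with a rule-of-thumb
#' (Silverman) bandwidth per axis, evaluated on an `n x n` grid covering the
#' data range expanded by `expand` bandwidths so essentially all mass lies
#' inside the grid (the grid integral is within 1% of 1).
#'
#' @param x,y coordinates (>= 5 points).
#' @param n grid resolution per axis (default 200).
#' @param expand margin in bandwidths around the data range (default 3).
#' @param hx,hy bandwidths; default `bw.nrd0` per axis.
#' @param xlim,ylim optional explicit grid limits (used to put two groups on
#'   one common grid).
#' @return object of class `kde_grid`: list with `x`, `y` (grid axes), `z`
#'   (density matrix, `z[i, j]` at `(x[i], y[j])`), `hx`, `hy`, `cell_area`.
#' @export
kde2d_grid <- function(x, y, n = 200L, expand = 3, hx = NULL, hy = NULL,
                       xlim = NULL, ylim = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5L, all(is.finite(x)),
            all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance axis")
  if (is.null(hx)) hx <- stats::bw.nrd0(x)
  if (is.null(hy)) hy <- stats::bw.nrd0(y)
  if (is.null(xlim)) xlim <- range(x) + c(-1, 1) * expand * hx
  if (is.null(ylim)) ylim <- range(y) + c(-1, 1) * expand * hy
  gx <- seq(xlim[1L], xlim[2L], length.out = n)
  gy <- seq(ylim[1L], ylim[2L], length.out = n)
  # z = (1/N) * sum_k phi((gx - x_k)/hx)/hx * phi((gy - y_k)/hy)/hy
  dx <- outer(gx, x, function(g, p) stats::dnorm(g - p, sd = hx))
  dy <- outer(gy, y, function(g, p) stats::dnorm(g - p, sd = hy))
  z <- (dx %*% t(dy)) / length(x)
  out <- list(x = gx, y = gy, z = z, hx = hx, hy = hy,
              cell_area = diff(gx[1:2]) * diff(gy[1:2]))
  class(out) <- "kde_grid"
  out
}

#' @export
print.kde_grid <- function(x, ...) {
  cat("KDE grid", length(x$x), "x", length(x$y),
      sprintf("| bandwidths (%.3g, %.3g) | grid mass %.4f\n",
              x$hx, x$hy, sum(x$z) * x$cell_area))
  invisible(x)
}

#' Highest-density isopleth region
#'
#' The smallest set of grid cells, filled in decreasing density order, whose
#' cumulative share of the total grid mass reaches `level`.
#'
#' @param kde a `kde_grid` (or a bare density matrix).
#' @param level mass level in (0, 1), e.g. 0.95.
#' @return logical matrix mask, same shape as the density grid.
#' @export
isopleth_region <- function(kde, level = 0.95) {
  stopifnot(level > 0, level < 1)
  z <- if (inherits(kde, "kde_grid")) kde$z else kde
  d <- as.vector(z)
  o <- order(d, decreasing = TRUE)
  cs <- cumsum(d[o])
  k <- which(cs >= level * sum(d))[1L]
  mask <- logical(length(d))
  mask[o[seq_len(k)]] <- TRUE
  matrix(mask, nrow = nrow(z))
}

#' Fraction of a reference region covered by a group region
#'
#' Cell-count fraction `|group & reference| / |reference|`; the
#' operationalisation of "coverage of overall trait space".
#'
#' @param group_mask,reference_mask logical masks on one shared grid.
#' @return proportion in `[0, 1]`.
#' @export
coverage_fraction <- function(group_mask, reference_mask) {
  stopifnot(identical(dim(group_mask), dim(reference_mask)))
  n_ref <- sum(reference_mask)
  if (n_ref == 0L) stop("empty reference region")
  sum(group_mask & reference_mask) / n_ref
}

#' Overlap mass and group-unique mass of two densities
#'
#' On a shared grid: `overlap_mass = sum(min(fA, fB)) * cell_area` (symmetric
#' in A and B); `unique_mass_A` is the mass of A falling outside B's
#' `level`-isopleth region, and symmetrically for B.
#'
#' @param kdeA,kdeB `kde_grid` objects on identical grids.
#' @param level isopleth level for the unique-mass regions (default 0.95).
#' @return list `overlap_mass`, `unique_mass_A`, `unique_mass_B`, `level`.
#' @export
overlap_and_unique <- function(kdeA, kdeB, level = 0.95) {
  stopifnot(inherits(kdeA, "kde_grid"), inherits(kdeB, "kde_grid"))
  if (!isTRUE(all.equal(kdeA$x, kdeB$x)) || !isTRUE(all.equal(kdeA$y, kdeB$y))) {
    stop("densities must share one grid (pass xlim/ylim to kde2d_grid)")
  }
  area <- kdeA$cell_area
  maskA <- isopleth_region(kdeA, level)
  maskB <- isopleth_region(kdeB, level)
  list(
    overlap_mass = sum(pmin(kdeA$z, kdeB$z)) * area,
    unique_mass_A = sum(kdeA$z[!maskB]) * area,
    unique_mass_B = sum(kdeB$z[!maskA]) * area,
    level = level
  )
}

#' Permutation null for a group statistic
#'
#' Draws `n_perm` random subsets of `group_size` rows from the pool without
#' replacement, evaluates `statistic_fn` on each, and returns the
#' add-one-estimator p-value `(1 + #{null at least as extreme}) /
#' (n_perm + 1)` for the requested tail.
#'
#' @param statistic_fn function taking a matrix/data.frame of pooled rows.
#' @param group_size observed group size (must be `< nrow(pool)`).
#' @param pool matrix or data.frame of rows to resample from.
#' @param observed observed value of the statistic.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed optional seed.
#' @param tail `"lower"` (observed below null is extreme), `"upper"`, or
#'   `"two"`.
#' @return list `p_value`, `null` (vector), `null_mean`, `observed`,
#'   `n_perm`, `tail`.
#' @export
permutation_null <- function(statistic_fn, group_size, pool, observed,
                             n_perm = 999L, seed = NULL,
                             tail = c("lower", "upper", "two")) {
  tail <- match.arg(tail)
  n_pool <- nrow(pool)
  if (group_size >= n_pool) stop("group_size must be smaller than the pool")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n_pool, group_size)
    as.numeric(statistic_fn(pool[idx, , drop = FALSE]))
  }, numeric(1))
  p_lo <- (1 + sum(null <= observed)) / (n_perm + 1)
  p_hi <- (1 + sum(null >= observed)) / (n_perm + 1)
  p <- switch(tail, lower = p_lo, upper = p_hi, two = min(1, 2 * min(p_lo, p_hi)))
  list(p_value = p, null = null, null_mean = mean(null), observed = observed,
       n_perm = n_perm, tail = tail)
}

#' Euclidean distance between group centroids
#'
#' @param groupA_points,groupB_points matrices/data.frames of coordinates
#'   (columns = axes), both non-empty.
#' @return non-negative distance in the coordinate units.
#' @export
centroid_distance <- function(groupA_points, groupB_points) {
  A <- as.matrix(groupA_points); B <- as.matrix(groupB_points)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty group")
  sqrt(sum((colMeans(A) - colMeans(B))^2))
}

#' Trait measurement coverage of a species universe
#'
#' Proportion of the species universe with both focal traits measured,
#' overall and stratified by managed status (each stratum's coverage is
#' computed over that stratum's universe).
#'
#' @param species_universe data.frame with `species` and logical `managed`.
#' @param traits data.frame with `species`, `itd`, `tongue`.
#' @return list `overall`, `managed`, `wild`, `n_universe`, `n_measured`.
#' @export
trait_coverage_summary <- function(species_universe, traits) {
  stopifnot(nrow(species_universe) > 0L,
            all(c("species", "managed") %in% names(species_universe)))
  measured <- unique(traits$species[is.finite(traits$itd) & is.finite(traits$tongue)])
  has <- species_universe$species %in% measured
  man <- as.logical(species_universe$managed)
  list(
    overall = mean(has),
    managed = if (any(man)) mean(has[man]) else NA_real_,
    wild = if (any(!man)) mean(has[!man]) else NA_real_,
    n_universe = nrow(species_universe),
    n_measured = sum(has)
  )
}
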