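# Genus-PC residualisation, kernel densities, isopleths, overlap,
# permutation nulls

test_that("residualisation removes genus structure and centres residuals", {
  set.seed(4)
  tr <- gen_traits(trait_spec(seed = 4))
  res <- residualize_on_genus_pcs(tr)
  expect_equal(mean(res$x), 0, tolerance = 1e-10)
  expect_equal(mean(res$y), 0, tolerance = 1e-10)

  # residuals orthogonal to the genus PC regressors
  z <- scale(as.matrix(tr[, c("itd", "tongue")]))
  gm <- matrix(c(tapply(z[, 1], tr$genus, mean), tapply(z[, 2], tr$genus, mean)),
               ncol = 2, dimnames = list(sort(unique(tr$genus)), NULL))
  sc <- prcomp(gm)$x[tr$genus, 1:2]
  expect_lt(abs(sum(res$x * sc[, 1])), 1e-8)
  expect_lt(abs(sum(res$x * sc[, 2])), 1e-8)
  expect_lt(abs(sum(res$y * sc[, 1])), 1e-8)
  expect_lt(abs(sum(res$y * sc[, 2])), 1e-8)
})

test_that("identical genus means leave the z-scored traits untouched", {
  # genera perfectly balanced around the same mean: nothing to remove
  base <- data.frame(
    species = paste0("s", 1:12),
    genus = rep(c("Ga", "Gb", "Gc"), each = 4),
    itd = rep(c(1.8, 2.2, 1.6, 2.4), 3),
    tongue = rep(c(5.5, 6.5, 5.0, 7.0), 3),
    stringsAsFactors = FALSE)
  res <- residualize_on_genus_pcs(base)
  z <- scale(as.matrix(base[, c("itd", "tongue")]))
  expect_equal(res$x, unname(z[, 1]), tolerance = 1e-10)
  expect_equal(res$y, unname(z[, 2]), tolerance = 1e-10)
})

test_that("traits that are pure genus effects give zero residuals", {
  tr <- data.frame(
    species = paste0("s", 1:8),
    genus = rep(c("Ga", "Gb", "Gc", "Gd"), each = 2),
    itd = rep(c(1.5, 2.0, 2.5, 3.0), each = 2),
    tongue = rep(c(4.0, 5.0, 6.0, 7.0), each = 2),
    stringsAsFactors = FALSE)
  res <- residualize_on_genus_pcs(tr, n_pcs = 1L)
  expect_true(all(abs(res$x) < 1e-10))
  expect_true(all(abs(res$y) < 1e-10))
  expect_error(residualize_on_genus_pcs(tr[tr$genus %in% c("Ga", "Gb"), ]),
               "more genera")
})

test_that("the KDE integrates to one and matches a brute-force kernel sum", {
  set.seed(6)
  x <- rnorm(2000); y <- rnorm(2000)
  k <- kde2d_grid(x, y, n = 100L)
  expect_gt(sum(k$z) * k$cell_area, 0.99)
  expect_lt(sum(k$z) * k$cell_area, 1.01)
  peak <- which(k$z == max(k$z), arr.ind = TRUE)
  expect_lt(abs(k$x[peak[1]]), 0.5)
  expect_lt(abs(k$y[peak[2]]), 0.5)

  xs <- rnorm(50); ys <- rnorm(50)
  ks <- kde2d_grid(xs, ys, n = 20L)
  expect_equal(ks$z, kde_brute(xs, ys, ks$x, ks$y, ks$hx, ks$hy),
               tolerance = 1e-12)

  expect_error(kde2d_grid(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("isopleth regions are minimal highest-density cell sets", {
  set.seed(9)
  k <- kde2d_grid(rnorm(500), rnorm(500), n = 60L)
  mask <- isopleth_region(k, 0.95)
  total <- sum(k$z)
  expect_gte(sum(k$z[mask]) / total, 0.95)
  # dropping the least dense included cell dips below the level
  inc <- k$z[mask]
  expect_lt((sum(inc) - min(inc)) / total, 0.95)
  # all excluded cells are no denser than any included cell
  expect_lte(max(k$z[!mask]), min(inc))
  # near level 1 everything with appreciable mass is included
  big <- isopleth_region(k, 0.999)
  expect_gt(sum(big) / length(big), sum(mask) / length(mask))
})

test_that("coverage fraction behaves on equal, disjoint and half overlaps", {
  ref <- matrix(FALSE, 10, 10); ref[3:8, 3:8] <- TRUE
  expect_equal(coverage_fraction(ref, ref), 1)
  dis <- matrix(FALSE, 10, 10); dis[1:2, 1:2] <- TRUE
  expect_equal(coverage_fraction(dis, ref), 0)
  half <- matrix(FALSE, 10, 10); half[3:8, 3:5] <- TRUE
  expect_equal(coverage_fraction(half, ref), 0.5)
  expect_error(coverage_fraction(ref, matrix(FALSE, 10, 10)), "empty reference")
})

test_that("overlap mass is symmetric, ~1 for self-joins, ~0 when separated", {
  set.seed(10)
  x <- rnorm(400); y <- rnorm(400)
  lim <- c(-15, 25)
  kA <- kde2d_grid(x, y, n = 150L, xlim = lim, ylim = lim)
  self <- overlap_and_unique(kA, kA)
  expect_gt(self$overlap_mass, 0.98)
  expect_equal(self$unique_mass_A, 1 - 0.95, tolerance = 0.02)

  kB <- kde2d_grid(x + 20, y + 20, n = 150L, xlim = lim, ylim = c(-15, 45))
  expect_error(overlap_and_unique(kA, kB), "share one grid")
  kB2 <- kde2d_grid(x + 20, y, n = 150L, xlim = lim, ylim = lim)
  far <- overlap_and_unique(kA, kB2)
  expect_lt(far$overlap_mass, 0.01)
  expect_gt(far$unique_mass_A, 0.95)
  rev <- overlap_and_unique(kB2, kA)
  expect_equal(rev$overlap_mass, far$overlap_mass, tolerance = 1e-12)
})

test_that("permutation p-values hit the add-one bound and reproduce per seed", {
  set.seed(12)
  pool <- cbind(x = rnorm(60), y = rnorm(60))
  stat <- function(pts) mean(pts[, 1])
  out <- permutation_null(stat, group_size = 10L, pool = pool,
                          observed = 100, n_perm = 199L, seed = 3, tail = "upper")
  expect_equal(out$p_value, 1 / 200)
  out2 <- permutation_null(stat, group_size = 10L, pool = pool,
                           observed = 100, n_perm = 199L, seed = 3, tail = "upper")
  expect_identical(out$null, out2$null)
  expect_error(permutation_null(stat, 60L, pool, observed = 0), "smaller than")
})

test_that("centroid distance does the obvious geometry", {
  A <- matrix(c(0, 0, 0, 0), 2, 2)
  expect_equal(centroid_distance(A, A), 0)
  B <- matrix(c(3, 3, 4, 4), 2, 2)
  expect_equal(centroid_distance(A, B), 5)
  set.seed(14)
  for (rep in 1:10) {
    P <- matrix(rnorm(20), 10); Q <- matrix(rnorm(20), 10)
    expect_equal(centroid_distance(P, Q),
                 sqrt(sum((colMeans(P) - colMeans(Q))^2)), tolerance = 1e-12)
  }
  expect_error(centroid_distance(A[0, , drop = FALSE], B), "empty group")
})

test_that("trait coverage is stratified over each stratum's own universe", {
  uni <- data.frame(species = paste0("s", 1:10),
                    managed = rep(c(TRUE, FALSE), c(2, 8)),
                    stringsAsFactors = FALSE)
  tr <- data.frame(species = c("s1", "s3", "s4"), itd = 1, tongue = 2,
                   stringsAsFactors = FALSE)
  cov <- trait_coverage_summary(uni, tr)
  expect_equal(cov$overall, 0.3)
  expect_equal(cov$managed, 0.5)   # s1 of {s1, s2}
  expect_equal(cov$wild, 0.25)     # s3, s4 of 8
  all_in <- trait_coverage_summary(uni, data.frame(species = uni$species,
                                                   itd = 1, tongue = 1))
  expect_equal(all_in$overall, 1)
})
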