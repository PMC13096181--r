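# Species strength, Bluethgen d/d', z-scores, filtering, aggregation,
# correlation machinery

named_mat <- function(m) {
  dimnames(m) <- list(paste0("P", seq_len(nrow(m))), paste0("G", seq_len(ncol(m))))
  m
}

test_that("cleaning drops empty margins and respects orientation", {
  m <- named_mat(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  out <- clean_network(m)
  expect_identical(dim(out), c(1L, 1L))
  expect_equal(out[1, 1], 1)

  clean <- named_mat(matrix(1:4, 2, 2))
  expect_identical(clean_network(clean), clean_network(clean_network(clean)))

  expect_error(clean_network(named_mat(matrix(0, 2, 2))), "empty after cleaning")
  expect_error(clean_network(named_mat(matrix(-1, 1, 1))), "negative")

  flipped <- clean_network(t(clean), orientation = "pollinators_rows")
  expect_identical(flipped, clean)
})

test_that("genus parsing takes the first token, capitalises, maps synonyms", {
  expect_identical(parse_genus("Apis mellifera L. 1758"), "Apis")
  expect_identical(parse_genus("apis cf. mellifera"), "Apis")
  expect_identical(parse_genus("Chalcosmia fulva", c(Chalcosmia = "Osmia")), "Osmia")
  expect_identical(parse_genus(c("", "  ")), c(NA_character_, NA_character_))
})

test_that("species strength matches hand computations and conserves totals", {
  m <- named_mat(matrix(c(1, 1, 0, 2), 2, 2, byrow = TRUE))
  expect_equal(unname(species_strength(m)), c(0.5, 1.5))
  expect_equal(unname(species_strength(named_mat(diag(3)))), c(1, 1, 1))
  set.seed(8)
  for (rep in 1:25) {
    m <- random_clean_matrix(4, 3, total = 30)
    expect_equal(sum(species_strength(m)), 4, tolerance = 1e-12)
  }
})

test_that("d and d' match the hand-evaluated examples", {
  u <- named_mat(matrix(1, 2, 2))
  expect_equal(bluethgen_d(u)$d, c(0, 0))
  expect_equal(bluethgen_d(u)$dprime, c(0, 0))

  id3 <- named_mat(diag(3))
  dd <- bluethgen_d(id3)
  expect_equal(dd$d, rep(log(3), 3))
  expect_equal(dd$dprime, rep(1, 3))

  m <- named_mat(matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE))
  # column 1: p' = (2/3, 1/3), q = (1/2, 1/2)
  expect_equal(bluethgen_d(m)$d[1],
               2 / 3 * log((2 / 3) / 0.5) + 1 / 3 * log((1 / 3) / 0.5),
               tolerance = 1e-12)
})

test_that("d is non-negative, d' bounded, metrics invariant to permutation", {
  set.seed(13)
  for (rep in 1:30) {
    m <- random_clean_matrix(sample(2:5, 1), sample(2:5, 1), total = 40)
    dd <- bluethgen_d(m)
    expect_true(all(dd$d >= -1e-12))
    expect_true(all(dd$dprime >= 0 & dd$dprime <= 1))
    perm <- m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]
    dd2 <- bluethgen_d(perm)
    expect_equal(sort(dd2$d), sort(dd$d), tolerance = 1e-12)
    expect_equal(sort(dd2$dprime), sort(dd$dprime), tolerance = 1e-12)
    expect_equal(sort(species_strength(perm)), sort(species_strength(m)),
                 tolerance = 1e-12)
  }
})

test_that("d_min/d_max equal exhaustive search over integer allocations", {
  set.seed(21)
  check_matrix <- function(m) {
    dd <- bluethgen_d(m)
    q <- rowSums(m) / sum(m)
    for (j in seq_len(ncol(m))) {
      ex <- d_exhaustive(sum(m[, j]), q)
      expect_equal(dd$d_min[j], unname(ex["min"]), tolerance = 1e-10)
      expect_equal(dd$d_max[j], unname(ex["max"]), tolerance = 1e-10)
      expect_true(dd$d[j] >= dd$d_min[j] - 1e-10)
      expect_true(dd$d[j] <= dd$d_max[j] + 1e-10)
    }
  }
  # full enumeration of small 2x2 matrices with positive margins
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) for (d in 0:3) {
    m <- named_mat(matrix(c(a, b, cc, d), 2, 2))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) check_matrix(m)
  }
  # random larger matrices up to 4x4, grand total <= 12
  for (rep in 1:60) {
    m <- random_clean_matrix(sample(2:4, 1), sample(2:4, 1),
                             total = sample(6:12, 1))
    check_matrix(m)
  }
})

test_that("z-scoring gives mean 0 / sd 1 and zeros on degenerate input", {
  expect_equal(zscore_within_network(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zscore_within_network(c(5, 5, 5)), c(0, 0, 0))
  expect_error(zscore_within_network(1), "at least 2")
  set.seed(3)
  z <- zscore_within_network(rnorm(40, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("networks with fewer than 3 matched genera are dropped", {
  rows <- data.frame(
    network_id = c("a", "a", "b", "b", "b"),
    genus = c("Apis", "Bombus", "Apis", "Bombus", "Osmia"),
    z_strength = 0, interactions = 1, stringsAsFactors = FALSE)
  expect_message(out <- filter_small_networks(rows), "dropped 1 network")
  expect_identical(unique(out$network_id), "b")
  expect_identical(attr(out, "dropped_networks"), "a")
  empty <- rows[0, ]
  expect_identical(nrow(filter_small_networks(empty)), 0L)
})

test_that("region-balanced aggregation averages within then across regions", {
  rows <- data.frame(network_id = c("n1", "n2", "n3"),
                     region = c("A", "A", "B"), genus = "Apis",
                     z_strength = c(1, 3, -2), interactions = c(5, 5, 5),
                     stringsAsFactors = FALSE)
  agg <- aggregate_region_balanced(rows)
  expect_equal(agg$mean_z_strength, 0)  # mean of (2, -2)
  expect_identical(agg$n_regions, 2L)

  single <- rows[1, ]
  expect_equal(aggregate_region_balanced(single)$mean_z_strength, 1)

  unlab <- data.frame(network_id = c("n1", "n2"), region = NA_character_,
                      genus = "Apis", z_strength = c(1, 3),
                      interactions = c(10, 30), stringsAsFactors = FALSE)
  expect_equal(aggregate_region_balanced(unlab)$mean_z_strength, 2.5)

  # all networks in one region: region balancing reduces to the plain mean
  one_reg <- data.frame(network_id = paste0("n", 1:4), region = "EU",
                        genus = "Apis", z_strength = c(0.3, -1, 2, 0.5),
                        interactions = 1, stringsAsFactors = FALSE)
  expect_equal(aggregate_region_balanced(one_reg)$mean_z_strength,
               mean(one_reg$z_strength))
})

test_that("Spearman handles monotone pairs, ties and degenerate input", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  set.seed(19)
  for (rep in 1:50) {
    x <- sample(1:5, 12, replace = TRUE)  # heavy ties
    y <- x + sample(-2:2, 12, replace = TRUE)
    expect_equal(spearman_cor(x, y)$rho, spearman_oracle(x, y), tolerance = 1e-12)
    expect_equal(spearman_cor(x, y)$rho,
                 unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  }
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
})

test_that("leave-one-region-out recomputes the aggregation per exclusion", {
  set.seed(2)
  # region EU carries all the signal: its genera correlate with effort there
  mk_rows <- function(region, zshift) {
    data.frame(network_id = paste0(region, 1:2),
               region = region,
               genus = rep(paste0("g", 1:6), each = 2)[1:12],
               z_strength = rep(zshift, each = 2)[1:12] + rnorm(12, 0, 0.01),
               interactions = 1, stringsAsFactors = FALSE)
  }
  rows <- rbind(mk_rows("EU", seq(-1, 1, length.out = 6)),
                mk_rows("NA", rep(0, 6)))
  effort <- setNames(seq(10, 60, 10), paste0("g", 1:6))
  out <- leave_one_region_out(rows, effort)
  rho_no_eu <- out$rho[out$excluded_region == "EU"]
  rho_no_na <- out$rho[out$excluded_region == "NA"]
  expect_true(abs(rho_no_na) > 0.9)        # signal intact without the flat region
  expect_true(abs(rho_no_eu) < abs(rho_no_na))  # collapses without the signal

  expect_error(leave_one_region_out(rows[rows$region == "EU", ], effort),
               "at least 2")
})

test_that("bootstrap correlation is seed-reproducible and detects signal", {
  set.seed(31)
  rows <- do.call(rbind, lapply(1:6, function(k) {
    data.frame(network_id = paste0("n", k), region = c("A", "B", "C")[k %% 3 + 1],
               genus = paste0("g", 1:8),
               z_strength = scale(1:8 + rnorm(8, 0, 0.1))[, 1],
               interactions = 10, stringsAsFactors = FALSE)
  }))
  effort <- setNames(2^(1:8), paste0("g", 1:8))
  b1 <- bootstrap_centrality_correlation(rows, effort, B = 100L, seed = 7)
  b2 <- bootstrap_centrality_correlation(rows, effort, B = 100L, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] > 0)  # perfectly aligned construction: CI excludes 0
  expect_error(bootstrap_centrality_correlation(rows, effort, B = 50L), "at least 100")
})

test_that("the per-network metric table wires cleaning to z-scores", {
  gn <- gen_networks(network_spec(genera = paste0("Genus", letters[1:5]),
                                  n_networks = 4L, seed = 5))
  rows <- network_metric_table(gn$networks)
  expect_identical(sort(unique(rows$network_id)), paste0("net0", 1:4))
  for (id in unique(rows$network_id)) {
    z <- rows$z_strength[rows$network_id == id]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  expect_true(all(rows$dprime >= 0 & rows$dprime <= 1))
})
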