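# Popularity expectations, quadrants, scaling, family comparisons, share
# trends, NB count models

test_that("popularity expectations conserve totals and zero out when aligned", {
  obs <- c(A = 100, B = 300, C = 600)
  pop <- c(A = 1, B = 3, C = 6)
  out <- expected_from_popularity(obs, pop)
  expect_equal(out$residual, rep(0, 3))
  expect_equal(sum(out$expected), sum(obs))

  pop2 <- c(A = 5, B = 1, C = 4)
  out2 <- expected_from_popularity(obs, pop2)
  expect_equal(sum(out2$expected), sum(obs), tolerance = 1e-12)
  expect_equal(out2$pct_deviation, 100 * out2$residual / out2$expected)

  expect_error(expected_from_popularity(obs, c(A = 1, B = 0, C = 2)), "positive")
  expect_error(expected_from_popularity(obs, c(A = 1, B = 2, X = 3)), "same genus set")
})

test_that("quadrant classification partitions and records thresholds", {
  eff <- c(a = 1, b = 1, c = 1000, d = 1000)
  cen <- c(a = -1, b = 1, c = -1, d = 1)
  q <- classify_quadrants(eff, cen, effort_threshold = 1, centrality_threshold = 0,
                          managed = c(a = FALSE, b = FALSE, c = TRUE, d = TRUE))
  expect_equal(as.vector(q$group_sizes), c(1, 1, 1, 1))
  expect_identical(q$assignments$group[q$assignments$genus == "d"], "HEHC")
  expect_equal(unname(q$managed_share["HEHC"]), 1)
  expect_equal(unname(q$managed_share["LELC"]), 0)

  all_low <- classify_quadrants(c(a = 1, b = 2), c(a = 0, b = 0),
                                effort_threshold = 10, centrality_threshold = 5)
  expect_identical(unique(all_low$assignments$group), "LELC")

  set.seed(22)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    g <- paste0("g", seq_len(n))
    qq <- classify_quadrants(setNames(rpois(n, 50), g), setNames(rnorm(n), g))
    expect_identical(sum(qq$group_sizes), n)             # always a partition
    expect_identical(sort(qq$assignments$genus), sort(g))
  }
  expect_error(classify_quadrants(eff, cen, effort_threshold = Inf), "finite")
})

test_that("scaling fit recovers a constructed exponent and flags outliers", {
  set.seed(23)
  richness <- exp(runif(60, log(1e5), log(1e8)))
  articles <- richness^0.5
  names(richness) <- names(articles) <- paste0("g", 1:60)
  fit <- richness_effort_scaling(articles, richness)
  expect_equal(fit$fit$slope, 0.5, tolerance = 0.01)

  # one gross outlier is caught by the Cook's distance rule
  articles2 <- articles; articles2["g1"] <- articles2["g1"] * 1e6
  fit2 <- richness_effort_scaling(articles2, richness)
  expect_true(fit2$influence$flagged[fit2$influence$genus == "g1"])
  expect_true(fit2$influence$cooks_d[fit2$influence$genus == "g1"] > 4 / 60)

  # named-exclusion and trim refits drop the right number of genera
  expect_equal(fit$refits$trim_top_richness$n, 60 - ceiling(0.6))
  expect_error(richness_effort_scaling(articles[1:5], richness[1:5]), "at least 10")
})

test_that("duplicating the data keeps the slope and shrinks HC3 SEs ~ sqrt(2)", {
  set.seed(24)
  richness <- exp(runif(40, 2, 10)); articles <- richness^0.7 * exp(rnorm(40, 0, 0.3))
  names(richness) <- names(articles) <- paste0("g", 1:40)
  one <- richness_effort_scaling(articles, richness)
  rich2 <- c(richness, setNames(richness, paste0("h", 1:40)))
  art2 <- c(articles, setNames(articles, paste0("h", 1:40)))
  two <- richness_effort_scaling(art2, rich2)
  expect_equal(two$fit$slope, one$fit$slope, tolerance = 1e-10)
  expect_equal(one$fit$se / two$fit$se, sqrt(2), tolerance = 0.05)
})

test_that("HC3 matches the literal-formula oracle and scales with y", {
  set.seed(25)
  for (rep in 1:50) {
    X <- cbind(1, rnorm(20))
    y <- X %*% c(1, 2) + rnorm(20) * (1 + abs(X[, 2]))
    e <- stats::lm.fit(X, y)$residuals
    expect_equal(unname(hc3_covariance(X, e)), unname(hc3_oracle(X, e)),
                 tolerance = 1e-10)
  }
  X <- cbind(1, rnorm(30)); e <- rnorm(30)
  expect_equal(hc3_covariance(X, 3 * e), 9 * hc3_covariance(X, e),
               tolerance = 1e-12)
  # homoscedastic, large n: HC3 close to the classical OLS covariance
  set.seed(26)
  Xb <- cbind(1, rnorm(2000)); yb <- Xb %*% c(0, 1) + rnorm(2000)
  fit <- stats::lm.fit(Xb, yb)
  ols_se <- sqrt(diag(solve(crossprod(Xb)) * sum(fit$residuals^2) / (2000 - 2)))
  hc3_se <- sqrt(diag(hc3_covariance(Xb, fit$residuals)))
  expect_equal(unname(hc3_se / ols_se), c(1, 1), tolerance = 0.05)
})

test_that("Welch ANOVA equals the t-test square for 2 groups and oneway.test always", {
  set.seed(27)
  g1 <- rnorm(10); g2 <- rnorm(14, 0.4, 2)
  w <- welch_anova(list(g1, g2))
  tt <- t.test(g1, g2)
  expect_equal(w$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-10)

  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_lt(welch_anova(same)$F, 1e-12)
  expect_equal(welch_anova(same)$p_value, 1, tolerance = 1e-6)

  for (rep in 1:50) {
    k <- sample(2:5, 1)
    gr <- lapply(seq_len(k), function(i) rnorm(sample(5:15, 1), i / 3, runif(1, 0.5, 2)))
    w <- welch_anova(gr)
    df <- data.frame(y = unlist(gr), g = factor(rep(seq_len(k), lengths(gr))))
    ot <- oneway.test(y ~ g, df, var.equal = FALSE)
    expect_equal(w$F, unname(ot$statistic), tolerance = 1e-10)
    expect_equal(w$df2, unname(ot$parameter[2]), tolerance = 1e-10)
    expect_equal(w$p_value, ot$p.value, tolerance = 1e-10)
  }
  expect_error(welch_anova(list(c(1, 1, 1), rnorm(5))), "zero-variance")
  expect_error(welch_anova(list(rnorm(5), 1)), "at least 2")
})

test_that("Games-Howell agrees with Welch t quantities pair by pair", {
  set.seed(28)
  for (rep in 1:25) {
    k <- sample(3:5, 1)
    gr <- lapply(seq_len(k), function(i) rnorm(sample(6:12, 1), i / 2, runif(1, 0.5, 2)))
    names(gr) <- paste0("f", seq_len(k))
    gh <- games_howell(gr)
    expect_equal(nrow(gh), k * (k - 1) / 2)
    for (r in seq_len(nrow(gh))) {
      a <- gr[[gh$group_a[r]]]; b <- gr[[gh$group_b[r]]]
      tt <- t.test(a, b)  # independent Welch se and df
      expect_equal(gh$difference[r], unname(tt$estimate[1] - tt$estimate[2]),
                   tolerance = 1e-10)
      expect_equal(gh$df[r], unname(tt$parameter), tolerance = 1e-10)
      se <- gh$difference[r] / unname(tt$statistic)
      expect_equal(gh$se[r], se, tolerance = 1e-10)
      expect_lt(abs(gh$p_value[r] -
                      ptukey(abs(unname(tt$statistic)) * sqrt(2), k,
                             unname(tt$parameter), lower.tail = FALSE)), 1e-10)
    }
    expect_equal(gh$p_adj, bh_oracle(gh$p_value), tolerance = 1e-12)
  }
  two_same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5), c = c(9, 9.1, 9.2, 9.3, 9.4))
  gh <- games_howell(two_same)
  expect_gt(gh$p_value[gh$group_a == "a" & gh$group_b == "b"], 0.99)
  expect_identical(which.min(gh$p_value), which(gh$group_b == "c")[1])
})

test_that("BH adjustment matches the literal step-up and keeps its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(29)
  for (rep in 1:50) {
    p <- runif(sample(3:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("binomial share trends recover a logistic slope and flag separation", {
  years <- 1980:2019
  b <- 0.05
  sh <- plogis(-2 + b * (years - 2000))
  tot <- rep(2e6, length(years))
  s <- round(sh * tot); f <- tot - s
  fit <- binomial_share_trend(s, f, years)
  expect_equal(fit$slope, b, tolerance = 1e-3)

  const <- binomial_share_trend(rep(50, 10), rep(50, 10), 2001:2010)
  expect_equal(const$slope, 0, tolerance = 1e-8)

  sep <- binomial_share_trend(rep(0, 5), rep(10, 5), 2001:2005)
  expect_true(sep$separated)
  expect_true(is.na(sep$slope))

  # small fixture against the hand-rolled IRLS oracle
  set.seed(30)
  s2 <- rbinom(12, 400, plogis(-1 + 0.08 * (1:12)))
  fit2 <- binomial_share_trend(s2, 400 - s2, 1:12)
  oracle <- logit_irls_oracle(s2, 400 - s2, 1:12)
  expect_equal(fit2$slope, unname(oracle[2]), tolerance = 1e-8)
  expect_equal(fit2$intercept, unname(oracle[1]), tolerance = 1e-8)
})

test_that("one-vs-rest share trends are BH-adjusted across levels", {
  set.seed(31)
  years <- 2000:2019
  counts <- rbind(
    data.frame(year = years, level = "social",
               count = rpois(20, 40 + 3 * (years - 2000))),
    data.frame(year = years, level = "solitary", count = rpois(20, 60)),
    data.frame(year = years, level = "other", count = rpois(20, 10)))
  out <- share_trend_one_vs_rest(counts)
  expect_identical(nrow(out), 3L)
  expect_equal(out$p_adj, bh_oracle(out$p_value), tolerance = 1e-12)
  expect_gt(out$slope[out$level == "social"], 0)
})

test_that("nb_glm matches glm.nb and honours the offset contract", {
  set.seed(32)
  n <- 600
  man <- rbinom(n, 1, 0.5)
  expo <- runif(n, 50, 500)
  mu <- expo * exp(-2 + log(2.86) * man)
  y <- rnbinom(n, size = 2, mu = mu)
  X <- cbind(`(Intercept)` = 1, managed = man)
  fit <- nb_glm(y, X, offset = log(expo))
  ref <- MASS::glm.nb(y ~ man + offset(log(expo)))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(fit$theta, ref$theta, tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-3)
  expect_equal(fit$irr$irr, exp(unname(fit$coefficients)))
  expect_true(all(fit$irr$ci_lower < fit$irr$irr & fit$irr$irr < fit$irr$ci_upper))

  # doubling every exposure shifts only the intercept, by -log(2)
  fit2 <- nb_glm(y, X, offset = log(2 * expo))
  expect_equal(fit2$coefficients[["(Intercept)"]],
               fit$coefficients[["(Intercept)"]] - log(2), tolerance = 1e-6)
  expect_equal(fit2$coefficients[["managed"]], fit$coefficients[["managed"]],
               tolerance = 1e-6)

  # Poisson-generated counts drive theta towards the Poisson limit
  yp <- rpois(n, exp(1 + 0.5 * man))
  fitp <- nb_glm(yp, X)
  pois <- glm(yp ~ man, family = poisson())
  expect_gt(fitp$theta, 100)
  expect_lt(abs(fitp$coefficients[["managed"]] - coef(pois)[["man"]]),
            2 * summary(pois)$coefficients["man", 2])

  expect_error(nb_glm(y, cbind(X, man)), "rank deficient")
})

test_that("era share changes reproduce the worked percentage points", {
  counts <- data.frame(
    year = rep(c(1990:1994, 2015:2019), each = 2),
    category = rep(c("managed", "wild"), 10),
    count = c(rbind(rep(10, 5), rep(90, 5)), rbind(rep(31, 5), rep(69, 5))))
  out <- era_share_change(counts, 1990:1994, 2015:2019)
  expect_equal(out$change_points[out$category == "managed"], 21)
  expect_equal(out$change_points[out$category == "wild"], -21)
  flipped <- era_share_change(counts, 2015:2019, 1990:1994)
  expect_equal(flipped$change_points[flipped$category == "managed"], -21)
  const <- era_share_change(counts[counts$year < 2000, ], 1990:1991, 1993:1994)
  expect_equal(const$change_points, c(0, 0))
  expect_error(era_share_change(counts, 1970:1971, 2015:2019), "empty window")
})
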