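# Bias statistics: popularity expectations, policy-group quadrants,
# richness-effort scaling with robust errors and influence trims, family
# comparisons, share trends, and negative-binomial count models with an
# exposure offset.

#' Observed vs popularity-expected research effort
#'
#' Distributes the total observed paper count over genera proportionally to
#' public popularity: `expected_g = T * pop_g / sum(pop)` with
#' `T = sum(observed)`, so expectations conserve the total exactly. Reports
#' residuals (observed - expected) and percentage deviations
#' `100 * residual / expected`.
#'
#' @param observed named numeric vector, genus -> observed paper count.
#' @param popularity named numeric vector over the same genera; strictly
#'   positive (any common scale, e.g. normalised to *Apis* = 1).
#' @return data.frame `genus`, `observed`, `expected`, `residual`, `pct_deviation`,
#'   sorted by decreasing observed count.
#' @export
expected_from_popularity <- function(observed, popularity) {
  if (!setequal(names(observed), names(popularity))) {
    stop("observed and popularity must cover the same genus set")
  }
  popularity <- popularity[names(observed)]
  if (any(!is.finite(popularity) | popularity <= 0)) {
    stop("popularity must be strictly positive")
  }
  total <- sum(observed)
  expected <- total * as.numeric(popularity) / sum(popularity)
  out <- data.frame(
    genus = names(observed),
    observed = as.numeric(observed),
    expected = expected,
    residual = as.numeric(observed) - expected,
    pct_deviation = 100 * (as.numeric(observed) - expected) / expected,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$observed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify genera into effort-by-centrality policy groups
#'
#' Crosses high/low research effort with high/low network centrality:
#' HE iff effort exceeds `effort_threshold` (compared on the
#' `log10(effort + 1)` scale), HC iff centrality exceeds
#' `centrality_threshold`; the four groups LELC, LEHC, HELC, HEHC partition
#' the classified genus set. Defaults are median splits, and the thresholds
#' actually used are always recorded in the output.
#'
#' @param effort named numeric vector, genus -> total papers.
#' @param centrality named numeric vector, genus -> mean z-strength.
#' @param effort_threshold threshold on the `log10(effort + 1)` scale;
#'   default the median.
#' @param centrality_threshold threshold on centrality; default the median.
#' @param managed optional named logical vector for managed shares per group.
#' @return object of class `quadrant_assignment`: list with `assignments`
#'   (data.frame `genus`, `effort`, `log_effort`, `centrality`, `group`),
#'   `thresholds`, `group_sizes`, `managed_share`.
#' @export
classify_quadrants <- function(effort, centrality, effort_threshold = NULL,
                               centrality_threshold = NULL, managed = NULL) {
  genera <- intersect(names(effort), names(centrality))
  if (!length(genera)) stop("no genera present in both inputs")
  le <- log10(as.numeric(effort[genera]) + 1)
  ce <- as.numeric(centrality[genera])
  if (is.null(effort_threshold)) effort_threshold <- stats::median(le)
  if (is.null(centrality_threshold)) centrality_threshold <- stats::median(ce)
  if (!is.finite(effort_threshold) || !is.finite(centrality_threshold)) {
    stop("thresholds must be finite")
  }
  he <- le > effort_threshold
  hc <- ce > centrality_threshold
  group <- ifelse(he & hc, "HEHC",
                  ifelse(he & !hc, "HELC", ifelse(hc, "LEHC", "LELC")))
  assignments <- data.frame(genus = genera, effort = as.numeric(effort[genera]),
                            log_effort = le, centrality = ce, group = group,
                            stringsAsFactors = FALSE)
  sizes <- table(factor(group, levels = c("LELC", "LEHC", "HELC", "HEHC")))
  managed_share <- NULL
  if (!is.null(managed)) {
    mg <- as.logical(managed[genera])
    managed_share <- tapply(mg, factor(group, levels = names(sizes)), mean)
  }
  out <- list(assignments = assignments,
              thresholds = c(effort_threshold = effort_threshold,
                             centrality_threshold = centrality_threshold),
              group_sizes = sizes, managed_share = managed_share)
  class(out) <- "quadrant_assignment"
  out
}

#' @export
print.quadrant_assignment <- function(x, ...) {
  cat("Policy groups (effort x centrality),", sum(x$group_sizes),
      "genera classified\n")
  print(x$group_sizes)
  cat(sprintf("thresholds: log10(effort+1) > %.3f, z-strength > %.3f\n",
              x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' HC3 heteroskedasticity-robust covariance
#'
#' `(X'X)^-1 X' diag(e_i^2 / (1 - h_ii)^2) X (X'X)^-1`, with `h_ii` the hat
#' diagonal.
#'
#' @param X full-rank design matrix.
#' @param e residual vector.
#' @return covariance matrix of the coefficient estimates.
#' @export
hc3_covariance <- function(X, e) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(e))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  XtXi <- solve(crossprod(X))
  h <- rowSums((X %*% XtXi) * X)
  if (any(h >= 1 - 1e-10)) stop("hat value of 1: HC3 undefined")
  d <- e^2 / (1 - h)^2
  XtXi %*% crossprod(X, X * d) %*% XtXi
}

.ols_hc3 <- function(x, y, conf = 0.95) {
  X <- cbind(`(Intercept)` = 1, slope = x)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  V <- hc3_covariance(X, fit$residuals)
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n <- length(y); p <- 2L
  rss <- sum(fit$residuals^2); tss <- sum((y - mean(y))^2)
  adj_r2 <- 1 - (rss / (n - p)) / (tss / (n - 1))
  list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
       se = unname(se[2L]),
       ci = c(lower = unname(beta[2L] - z * se[2L]),
              upper = unname(beta[2L] + z * se[2L])),
       adj_r2 = adj_r2, n = n)
}

#' Richness-effort scaling with robust errors and influence trims
#'
#' Fits `log10(articles + 1) ~ log10(richness)` over genera by OLS with HC3
#' standard errors, flags high-influence genera (Cook's distance > 4/n or
#' leverage > 2p/n), and refits (a) without the flagged genera, (b) without
#' named dominant genera, (c) trimming the top 1% by richness and (d) by
#' article count (top 1% = `ceiling(0.01 n)` genera).
#'
#' @param articles named numeric vector, genus -> total papers.
#' @param richness named numeric vector, genus -> species richness.
#' @param exclude_genera genera for the named-exclusion refit
#'   (default Apis and Bombus).
#' @param conf confidence level (default 0.95).
#' @return object of class `scaling_fit`: `fit` (full fit), `influence`
#'   (data.frame with flags), `refits` (named list of sub-fits).
#' @export
richness_effort_scaling <- function(articles, richness,
                                    exclude_genera = c("Apis", "Bombus"),
                                    conf = 0.95) {
  genera <- intersect(names(articles), names(richness))
  if (length(genera) < 10L) stop("need at least 10 genera")
  x <- log10(as.numeric(richness[genera]))
  y <- log10(as.numeric(articles[genera]) + 1)
  if (stats::sd(x) == 0) stop("constant regressor")
  n <- length(y); p <- 2L
  full <- .ols_hc3(x, y, conf)
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, y)
  h <- rowSums((X %*% solve(crossprod(X))) * X)
  s2 <- sum(fit$residuals^2) / (n - p)
  cooks <- fit$residuals^2 / (p * s2) * h / (1 - h)^2
  flagged <- cooks > 4 / n | h > 2 * p / n
  influence <- data.frame(genus = genera, cooks_d = cooks, leverage = h,
                          flagged = flagged, stringsAsFactors = FALSE)
  refit <- function(keep) {
    if (sum(keep) < 3L || stats::sd(x[keep]) == 0) return(NULL)
    .ols_hc3(x[keep], y[keep], conf)
  }
  k_trim <- ceiling(0.01 * n)
  top_rich <- genera[order(-x)][seq_len(k_trim)]
  top_art <- genera[order(-y)][seq_len(k_trim)]
  refits <- list(
    excluding_influential = refit(!flagged),
    excluding_named = refit(!(genera %in% exclude_genera)),
    trim_top_richness = refit(!(genera %in% top_rich)),
    trim_top_articles = refit(!(genera %in% top_art))
  )
  out <- list(fit = full, influence = influence, refits = refits,
              exclude_genera = exclude_genera)
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Richness-effort scaling: slope %.3f (%.3f-%.3f, HC3), adj R2 %.3f, n = %d\n",
              x$fit$slope, x$fit$ci[1], x$fit$ci[2], x$fit$adj_r2, x$fit$n))
  cat(" ", sum(x$influence$flagged), "high-influence genera flagged\n")
  for (nm in names(x$refits)) {
    r <- x$refits[[nm]]
    if (!is.null(r)) {
      cat(sprintf("  %s: slope %.3f (%.3f-%.3f), n = %d\n", nm, r$slope,
                  r$ci[1], r$ci[2], r$n))
    }
  }
  invisible(x)
}

.check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  for (g in groups) {
    if (length(g) < 2L) stop("every group needs at least 2 values")
    if (stats::var(g) == 0) stop("zero-variance group")
  }
  invisible(groups)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Tests for mean differences among groups without assuming equal variances;
#' Satterthwaite-type denominator degrees of freedom.
#'
#' @param groups list of numeric vectors, each with >= 2 values and positive
#'   variance (groups failing this should be excluded upstream).
#' @return list `F`, `df1`, `df2`, `p_value`, `k`.
#' @export
welch_anova <- function(groups) {
  .check_groups(groups)
  k <- length(groups)
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  w <- n / v
  sw <- sum(w)
  mw <- sum(w * m) / sw
  tmp <- sum((1 - w / sw)^2 / (n - 1))
  Fstat <- (sum(w * (m - mw)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * tmp)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * tmp)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE), k = k)
}

#' Games-Howell pairwise comparisons
#'
#' Unequal-variance pairwise contrasts with Welch-Satterthwaite degrees of
#' freedom and a studentised-range reference distribution, plus
#' Benjamini-Hochberg adjustment across the `k(k-1)/2` pairs.
#'
#' @param groups named list of numeric vectors (as for [welch_anova()]).
#' @param conf confidence level for the interval (default 0.95).
#' @return data.frame `group_a`, `group_b`, `difference`, `se`, `df`,
#'   `ci_lower`, `ci_upper`, `p_value`, `p_adj`.
#' @export
games_howell <- function(groups, conf = 0.95) {
  .check_groups(groups)
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  prs <- utils::combn(k, 2L)
  res <- lapply(seq_len(ncol(prs)), function(c0) {
    i <- prs[1L, c0]; j <- prs[2L, c0]
    se <- sqrt(v[i] / n[i] + v[j] / n[j])
    df <- (v[i] / n[i] + v[j] / n[j])^2 /
      ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    diff <- m[i] - m[j]
    q <- abs(diff) / se * sqrt(2)
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    hw <- stats::qtukey(conf, nmeans = k, df = df) / sqrt(2) * se
    data.frame(group_a = nm[i], group_b = nm[j], difference = diff, se = se,
               df = df, ci_lower = diff - hw, ci_upper = diff + hw,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment; adjusted values are never below the raw p-values
#' and the ordering is preserved.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Binomial share trend over years
#'
#' Logit-link binomial GLM of a category's share of yearly totals on
#' calendar year, using the two-column successes/failures response.
#' Complete separation (all shares 0 or all 1) is flagged instead of
#' estimated.
#'
#' @param successes,failures integer vectors per year.
#' @param year calendar years.
#' @return list `slope` (per year, logit scale), `se`, `p_value`,
#'   `intercept`, `converged`, `separated`.
#' @export
binomial_share_trend <- function(successes, failures, year) {
  stopifnot(length(successes) == length(failures),
            length(successes) == length(year))
  tot <- successes + failures
  if (any(tot <= 0)) stop("each year needs a positive total")
  sh <- successes / tot
  if (all(sh == 0) || all(sh == 1)) {
    return(list(slope = NA_real_, se = NA_real_, p_value = NA_real_,
                intercept = NA_real_, converged = FALSE, separated = TRUE))
  }
  fit <- stats::glm(cbind(successes, failures) ~ year, family = stats::binomial())
  s <- summary(fit)$coefficients
  list(slope = s["year", "Estimate"], se = s["year", "Std. Error"],
       p_value = s["year", "Pr(>|z|)"], intercept = s["(Intercept)", "Estimate"],
       converged = fit$converged, separated = FALSE)
}

#' One-vs-rest share trends across category levels
#'
#' Fits [binomial_share_trend()] for each level of a composition (that
#' level's counts vs all others) and BH-adjusts the p-values across levels.
#'
#' @param counts data.frame with `year`, `level`, `count`.
#' @param levels optional subset/order of levels to fit.
#' @return data.frame `level`, `slope`, `se`, `p_value`, `p_adj`,
#'   `separated`.
#' @export
share_trend_one_vs_rest <- function(counts, levels = NULL) {
  stopifnot(all(c("year", "level", "count") %in% names(counts)))
  if (is.null(levels)) levels <- unique(counts$level)
  years <- sort(unique(counts$year))
  tot <- tapply(counts$count, counts$year, sum)[as.character(years)]
  res <- lapply(levels, function(lv) {
    s <- tapply(counts$count[counts$level == lv],
                counts$year[counts$level == lv], sum)[as.character(years)]
    s[is.na(s)] <- 0
    fit <- binomial_share_trend(as.numeric(s), as.numeric(tot - s), years)
    data.frame(level = lv, slope = fit$slope, se = fit$se,
               p_value = fit$p_value, separated = fit$separated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !out$separated
  out$p_adj <- NA_real_
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p_value[ok])
  rownames(out) <- NULL
  out
}

# profile-likelihood ML update for the NB dispersion theta given mu
.theta_ml <- function(y, mu, theta0 = NULL, max_iter = 50L, tol = 1e-10) {
  n <- length(y)
  if (is.null(theta0)) {
    num <- mean(y)^2
    den <- max(stats::var(y) - mean(y), mean(y) * 0.1)
    theta0 <- max(num / den, 0.1)
  }
  lt <- log(theta0)
  for (it in seq_len(max_iter)) {
    th <- exp(lt)
    score <- sum(digamma(y + th) - digamma(th) + log(th) + 1 -
                   log(th + mu) - (y + th) / (th + mu))
    info <- sum(trigamma(y + th) - trigamma(th) + 1 / th -
                  2 / (th + mu) + (y + th) / (th + mu)^2)
    # Newton on log(theta): d/dlt = theta * score
    g <- th * score
    h2 <- th * score + th^2 * info
    if (!is.finite(g) || !is.finite(h2) || h2 == 0) break
    step <- g / h2
    step <- sign(step) * min(abs(step), 2)
    lt_new <- lt - step
    if (abs(lt_new - lt) < tol) { lt <- lt_new; break }
    lt <- lt_new
  }
  min(exp(lt), 1e8)
}

#' Negative-binomial GLM with log link and exposure offset
#'
#' Fits `counts ~ NB(mean = exp(X beta + offset), dispersion theta)` by
#' alternating iteratively reweighted least squares for `beta` (at the
#' current `theta`) with maximum-likelihood updates of `theta`, until the
#' joint log-likelihood changes by less than `tol` (default 1e-8).
#' Coefficients are reported as incidence rate ratios `exp(beta)` with Wald
#' 95% intervals `exp(beta +/- 1.96 se)`. A fitted `theta` beyond 1e4 raises
#' the Poisson-limit flag (variance ~ mean; the NB adds nothing).
#'
#' @param counts non-negative integer response.
#' @param X design matrix (full rank; include the intercept column).
#' @param offset log-exposure vector (default all zero).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter outer iteration cap (default 100).
#' @return object of class `nb_fit`: `coefficients`, `se`, `theta`, `irr`
#'   (data.frame with IRRs and Wald CIs), `loglik`, `converged`,
#'   `poisson_limit`, `iterations`, `mu`.
#' @export
nb_glm <- function(counts, X, offset = NULL, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(counts)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(y >= 0), all(is.finite(X)))
  if (is.null(offset)) offset <- rep(0, n)
  stopifnot(length(offset) == n, all(is.finite(offset)))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  # Poisson start for beta
  pois <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(), offset = offset))
  beta <- pois$coefficients
  eta <- drop(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e10)
  theta <- .theta_ml(y, mu)
  ll <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # IRLS for beta at fixed theta
    for (inner in seq_len(25L)) {
      w <- mu / (1 + mu / theta)
      z <- (eta - offset) + (y - mu) / mu
      fit <- stats::lm.wfit(X, z, w)
      beta_new <- fit$coefficients
      if (any(!is.finite(beta_new))) stop("IRLS produced non-finite coefficients")
      eta <- drop(X %*% beta_new) + offset
      mu <- pmin(exp(eta), 1e10)
      if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
      beta <- beta_new
    }
    theta <- .theta_ml(y, mu, theta0 = theta)
    ll_new <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
    trace <- c(trace, ll_new)
    if (is.finite(ll_new) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) {
    stop("nb_glm did not converge in ", max_iter,
         " iterations; log-likelihood trace: ",
         paste(sprintf("%.4f", utils::tail(trace, 5L)), collapse = ", "))
  }
  w <- mu / (1 + mu / theta)
  V <- solve(crossprod(X, X * w))
  se <- sqrt(diag(V))
  zq <- stats::qnorm(0.975)
  irr <- data.frame(
    term = colnames(X),
    estimate = unname(beta),
    se = unname(se),
    irr = exp(unname(beta)),
    ci_lower = exp(unname(beta) - zq * se),
    ci_upper = exp(unname(beta) + zq * se),
    p_value = 2 * stats::pnorm(abs(unname(beta) / se), lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  out <- list(coefficients = stats::setNames(unname(beta), colnames(X)),
              se = stats::setNames(unname(se), colnames(X)),
              vcov = V, theta = theta, irr = irr, loglik = ll,
              converged = converged, poisson_limit = theta > 1e4,
              iterations = it, mu = mu)
  class(out) <- "nb_fit"
  out
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("Negative-binomial GLM (log link), theta = %.3f%s\n", x$theta,
              if (x$poisson_limit) " [Poisson limit]" else ""))
  print(x$irr[, c("term", "irr", "ci_lower", "ci_upper", "p_value")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Early-vs-recent change in category shares
#'
#' Mean share of each category over the recent window minus its mean share
#' over the early window, in percentage points.
#'
#' @param counts data.frame `year`, `category`, `count`.
#' @param early_window,recent_window integer vectors of years (e.g. two
#'   five-year windows).
#' @return data.frame `category`, `early_share`, `recent_share`,
#'   `change_points`.
#' @export
era_share_change <- function(counts, early_window, recent_window) {
  stopifnot(all(c("year", "category", "count") %in% names(counts)),
            length(early_window) > 0L, length(recent_window) > 0L)
  mean_share <- function(window) {
    sub <- counts[counts$year %in% window, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty window")
    tot <- tapply(sub$count, sub$year, sum)
    if (any(tot == 0)) stop("window contains a year with zero total")
    shares <- lapply(sort(unique(sub$year)), function(yy) {
      s <- sub[sub$year == yy, , drop = FALSE]
      sh <- tapply(s$count, s$category, sum) / sum(s$count)
      data.frame(category = names(sh), share = as.numeric(sh), year = yy,
                 stringsAsFactors = FALSE)
    })
    shares <- do.call(rbind, shares)
    tapply(shares$share, shares$category, mean)
  }
  early <- mean_share(early_window)
  recent <- mean_share(recent_window)
  cats <- union(names(early), names(recent))
  e <- ifelse(cats %in% names(early), early[cats], 0)
  r <- ifelse(cats %in% names(recent), recent[cats], 0)
  data.frame(category = cats, early_share = as.numeric(e),
             recent_share = as.numeric(r),
             change_points = 100 * (as.numeric(r) - as.numeric(e)),
             stringsAsFactors = FALSE, row.names = NULL)
}
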