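# Independent brute-force oracles and small fixture builders shared across
# the test files. These deliberately re-derive quantities from first
# principles (enumeration, literal formulas, double loops) so they cannot
# share a code path with the implementation they check.

# all compositions of the integer A into m non-negative parts
compositions <- function(A, m) {
  if (m == 1L) return(matrix(A, 1L))
  out <- list()
  for (k in 0:A) {
    out[[k + 1L]] <- cbind(k, compositions(A - k, m - 1L))
  }
  unname(do.call(rbind, out))
}

# exhaustive min/max of the column KL statistic over integer allocations
d_exhaustive <- function(A, q) {
  comps <- compositions(A, length(q))
  vals <- apply(comps, 1L, function(x) {
    nz <- x > 0
    sum((x[nz] / A) * log((x[nz] / A) / q[nz]))
  })
  c(min = min(vals), max = max(vals))
}

# random integer interaction matrix with no zero rows/columns
random_clean_matrix <- function(nr, nc, total) {
  repeat {
    cells <- as.vector(stats::rmultinom(1L, total, rep(1, nr * nc)))
    m <- matrix(cells, nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      dimnames(m) <- list(paste0("P", seq_len(nr)), paste0("G", seq_len(nc)))
      return(m)
    }
  }
}

# naive Spearman: explicit average ranks, then the Pearson formula by hand
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# literal BH step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# literal HC3 formula, element by element
hc3_oracle <- function(X, e) {
  XtXi <- solve(t(X) %*% X)
  H <- X %*% XtXi %*% t(X)
  D <- diag(e^2 / (1 - diag(H))^2)
  XtXi %*% t(X) %*% D %*% X %*% XtXi
}

# double-loop kernel sum for the 2-D KDE
kde_brute <- function(px, py, gx, gy, hx, hy) {
  z <- matrix(0, length(gx), length(gy))
  for (i in seq_along(gx)) {
    for (j in seq_along(gy)) {
      z[i, j] <- mean(stats::dnorm(gx[i] - px, sd = hx) *
                        stats::dnorm(gy[j] - py, sd = hy))
    }
  }
  z
}

# hand-rolled IRLS for a two-column binomial logit fit of share on year
logit_irls_oracle <- function(s, f, x) {
  X <- cbind(1, x)
  n <- s + f
  beta <- c(stats::qlogis(pmin(pmax(sum(s) / sum(n), 1e-6), 1 - 1e-6)), 0)
  for (i in 1:100) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- n * mu * (1 - mu)
    z <- eta + (s / n - mu) / (mu * (1 - mu))
    beta_new <- solve(t(X) %*% (X * W), t(X) %*% (W * z))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

# small synthetic corpus helper used by several linkage tests
tiny_records <- function(ids, source, dois = NULL, titles = NULL, years = NULL) {
  n <- length(ids)
  data.frame(record_id = ids, source = source,
             doi = if (is.null(dois)) rep(NA_character_, n) else dois,
             title = if (is.null(titles)) paste("title", seq_len(n)) else titles,
             abstract = "", year = if (is.null(years)) rep(2000L, n) else years,
             stringsAsFactors = FALSE)
}
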