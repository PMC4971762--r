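# Independent brute-force oracles used to freeze expected values.
# Each is deliberately written along a different route than the package
# implementation it checks.

# Benjamini-Hochberg by literal step-up enumeration:
# q_(i) = min_{j >= i} m * p_(j) / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Pearson chi-square statistic from first principles.
chisq_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Upper-tail Poisson probability P(X >= k) by term-by-term summation.
pois_upper_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  x <- k
  term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  total <- term
  repeat {
    x <- x + 1
    term <- term * lambda / x
    total <- total + term
    if (term < 1e-18 * max(total, 1e-300)) break
  }
  total
}

# Two-sided conditional binomial test: enumerate P(S_a = s | S) under
# Binomial(S, prob) and sum probabilities <= that of the observed split.
binom_two_sided_oracle <- function(Sa, S, prob) {
  w <- dbinom(0:S, S, prob)
  sum(w[w <= w[Sa + 1] * (1 + 1e-12)])
}

# Upper-tail hypergeometric overlap probability by enumerating every
# placement of A over the universe (feasible for |U| <= 12).
hyper_enum_oracle <- function(n_universe, n_a, n_b, overlap) {
  hits <- 0
  total <- 0
  b_set <- seq_len(n_b)  # WLOG B occupies the first n_b slots
  placements <- utils::combn(n_universe, n_a)
  for (j in seq_len(ncol(placements))) {
    total <- total + 1
    if (length(intersect(placements[, j], b_set)) >= overlap) hits <- hits + 1
  }
  hits / total
}

# Partial correlations via residual regression: regress features i and j
# on all remaining features and correlate the residuals.
pcor_resid_oracle <- function(X) {
  k <- ncol(X)
  P <- diag(k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      others <- X[, -c(i, j), drop = FALSE]
      ri <- stats::lm.fit(cbind(1, others), X[, i])$residuals
      rj <- stats::lm.fit(cbind(1, others), X[, j])$residuals
      P[i, j] <- P[j, i] <- stats::cor(ri, rj)
    }
  }
  dimnames(P) <- list(colnames(X), colnames(X))
  P
}

# Two-sample KS statistic by exhaustive ECDF evaluation at every pooled
# point.
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# All permutations of a vector (recursive; for small n).
all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- list()
  for (i in seq_along(v)) {
    rest <- all_perms(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}
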