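# Independent oracles used by the tests. These deliberately re-derive
# results through different routes than the package implementation.

# Jackknife richness oracle: hard-coded closed-form estimators of orders
# 1..5 in terms of the frequencies f_i (species observed i times), plus the
# sequential order-selection cascade. The package derives the same
# coefficients from the generalized leave-j-out construction instead.
oracle_jackknife <- function(counts, alpha = 0.05) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  S <- length(counts)
  fi <- vapply(1:5, function(i) sum(counts == i), numeric(1))
  A <- matrix(1, 5, 6)  # a[i, k+1]: coefficient of f_i in the order-k estimator
  A[1, 2] <- 1 + (n - 1) / n
  A[1, 3] <- 1 + (2 * n - 3) / n
  A[2, 3] <- 1 - (n - 2)^2 / (n * (n - 1))
  A[1, 4] <- 1 + (3 * n - 6) / n
  A[2, 4] <- 1 - (3 * n^2 - 15 * n + 19) / (n * (n - 1))
  A[3, 4] <- 1 + (n - 3)^3 / (n * (n - 1) * (n - 2))
  A[1, 5] <- 1 + (4 * n - 10) / n
  A[2, 5] <- 1 - (6 * n^2 - 36 * n + 55) / (n * (n - 1))
  A[3, 5] <- 1 + (4 * n^3 - 42 * n^2 + 148 * n - 175) / (n * (n - 1) * (n - 2))
  A[4, 5] <- 1 - (n - 4)^4 / (n * (n - 1) * (n - 2) * (n - 3))
  A[1, 6] <- 1 + (5 * n - 15) / n
  A[2, 6] <- 1 - (10 * n^2 - 70 * n + 125) / (n * (n - 1))
  A[3, 6] <- 1 + (10 * n^3 - 120 * n^2 + 485 * n - 660) / (n * (n - 1) * (n - 2))
  A[4, 6] <- 1 - ((n - 4)^5 - (n - 5)^5) / (n * (n - 1) * (n - 2) * (n - 3))
  A[5, 6] <- 1 + (n - 5)^5 / (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
  Kmax <- max(c(0, which(fi > 0)))
  Kmax <- min(Kmax, n - 1)
  if (Kmax == 0) return(list(estimate = as.numeric(S), order = 0L))
  jack <- S + as.vector(crossprod(A[, 1:(Kmax + 1), drop = FALSE] - 1, fi))
  crit <- qnorm(1 - alpha / 2)
  Ts <- vapply(1:Kmax, function(k) {
    b <- A[, k + 1] - A[, k]
    d <- jack[k + 1] - jack[k]
    v <- sum(b^2 * fi) - d^2 / S
    if (v <= 1e-10) { if (d > 1e-10) Inf else 0 } else d / sqrt(v)
  }, numeric(1))
  m <- 0L
  while (m < Kmax && Ts[m + 1] >= crit) m <- m + 1L
  est <- if (m == Kmax) {
    jack[Kmax + 1]
  } else {
    w <- min(max(Ts[m + 1] / crit, 0), 1)
    jack[m + 1] + w * (jack[m + 2] - jack[m + 1])
  }
  list(estimate = max(est, S), order = m)
}

# Shannon / Simpson identities computed from their textbook definitions.
oracle_shannon_hill <- function(p) {
  p <- p[p > 0] / sum(p[p > 0])
  exp(-sum(p * log(p)))
}
oracle_simpson_hill <- function(p) {
  p <- p[p > 0] / sum(p[p > 0])
  1 / sum(p^2)
}

# Random abundance vectors for property sweeps.
random_abundance <- function(max_s = 12, max_count = 60) {
  s <- sample(2:max_s, 1)
  counts <- rnbinom(s, mu = runif(1, 0.5, max_count / 3), size = 0.7)
  if (all(counts == 0)) counts[sample(s, 1)] <- sample(1:5, 1)
  counts
}
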