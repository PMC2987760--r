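# Exact rational hypergeometric oracle, independent of the log-space
# implementation under test. Binomial coefficients and the pmf ratio are
# assembled from prime factorizations of factorials (Legendre's formula):
# all exponents are exact integers, so the result is correct to double
# rounding (~1e-15 relative), with no lgamma/lchoose involved.

oracle_primes <- function(m) {
  ps <- integer(0)
  for (x in seq_len(m)[-1]) {
    small <- ps[ps * ps <= x]
    if (!length(small) || all(x %% small != 0)) ps <- c(ps, x)
  }
  ps
}

# exponent of prime p in m!
oracle_fact_exp <- function(m, p) {
  e <- 0L; q <- p
  while (q <= m) { e <- e + m %/% q; q <- q * p }
  e
}

# table E[i, m+1] = exponent of primes[i] in m!, m = 0..maxN
oracle_exp_table <- function(maxN) {
  primes <- oracle_primes(maxN)
  E <- vapply(0:maxN, function(m) vapply(primes, function(p) oracle_fact_exp(m, p), 0L),
              integer(length(primes)))
  list(primes = primes,
       E = matrix(E, nrow = length(primes), ncol = maxN + 1))
}

# exact binomial coefficient (valid while the result fits a double exactly
# or to double rounding)
oracle_choose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  if (n < 2) return(1)
  tab <- oracle_exp_table(n)
  e <- tab$E[, n + 1] - tab$E[, k + 1] - tab$E[, n - k + 1]
  prod(tab$primes^e)
}

# vectorized over k for scalar N, K, n; tab from oracle_exp_table(N)
oracle_hyper_pmf <- function(k, N, K, n, tab = oracle_exp_table(N)) {
  lo <- max(0, n + K - N); hi <- min(K, n)
  out <- numeric(length(k))
  ok <- k >= lo & k <= hi
  if (!any(ok)) return(out)
  kk <- k[ok]
  e <- tab$E[, K + 1] - tab$E[, kk + 1, drop = FALSE] -
    tab$E[, K - kk + 1, drop = FALSE] +
    tab$E[, N - K + 1] - tab$E[, n - kk + 1, drop = FALSE] -
    tab$E[, N - K - n + kk + 1, drop = FALSE] +
    tab$E[, n + 1] + tab$E[, N - n + 1] - tab$E[, N + 1]
  res <- rep(1, length(kk))
  for (i in seq_along(tab$primes)) res <- res * tab$primes[i]^e[i, ]
  out[ok] <- res
  out
}

oracle_hyper_upper <- function(k, N, K, n, tab = oracle_exp_table(N)) {
  sum(oracle_hyper_pmf(k:min(K, n), N, K, n, tab))
}

oracle_hyper_lower <- function(k, N, K, n, tab = oracle_exp_table(N)) {
  sum(oracle_hyper_pmf(max(0, n + K - N):k, N, K, n, tab))
}
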