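# Exact hypergeometric overlap statistics.
#
# All probabilities are computed in log space from log binomial
# coefficients, with log-sum-exp accumulation for the tails, so universes
# in the thousands cannot overflow. Three conventions are always reported:
# the point mass P[X = k] (what the legacy spreadsheet HYPGEOMDIST
# returns), and the upper/lower tails P[X >= k] / P[X <= k] that sound
# enrichment/depletion inference wants.

#' Natural log of a binomial coefficient
#'
#' Thin domain-checked wrapper used as the numerical backbone of the
#' hypergeometric computations; satisfies
#' \code{log_binomial(n, k) == log_binomial(n, n - k)}.
#'
#' @param n,k non-negative integers (vectorized), \code{k <= n}.
#' @return \code{log(choose(n, k))}.
#' @export
log_binomial <- function(n, k) {
  if (any(n < 0 | k < 0 | k > n | n != trunc(n) | k != trunc(k))) {
    stop_sigreverse("log_binomial requires integers 0 <= k <= n",
                    "sigreverse_domain_error")
  }
  lchoose(n, k)
}

#' Hypergeometric overlap counts
#'
#' Bundles the (N, K, n, k) quadruple of an overlap test: universe size N,
#' category size K within the universe, sample size n, and k observed
#' category members in the sample. Invariants are enforced on construction:
#' \code{K <= N}, \code{n <= N}, \code{max(0, n + K - N) <= k <= min(K, n)}.
#'
#' @param N,K,n,k non-negative integer counts.
#' @return an object of class \code{overlap_counts}.
#' @examples
#' overlap_counts(N = 419, K = 9, n = 41, k = 3)
#' @export
overlap_counts <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (!is_count(v)) {
      stop_sigreverse("overlap counts must be single non-negative integers",
                      "sigreverse_domain_error")
    }
  }
  if (K > N || n > N || k > min(K, n) || k < max(0, n + K - N)) {
    stop_sigreverse(
      sprintf("infeasible overlap counts (N=%d, K=%d, n=%d, k=%d): need K<=N, n<=N, max(0,n+K-N)<=k<=min(K,n)",
              N, K, n, k),
      "sigreverse_domain_error"
    )
  }
  structure(list(N = as.integer(N), K = as.integer(K),
                 n = as.integer(n), k = as.integer(k)),
            class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat(sprintf("<overlap_counts> N=%d, K=%d, n=%d, k=%d (expected %.4g)\n",
              x$N, x$K, x$n, x$k, x$n * x$K / x$N))
  invisible(x)
}

# Log point mass over a vector of k, for scalar N, K, n. Values outside the
# support get -Inf.
hyper_lpmf <- function(k, N, K, n) {
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  out <- rep(-Inf, length(k))
  ok <- k >= lo & k <= hi
  if (any(ok)) {
    out[ok] <- log_binomial(K, k[ok]) + log_binomial(N - K, n - k[ok]) -
      log_binomial(N, n)
  }
  out
}

hyper_upper_log <- function(k, N, K, n) {
  hi <- min(K, n)
  vapply(k, function(ki) {
    if (ki <= max(0, n + K - N)) return(0)  # log(1): whole support
    logsumexp(hyper_lpmf(ki:hi, N, K, n))
  }, 0)
}

hyper_lower_log <- function(k, N, K, n) {
  lo <- max(0, n + K - N)
  vapply(k, function(ki) {
    if (ki >= min(K, n)) return(0)
    logsumexp(hyper_lpmf(lo:ki, N, K, n))
  }, 0)
}

#' Hypergeometric probabilities for an overlap
#'
#' \code{hypergeom_pmf} is the point mass
#' \eqn{P[X = k] = C(K,k) C(N-K, n-k) / C(N,n)};
#' \code{hypergeom_upper} and \code{hypergeom_lower} are the one-sided
#' enrichment and depletion tails \eqn{P[X \ge k]} and \eqn{P[X \le k]}.
#' All are computed in log space.
#'
#' @param counts an \code{\link{overlap_counts}} object.
#' @return a probability in [0, 1].
#' @examples
#' hypergeom_pmf(overlap_counts(419, 9, 41, 3))    # ~0.041
#' hypergeom_upper(overlap_counts(716, 419, 56, 41))
#' @export
hypergeom_pmf <- function(counts) {
  stopifnot(inherits(counts, "overlap_counts"))
  exp(hyper_lpmf(counts$k, counts$N, counts$K, counts$n))
}

#' @rdname hypergeom_pmf
#' @export
hypergeom_upper <- function(counts) {
  stopifnot(inherits(counts, "overlap_counts"))
  min(1, exp(hyper_upper_log(counts$k, counts$N, counts$K, counts$n)))
}

#' @rdname hypergeom_pmf
#' @export
hypergeom_lower <- function(counts) {
  stopifnot(inherits(counts, "overlap_counts"))
  min(1, exp(hyper_lower_log(counts$k, counts$N, counts$K, counts$n)))
}

#' Exact hypergeometric overlap test
#'
#' Tests whether k observed category members among n sampled from a universe
#' of N containing K category members indicate enrichment or depletion.
#' All three probability conventions are reported; the significance call
#' uses the tail convention by default (\code{enriched} iff
#' \eqn{P[X \ge k] < \alpha} and k above expectation; \code{depleted} iff
#' \eqn{P[X \le k] < \alpha} and k below expectation), or the point mass
#' under \code{convention = "point"} for compatibility with legacy
#' spreadsheet-style analyses.
#'
#' @param counts an \code{\link{overlap_counts}} object.
#' @param alpha nominal significance level (default 0.05).
#' @param convention \code{"tail"} (default) or \code{"point"}: which
#'   probability drives the significance call.
#' @return an object of class \code{overlap_result}: the counts, the
#'   expectation nK/N, \code{p_point}, \code{p_upper}, \code{p_lower}, the
#'   call (\code{enriched}/\code{depleted}/\code{neutral}), alpha and the
#'   convention used.
#' @export
overlap_test <- function(counts, alpha = 0.05,
                         convention = c("tail", "point")) {
  stopifnot(inherits(counts, "overlap_counts"),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  convention <- match.arg(convention)
  expected <- counts$n * counts$K / counts$N
  p_point <- hypergeom_pmf(counts)
  p_upper <- hypergeom_upper(counts)
  p_lower <- hypergeom_lower(counts)
  call <- "neutral"
  p_enrich <- if (convention == "tail") p_upper else p_point
  p_deplete <- if (convention == "tail") p_lower else p_point
  if (counts$k > expected && p_enrich < alpha) call <- "enriched"
  if (counts$k < expected && p_deplete < alpha) call <- "depleted"
  structure(
    list(counts = counts, expected = expected,
         p_point = p_point, p_upper = p_upper, p_lower = p_lower,
         call = call, alpha = alpha, convention = convention),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  c <- x$counts
  cat(sprintf("Hypergeometric overlap test (N=%d, K=%d, n=%d, k=%d)\n",
              c$N, c$K, c$n, c$k))
  cat(sprintf("  expected k: %.4g\n", x$expected))
  cat(sprintf("  P[X = k]  = %.4g\n", x$p_point))
  cat(sprintf("  P[X >= k] = %.4g\n", x$p_upper))
  cat(sprintf("  P[X <= k] = %.4g\n", x$p_lower))
  cat(sprintf("  call: %s (alpha = %g, %s convention)\n",
              x$call, x$alpha, x$convention))
  invisible(x)
}

#' @export
as.data.frame.overlap_result <- function(x, ...) {
  c <- x$counts
  data.frame(N = c$N, K = c$K, n = c$n, k = c$k, expected = x$expected,
             p_point = x$p_point, p_upper = x$p_upper, p_lower = x$p_lower,
             call = x$call, stringsAsFactors = FALSE)
}

#' Directional overlap test of a drug set against a pooled disease signature
#'
#' The central reversal test: within the pooled disease universe (up ∪ down,
#' size N), the n drug genes falling in the universe are tested for
#' enrichment among the K upregulated disease genes (upper tail — do drug-
#' downregulated genes over-represent disease-upregulated ones?) and for
#' depletion among the downregulated disease genes (lower tail). Drug genes
#' outside the pooled universe are excluded from n.
#'
#' @param pooled a pooled \code{\link{directional_signature}}.
#' @param drug a homolog-mapped \code{\link{gene_set}} in the same species.
#' @param alpha nominal significance level.
#' @param convention \code{"tail"} or \code{"point"}; see
#'   \code{\link{overlap_test}}.
#' @return an object of class \code{directional_overlap}: the
#'   \code{\link{venn_counts}} and the up-test and down-test
#'   \code{overlap_result}s.
#' @export
directional_overlap_test <- function(pooled, drug, alpha = 0.05,
                                     convention = c("tail", "point")) {
  convention <- match.arg(convention)
  vc <- venn_counts(pooled, drug)
  if (vc$n_universe == 0L) {
    stop_sigreverse("directional overlap test undefined: pooled universe is empty",
                    "sigreverse_domain_error")
  }
  mk <- function(K, k) {
    counts <- overlap_counts(vc$n_universe, K, vc$n_universe_drug, k)
    if (vc$n_universe_drug == 0L) {
      # degenerate: nothing drawn, both tests uninformative
      res <- overlap_test(counts, alpha = alpha, convention = convention)
      res$p_point <- res$p_upper <- res$p_lower <- 1
      res$call <- "neutral"
      return(res)
    }
    overlap_test(counts, alpha = alpha, convention = convention)
  }
  structure(
    list(venn = vc,
         up_test = mk(vc$n_up, vc$n_up_drug),
         down_test = mk(vc$n_down, vc$n_down_drug),
         alpha = alpha, convention = convention),
    class = "directional_overlap"
  )
}

#' @export
print.directional_overlap <- function(x, ...) {
  print(x$venn)
  cat("\nUp-set test (enrichment, nominal p = P[X >= k]):\n")
  print(x$up_test)
  cat("\nDown-set test (depletion, nominal p = P[X <= k]):\n")
  print(x$down_test)
  invisible(x)
}

#' @export
as.data.frame.directional_overlap <- function(x, ...) {
  df <- rbind(as.data.frame(x$up_test), as.data.frame(x$down_test))
  cbind(test = c("up", "down"), df, stringsAsFactors = FALSE)
}
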