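#' Two-sample Wilcoxon/Mann-Whitney rank-sum test
#'
#' One-sided rank-sum p-value used by the SNV read-level filters. Ties are
#' handled by midranks. For combined sample sizes up to
#' `exact_n` (default 25) the exact permutation distribution of the rank
#' sum is computed (tie-aware, by dynamic programming over doubled
#' midranks); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative `"less"` (x stochastically smaller than y) or
#'   `"greater"`.
#' @param exact_n exact/approximate switch on `length(x) + length(y)`.
#' @return p-value in `[0, 1]`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6), "less")  # 1/20
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater"),
                          exact_n = 25) {
  alternative <- match.arg(alternative)
  assert_that(length(x) > 0 && length(y) > 0,
              "rank_sum_test requires non-empty samples")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))              # midranks
  W <- sum(r[seq_len(m)])
  if (N <= exact_n) {
    d <- as.integer(round(2 * r))  # doubled midranks are integers
    p <- ranksum_exact_p(d, m, as.integer(round(2 * W)), alternative)
  } else {
    mu <- m * (N + 1) / 2
    ties <- table(r)
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(1)
    if (alternative == "less") {
      p <- pnorm((W - mu + 0.5) / sqrt(sig2))
    } else {
      p <- pnorm((W - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
    }
  }
  min(max(p, 0), 1)
}

# Exact tail probability of the rank-sum statistic by DP.
# d: doubled midranks of the combined sample; m: size of x;
# w2: observed doubled rank sum of x.
ranksum_exact_p <- function(d, m, w2, alternative) {
  smax <- sum(d)
  # dp[k + 1, s + 1] = number of k-subsets of d with sum s
  dp <- matrix(0, nrow = m + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (di in d) {
    for (k in m:1) {
      idx <- seq_len(smax + 1 - di)
      dp[k + 1, idx + di] <- dp[k + 1, idx + di] + dp[k, idx]
    }
  }
  counts <- dp[m + 1, ]
  total <- sum(counts)
  sums <- 0:smax
  if (alternative == "less") {
    sum(counts[sums <= w2]) / total
  } else {
    sum(counts[sums >= w2]) / total
  }
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values: `q[i] = min over j with p[j] >= p[i] of p[j] * n / rank`
#'   with monotone enforcement; same order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0,1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}
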