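# One-sided Wilcoxon rank-sum p-value P(rank-sum of x >= observed), exact
# under ties for small samples, normal approximation with tie correction
# otherwise. The exact branch enumerates the permutation distribution of the
# rank sum by a subset-sum dynamic program over doubled midranks (midranks
# are multiples of 1/2, so doubling makes them integers); counts stay below
# 2^53 for the sample sizes where the branch is used.

rank_sum_p_greater <- function(x, y, exact_max = 25L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  if (max(n1, n2) <= exact_max) {
    r2 <- round(2 * rank(c(x, y)))
    w2 <- sum(r2[seq_len(n1)])
    total <- sum(r2)
    # dp[k + 1, s + 1] = number of k-subsets of the ranks seen so far
    # with doubled-rank sum s
    dp <- matrix(0, n1 + 1L, total + 1L)
    dp[1L, 1L] <- 1
    for (v in r2) {
      kmax <- min(n1, nrow(dp) - 1L)
      for (k in kmax:1L) {
        shifted <- c(rep(0, v), dp[k, seq_len(total + 1L - v)])
        dp[k + 1L, ] <- dp[k + 1L, ] + shifted
      }
    }
    counts <- dp[n1 + 1L, ]
    sum(counts[seq(w2 + 1L, total + 1L)]) / choose(n1 + n2, n1)
  } else {
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value
  }
}
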