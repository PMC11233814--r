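# Independent reference implementations used as oracles. These are written as
# literal transcriptions of the definitions (triple loops, textbook formulas)
# and must stay independent of the vectorized package code they check.

# Supervised contrastive loss by explicit nested loops over anchors,
# positives and the denominator set.
brute_force_supcon <- function(z, mask, tau) {
  m <- nrow(z)
  total <- 0
  for (r in seq_len(m)) {
    positives <- which(mask[r, ])
    if (length(positives) == 0) next
    l_r <- 0
    for (p in positives) {
      denom <- 0
      for (a in setdiff(seq_len(m), r)) {
        denom <- denom + exp(sum(z[r, ] * z[a, ]) / tau)
      }
      l_r <- l_r + log(exp(sum(z[r, ] * z[p, ]) / tau) / denom)
    }
    total <- total - l_r / length(positives)
  }
  total
}

# Textbook paired t-test: t = mean(d) / (sd(d)/sqrt(n)), dof n-1.
textbook_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, df = n - 1, p_value = 2 * stats::pt(-abs(t), n - 1))
}

# Random unit-norm embedding batch.
random_embeddings <- function(m, e) {
  u <- matrix(rnorm(m * e), m, e)
  u / sqrt(rowSums(u^2))
}

# Random orthogonal matrix via QR.
random_rotation <- function(e) {
  qr.Q(qr(matrix(rnorm(e * e), e)))
}
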