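# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and library calls) they verify.

# Benjamini-Hochberg by the literal min-over-tails definition:
# q_i = min over {j : p_j >= p_i} of min(1, m * p_j / rank(p_j))
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) m * p[j] / sum(p <= p[j]) else Inf
    }, numeric(1))
    min(1, cand)
  }, numeric(1))
}

# hypergeometric upper tail by exhaustive enumeration of the overlap
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# two-group Poisson LRT via glm(), the model the closed form must match
poisson_lrt_glm <- function(y, group, offset) {
  full <- glm(y ~ group, family = poisson(), offset = log(offset))
  null <- glm(y ~ 1, family = poisson(), offset = log(offset))
  as.numeric(null$deviance - full$deviance)
}

# TMM factor for a two-column matrix by the published M/A formula,
# written out directly (log2 ratios of count fractions, precision
# weights, optional symmetric trimming, geometric-mean rescale)
tmm_oracle_two_sample <- function(m, trim_m = 0, trim_a = 0) {
  stopifnot(ncol(m) == 2)
  lib <- colSums(m)
  f1 <- m[, 1] / lib[1]
  f2 <- m[, 2] / lib[2]
  keep <- m[, 1] > 0 & m[, 2] > 0
  M <- log2(f2[keep] / f1[keep])
  A <- 0.5 * log2(f2[keep] * f1[keep])
  w <- 1 / ((lib[2] - m[keep, 2]) / (lib[2] * m[keep, 2]) +
              (lib[1] - m[keep, 1]) / (lib[1] * m[keep, 1]))
  if (trim_m > 0 || trim_a > 0) {
    loM <- quantile(M, trim_m); hiM <- quantile(M, 1 - trim_m)
    loA <- quantile(A, trim_a); hiA <- quantile(A, 1 - trim_a)
    sel <- M >= loM & M <= hiM & A >= loA & A <= hiA
    M <- M[sel]; w <- w[sel]
  }
  f2_vs_1 <- 2^(sum(w * M) / sum(w))
  # rescale the pair so the geometric mean of factors is 1
  f <- c(1, f2_vs_1)
  f / exp(mean(log(f)))
}

# naive substring search (first exact occurrence), for PCR coordinates
naive_find <- function(subject, pattern) {
  as.integer(regexpr(pattern, subject, fixed = TRUE))
}
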