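# Independent oracles used across the suite. Each one evaluates its
# definition directly (enumeration / closed form / loops), sharing no code
# with the implementation it checks.

# KS running-sum enrichment oracle: walks every position of the ranking and
# evaluates the two running deviations of the member empirical CDF from the
# uniform CDF, then normalizes by the extremes obtained from the perfect
# constructions themselves.
oracle_es <- function(positions, n) {
  t <- length(positions)
  raw <- function(pos) {
    member <- rep(FALSE, n)
    member[pos] <- TRUE
    f <- cumsum(member) / t
    dplus <- -Inf
    dminus <- -Inf
    for (i in seq_len(n)) {
      dplus <- max(dplus, f[i] - i / n)
      f_before <- if (i == 1) 0 else f[i - 1]
      dminus <- max(dminus, i / n - f_before)
    }
    if (dplus > dminus) dplus else -dminus
  }
  r <- raw(positions)
  if (r > 0) r / raw(seq_len(t)) else -r / raw(seq(n - t + 1, n))
}

# Benjamini-Hochberg step-up oracle: sort, scale, enforce monotonicity from
# the largest p downwards.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- prev
  }
  q
}

# Spearman rho oracle for tie-free vectors: the classical d^2 formula.
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exact two-sided binomial p at 0.5 by enumeration: sum of all outcome
# probabilities not exceeding the observed one.
oracle_binom_two_sided <- function(k, n) {
  probs <- choose(n, 0:n) * 0.5^n
  sum(probs[probs <= probs[k + 1] + 1e-12])
}

# Hypergeometric upper tail by direct summation.
oracle_hyper_tail <- function(k, K, N, h) {
  kk <- k:min(K, h)
  sum(choose(K, kk) * choose(N - K, h - kk)) / choose(N, h)
}

# One-way ANOVA ICC oracle (k = 2), written as explicit loops over pairs.
oracle_icc <- function(values, pair) {
  pairs <- unique(pair)
  a <- length(pairs)
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  for (p in pairs) {
    v <- values[pair == p]
    ssb <- ssb + 2 * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  msb <- ssb / (a - 1)
  msw <- ssw / a
  (msb - msw) / (msb + msw)
}

# Brute-force substring match counter (one transcript counted once however
# many times the probe occurs inside it).
oracle_match_count <- function(probe, sequences) {
  sum(vapply(sequences, function(s) grepl(probe, s, fixed = TRUE), logical(1)))
}
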