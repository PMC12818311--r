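# Independent oracles used across test files.

# Clopper-Pearson interval by brute-force binomial tail sums (no pbinom):
# lower bound p solves sum_{k >= x} C(n,k) p^k (1-p)^(n-k) = alpha/2,
# upper bound solves sum_{k <= x} ... = alpha/2.
oracle_binom_ci <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  upper_tail <- function(p) sum(choose(n, x:n) * p^(x:n) * (1 - p)^(n - (x:n)))
  lower_tail <- function(p) sum(choose(n, 0:x) * p^(0:x) * (1 - p)^(n - (0:x)))
  lo <- if (x == 0) 0 else
    uniroot(function(p) upper_tail(p) - alpha / 2, c(1e-12, 1 - 1e-12),
            tol = 1e-10)$root
  hi <- if (x == n) 1 else
    uniroot(function(p) lower_tail(p) - alpha / 2, c(1e-12, 1 - 1e-12),
            tol = 1e-10)$root
  c(lo, hi)
}

# O(n^2) pairwise-comparison AUC oracle
oracle_auc <- function(a, b) {
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# trapezoid ring-locus average at high node count
oracle_ring_average <- function(fn, e, D, n = 1e4) {
  phi <- (seq_len(n) - 0.5) / n * 2 * pi
  R <- D / 2
  mean(resolution_at(fn, sqrt(e^2 + R^2 + 2 * e * R * cos(phi))))
}

# latencies on an exact recinormal quantile grid (no sampling noise)
recinormal_quantile_grid <- function(n, mu, sigma, t0 = 0) {
  p <- qnorm((seq_len(n) - 0.5) / n, mu, sigma)
  t0 + 1 / p
}
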