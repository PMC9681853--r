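# Independent brute-force oracles, kept deliberately naive and separate from
# the package's own computation paths.

# two-sided exact Wilcoxon p by full enumeration of rank assignments
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  subsets <- utils::combn(n + m, n)
  us <- apply(subsets, 2, function(ix) sum(seq_len(n + m)[ix]) - n * (n + 1) / 2)
  total <- length(us)
  p <- 2 * min(sum(us <= u_obs), sum(us >= u_obs)) / total
  min(p, 1)
}

# one-sided upper binomial tail by direct pmf summation
oracle_binomial_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), numeric(1)))
}

# Spearman as Pearson on hand-computed average ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# running-sum ES by an explicit position-by-position loop; magnitude ties
# (within accumulation precision) resolve to the positive extreme
oracle_es <- function(scores, is_member, weight = 1) {
  n <- length(scores)
  k <- sum(is_member)
  wsum <- sum(abs(scores[is_member])^weight)
  run <- 0
  hi <- -Inf
  lo <- Inf
  for (i in seq_len(n)) {
    run <- run + if (is_member[i]) abs(scores[i])^weight / wsum else -1 / (n - k)
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

# BH step-up by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
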