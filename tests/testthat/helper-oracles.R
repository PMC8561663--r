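# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formula
# evaluation, and rank-then-Pearson constructions.

# all compositions of N into k nonnegative parts (k x small N only)
enumerate_compositions <- function(k, N) {
  if (k == 1L) return(matrix(N, 1L))
  out <- NULL
  for (i in 0:N) {
    rest <- enumerate_compositions(k - 1L, N - i)
    out <- rbind(out, cbind(i, rest, deparse.level = 0))
  }
  out
}

# all permutations of 1..n (n <= 7)
enumerate_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  sub <- enumerate_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      block <- sub
      block <- cbind(block[, seq_len(pos - 1L), drop = FALSE], n,
                     block[, pos:(n - 1L), drop = FALSE])
    }
    out <- rbind(out, block)
  }
  out
}

# Spearman by explicit average-ranking then Pearson
oracle_spearman <- function(a, b) {
  stats::cor(rank(a), rank(b))
}

# ANOSIM R from its definition on distance ranks
oracle_anosim_R <- function(d, groups) {
  v <- as.matrix(d)
  pairs <- which(upper.tri(v), arr.ind = TRUE)
  dv <- v[upper.tri(v)]
  rk <- rank(dv)
  between <- groups[pairs[, 1L]] != groups[pairs[, 2L]]
  (mean(rk[between]) - mean(rk[!between])) / (length(dv) / 2)
}

# one-factor pseudo-F from the squared-distance sum-of-squares identity
oracle_permanova_F <- function(d, groups) {
  v <- as.matrix(d)^2
  n <- nrow(v)
  ss_total <- sum(v[upper.tri(v)]) / n
  ss_within <- 0
  for (lev in unique(groups)) {
    idx <- groups == lev
    vi <- v[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(vi[upper.tri(vi)]) / sum(idx)
  }
  ss_between <- ss_total - ss_within
  g <- length(unique(groups))
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# small deterministic community fixture
toy_community <- function() {
  community_matrix(
    rbind(c(5L, 3L, 2L), c(1L, 7L, 2L), c(4L, 4L, 2L),
          c(9L, 0L, 1L), c(2L, 2L, 6L), c(3L, 5L, 2L)),
    lineage = c("a", "a", "a", "b", "b", "b")
  )
}

# the interacting alternative frozen for power checks: two anticorrelated
# four-species blocks driven by one latent factor
interacting_alternative <- function(n_hosts = 150L) {
  w <- c(1, 1, 1, 1, -1, -1, -1, -1)
  sigma <- 0.8^2 * (w %o% w) + diag(rep(0.1, 8L))
  synthetic_spec(
    n_hosts, model = "interacting",
    mu = log(c(0.3, 0.2, 0.1, 0.05, 0.15, 0.1, 0.06, 0.04)),
    sigma = sigma
  )
}
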