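test_that("spearman_matrix matches a rank-then-Pearson oracle, with ties", {
  x <- cbind(a = c(3L, 1L, 4L, 4L, 2L),  # tie at rank 4/5
             b = c(10L, 2L, 9L, 7L, 2L)) # tie at rank 1/2
  m <- community_matrix(x, lineage = "t")
  r <- spearman_matrix(m)
  expect_equal(r[1L, 2L], oracle_spearman(x[, 1L], x[, 2L]), tolerance = 1e-12)
  expect_true(isSymmetric(r))
  expect_equal(diag(r), c(a = 1, b = 1))

  # identical columns correlate at 1; reversed ranking at -1
  y <- cbind(c(1L, 2L, 3L, 4L), c(2L, 4L, 6L, 8L), c(9L, 7L, 5L, 3L))
  ry <- spearman_matrix(community_matrix(y, "t"))
  expect_equal(ry[1L, 2L], 1)
  expect_equal(ry[1L, 3L], -1)

  # zero-variance species defines no pairs
  z <- cbind(c(1L, 2L, 3L), c(5L, 5L, 5L))
  rz <- spearman_matrix(community_matrix(z, "t"))
  expect_true(is.na(rz[1L, 2L]))

  expect_error(spearman_matrix(community_matrix(y[1:2, ], "t")), ">= 3 hosts")
})

test_that("correlation_quantiles uses linear interpolation over defined upper-triangle pairs", {
  # pair set {-0.4, 0, 0.4, 0.8} at level 0.5 interpolates to 0.2
  corr2 <- diag(4)
  corr2[1, 2] <- -0.4; corr2[1, 3] <- 0; corr2[1, 4] <- 0.4; corr2[2, 3] <- 0.8
  corr2[2, 4] <- NA; corr2[3, 4] <- NA
  corr2[lower.tri(corr2)] <- t(corr2)[lower.tri(corr2)]
  q <- correlation_quantiles(corr2, levels = 0.5)
  expect_equal(as.numeric(q), 0.2)
  expect_identical(attr(q, "n_pairs"), 4L)

  # a single defined pair returns its value at every level
  one <- diag(2)
  one[1L, 2L] <- one[2L, 1L] <- 0.3
  q2 <- correlation_quantiles(one, levels = c(0.2, 0.8))
  expect_equal(as.numeric(q2), c(0.3, 0.3))

  expect_error(correlation_quantiles(diag(2) * NA + diag(2)), "no defined")
})

test_that("the neutral test is reproducible, bounded, and respects the boundary definition", {
  spec <- lineage_preset("N2", n_hosts = 40L)
  m <- generate_neutral(spec, seed = 5L)
  r1 <- suppressWarnings(neutral_correlation_test(m, B = 10L, seed = 99L))
  r2 <- suppressWarnings(neutral_correlation_test(m, B = 10L, seed = 99L))
  expect_identical(r1$null_q, r2$null_q)
  expect_identical(c(r1$p_lower, r1$p_upper), c(r2$p_lower, r2$p_upper))
  expect_identical(nrow(r1$null_q), 10L)
  expect_true(r1$p_lower >= 0 && r1$p_lower <= 1)
  expect_true(r1$p_upper >= 0 && r1$p_upper <= 1)
  expect_lte(r1$empirical_q[1L], r1$empirical_q[2L])

  # empirical q80 above every simulated q80 gives p_upper exactly 0
  m_strong <- generate_interacting(interacting_alternative(60L), seed = 3L)
  rs <- suppressWarnings(neutral_correlation_test(m_strong, B = 25L, seed = 1L))
  if (rs$empirical_q[2L] > max(rs$null_q[, 2L])) {
    expect_identical(rs$p_upper, 0)
  }

  expect_error(neutral_correlation_test(m, B = 0L), "B")
})

test_that("p-values are invariant to species column order", {
  spec <- lineage_preset("N2", n_hosts = 60L)
  m <- generate_neutral(spec, seed = 17L)
  perm <- c(3L, 1L, 8L, 5L, 2L, 7L, 4L, 6L)
  m_perm <- subset_community(m, species = perm)
  r1 <- suppressWarnings(neutral_correlation_test(m, B = 200L, seed = 11L))
  r2 <- suppressWarnings(neutral_correlation_test(m_perm, B = 200L, seed = 11L))
  # empirical quantiles are exactly order-invariant; the null p-values are
  # equal in distribution, so two independent draws agree to Monte-Carlo error
  expect_equal(r1$empirical_q, r2$empirical_q, tolerance = 1e-12)
  expect_equal(r1$p_lower, r2$p_lower, tolerance = 0.15)
  expect_equal(r1$p_upper, r2$p_upper, tolerance = 0.15)
})

test_that("null correlations arise from sampling and tighten with host count", {
  # the spurious negative tail of the neutral null shrinks as hosts grow
  fit <- list(pi = lineage_preset("N2")$pi, theta = 0.1698)
  small <- simulate_structure_matched(fit, rep(10000L, 164L), seed = 21L)
  large <- simulate_structure_matched(fit, rep(10000L, 16400L), seed = 22L)
  r_small <- spearman_matrix(small)[upper.tri(diag(8L))]
  r_large <- spearman_matrix(large)[upper.tri(diag(8L))]
  expect_lt(min(r_large, na.rm = TRUE), 0.05)  # negatives are small...
  expect_lt(diff(range(r_large, na.rm = TRUE)),
            diff(range(r_small, na.rm = TRUE)))  # ...and the spread shrinks
})
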