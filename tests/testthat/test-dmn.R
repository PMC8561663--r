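test_that("dm_log_likelihood matches closed-form small cases", {
  # one host, counts (1,1), pi = (1/2, 1/2), theta = 1/2: probability 1/4
  m <- community_matrix(matrix(c(1L, 1L), 1L), lineage = "x")
  expect_equal(dm_log_likelihood(m, c(0.5, 0.5), 0.5), log(0.25),
               tolerance = 1e-12)

  # a single species always has probability 1
  m1 <- community_matrix(matrix(c(3L, 7L), 2L), lineage = "x")
  expect_identical(dm_log_likelihood(m1, 1, 0.3), 0)

  # theta -> 0 recovers the multinomial log-likelihood
  x <- rbind(c(4L, 1L, 2L), c(0L, 3L, 3L))
  m2 <- community_matrix(x, lineage = "x")
  pi <- c(0.5, 0.2, 0.3)
  ll_mult <- sum(apply(x, 1L, function(r) stats::dmultinom(r, prob = pi, log = TRUE)))
  expect_equal(dm_log_likelihood(m2, pi, 1e-8), ll_mult, tolerance = 1e-4)

  expect_error(dm_log_likelihood(m, c(0.7, 0.5), 0.5), "simplex")
  expect_error(dm_log_likelihood(m, c(0.5, 0.5), 1), "theta")
})

test_that("the pmf is normalized (brute-force enumeration)", {
  pi2 <- c(0.35, 0.65)
  pi3 <- c(0.2, 0.5, 0.3)
  for (k in 2:3) {
    pi <- if (k == 2L) pi2 else pi3
    for (N in 2:6) {
      comps <- enumerate_compositions(k, N)
      total <- sum(apply(comps, 1L, function(x) {
        exp(dm_log_likelihood(community_matrix(matrix(x, 1L), "z"),
                              pi, theta = 0.25))
      }))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("fit_dmn recovers known parameters and ascends from its initializer", {
  spec <- synthetic_spec(
    1000L, "neutral", pi = c(0.6, 0.3, 0.1), theta = 0.2,
    total_model = list(type = "fixed", totals = rep(5000L, 1000L))
  )
  m <- generate_neutral(spec, seed = 42L)
  fit <- fit_dmn(m)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta - 0.2), 3 * fit$se_theta)
  expect_true(all(abs(fit$pi - c(0.6, 0.3, 0.1)) < 3 * fit$se_pi))
  # loglik is consistent with dm_log_likelihood at the fitted parameters
  expect_equal(fit$loglik, dm_log_likelihood(m, fit$pi, fit$theta),
               tolerance = 1e-10)
  # monotone ascent: at least as good as the method-of-moments start
  init <- nemacomm:::.dm_moment_init(m$counts)
  expect_gte(fit$loglik, dm_log_likelihood(m, init$pi, init$theta))
  # invariants of the returned parameterization
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  expect_true(fit$theta > 0 && fit$theta < 1)
  expect_equal(sum(fit$gamma), (1 - fit$theta) / fit$theta, tolerance = 1e-8)
})

test_that("estimation bias shrinks as the host sample grows", {
  err <- vapply(c(200L, 2000L), function(n) {
    spec <- synthetic_spec(
      n, "neutral", pi = c(0.5, 0.3, 0.2), theta = 0.15,
      total_model = list(type = "fixed", totals = rep(2000L, n))
    )
    fits <- vapply(1:5, function(i) {
      fit_dmn(generate_neutral(spec, seed = 1000L * n + i))$theta
    }, numeric(1L))
    mean(abs(fits - 0.15))
  }, numeric(1L))
  expect_lt(err[2L], err[1L])
})

test_that("all-zero species are dropped with a warning, mirroring absent species", {
  x <- cbind(c(5L, 8L, 2L), 0L, c(1L, 0L, 4L))
  colnames(x) <- c("MYb71", "MYb181", "MYb120")
  m <- community_matrix(x, lineage = "daf-2")
  expect_warning(fit <- fit_dmn(m), "MYb181")
  expect_identical(fit$dropped_species, "MYb181")
  expect_identical(names(fit$pi), c("MYb71", "MYb120"))

  expect_error(fit_dmn(community_matrix(matrix(1:2, 1L), "x")),
               "insufficient samples")
})

test_that("structure-matched simulation conserves totals and obeys the seed", {
  fit <- list(pi = c(0.7, 0.2, 0.1), theta = 0.2)
  s1 <- simulate_structure_matched(fit, c(100L, 200L, 0L), seed = 7L)
  expect_identical(s1$totals, c(100L, 200L, 0L))
  s2 <- simulate_structure_matched(fit, c(100L, 200L, 0L), seed = 7L)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_structure_matched(fit, c(100L, 200L, 0L), seed = 8L)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("simulated moments match the Dirichlet-multinomial formulas", {
  # near-zero theta: per-species means approach N * pi
  fit0 <- list(pi = c(0.5, 0.5), theta = 1e-6)
  s <- simulate_structure_matched(fit0, rep(100L, 10000L), seed = 1L)
  expect_lt(abs(mean(s$counts[, 1L]) - 50) / 50, 0.01)

  # composition variance: Var(x_j/N) = pi_j (1-pi_j) (theta + (1-theta)/N)
  fit <- list(pi = c(0.3, 0.7), theta = 0.1)
  N <- 200L
  s2 <- simulate_structure_matched(fit, rep(N, 20000L), seed = 2L)
  v_obs <- stats::var(s2$counts[, 1L] / N)
  v_th <- 0.3 * 0.7 * (0.1 + 0.9 / N)
  expect_lt(abs(v_obs - v_th) / v_th, 0.05)
})
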