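test_that("log_standardize centers and scales per species, with ln(x+1)", {
  m <- toy_community()
  z <- log_standardize(m)
  expect_equal(unname(colMeans(z)), rep(0, 3L), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2L, sd)), rep(1, 3L), tolerance = 1e-12)

  # a zero count is ln(1) = 0 before standardization
  lx <- log_standardize(m, standardize = "none")
  expect_identical(lx[m$counts == 0], rep(0, sum(m$counts == 0)))
  expect_equal(lx, log(m$counts + 1), ignore_attr = TRUE)

  # doubling one species touches only that column pre-standardization
  m2 <- m
  m2$counts[, 2L] <- m2$counts[, 2L] * 2L
  lx2 <- log_standardize(community_matrix(m2$counts, m2$lineage),
                         standardize = "none")
  expect_identical(lx2[, c(1L, 3L)], lx[, c(1L, 3L)])
  expect_false(identical(lx2[, 2L], lx[, 2L]))

  # constant columns are zeroed with a warning
  const <- community_matrix(cbind(c(1L, 2L, 3L), 4L), "x")
  expect_warning(zc <- log_standardize(const), "constant")
  expect_identical(unname(zc[, 2L]), rep(0, 3L))
})

test_that("pca_ordination matches a covariance-eigendecomposition oracle", {
  set.seed(13)
  x <- matrix(rnorm(40), 10L, 4L)
  res <- pca_ordination(x, n_components = 4L)
  expect_equal(sum(res$variance_fraction_all), 1, tolerance = 1e-10)
  expect_true(all(res$variance_fraction >= 0))
  # orthogonality of components
  expect_equal(crossprod(res$loadings), diag(4L),
               ignore_attr = TRUE, tolerance = 1e-10)

  eig <- eigen(stats::cov(x), symmetric = TRUE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  for (j in 1:4) {
    sc_o <- xc %*% eig$vectors[, j]
    # compare up to sign
    agree <- min(max(abs(res$scores[, j] - sc_o)),
                 max(abs(res$scores[, j] + sc_o)))
    expect_lt(agree, 1e-8)
  }
  expect_equal(res$variance_fraction_all,
               eig$values / sum(eig$values), tolerance = 1e-10)
  # sign convention: dominant loading of each component is positive
  for (j in 1:4) {
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }

  # collinear 2-D cloud: one component carries all variance
  y <- cbind(1:6, 2 * (1:6))
  resy <- suppressWarnings(pca_ordination(y, n_components = 2L))
  expect_equal(resy$variance_fraction_all[1L], 1, tolerance = 1e-10)
  expect_warning(pca_ordination(y, n_components = 2L), "rank")
})

test_that("bray_curtis evaluates the formula and stays within [0, 1]", {
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2), c(3, 0)))), 2 / 3,
               tolerance = 1e-12)
  expect_equal(as.numeric(bray_curtis(rbind(c(2, 5), c(2, 5)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(3, 0), c(0, 7)))), 1)
  expect_warning(dz <- bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_equal(as.numeric(dz), 0)

  m <- toy_community()
  d <- bray_curtis(log_standardize(m, "none"))
  v <- as.matrix(d)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(isSymmetric(v))
  expect_identical(unname(diag(v)), rep(0, 6L))
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "nonnegative")
})

test_that("anosim agrees with its exhaustive-permutation oracle", {
  m <- toy_community()
  d <- bray_curtis(log_standardize(m, "none"))
  g <- m$lineage
  res <- anosim_test(d, g, n_perm = 719L, seed = 1L)
  expect_equal(res$R, oracle_anosim_R(d, g), tolerance = 1e-12)
  expect_gte(res$R, -1)
  expect_lte(res$R, 1)

  perms <- enumerate_permutations(6L)
  r_perm <- apply(perms, 1L, function(p) oracle_anosim_R(d, g[p]))
  p_exhaustive <- mean(r_perm >= res$R - 1e-12)
  expect_equal(res$p, p_exhaustive, tolerance = 1e-12)

  expect_error(anosim_test(d, rep("a", 6L)), ">= 2 groups")
})

test_that("permanova agrees with the direct sum-of-squares oracle", {
  m <- toy_community()
  d <- bray_curtis(log_standardize(m, "none"))
  g <- m$lineage
  res <- permanova_test(d, g, n_perm = 719L, seed = 1L)
  expect_equal(res$F, oracle_permanova_F(d, g), tolerance = 1e-10)

  perms <- enumerate_permutations(6L)
  f_perm <- apply(perms, 1L, function(p) oracle_permanova_F(d, g[p]))
  expect_equal(res$p, mean(f_perm >= res$F - 1e-12), tolerance = 1e-12)

  # widely separated clusters saturate significance at 1/(n_perm+1)
  # (10 per group, so partition-preserving permutations are vanishingly rare)
  set.seed(5)
  far <- rbind(matrix(c(100L, 0L), 10L, 2L, byrow = TRUE) + rpois(20L, 2),
               matrix(c(0L, 100L), 10L, 2L, byrow = TRUE) + rpois(20L, 2))
  dfar <- bray_curtis(far)
  gfar <- rep(c("a", "b"), each = 10L)
  resf <- permanova_test(dfar, gfar, n_perm = 99L, seed = 2L)
  expect_equal(resf$p, 1 / 100)

  # label-permutation invariance: permuting hosts and labels together
  set.seed(9)
  pp <- sample(6L)
  d_perm <- stats::as.dist(as.matrix(d)[pp, pp])
  res2 <- permanova_test(d_perm, g[pp], n_perm = 199L, seed = 3L)
  expect_equal(res2$F, res$F, tolerance = 1e-10)
})

test_that("anosim R is near zero under random labelings", {
  set.seed(23)
  m <- generate_neutral(lineage_preset("N2", n_hosts = 60L), seed = 51L)
  d <- bray_curtis(log_standardize(m, "none"))
  inside <- 0L
  for (i in 1:40) {
    g <- sample(rep(c("a", "b"), each = 30L))
    r <- oracle_anosim_R(d, g)
    inside <- inside + (abs(r) < 0.1)
  }
  expect_gte(inside / 40, 0.95)
})
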