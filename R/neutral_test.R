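#' Pairwise Spearman correlation matrix of species counts
#'
#' Rank correlations between species across hosts, computed on raw counts
#' (not relative abundances): with per-host totals varying over orders of
#' magnitude, a positive correlation between two species' counts can simply
#' reflect common species being common together, which is exactly the
#' pattern the neutral null reproduces and the quantile test accounts for.
#' Ties receive average ranks. A species with zero variance across hosts
#' defines no correlation; its pairs are `NA`.
#'
#' @param m A [community_matrix()] or a numeric hosts-by-species matrix.
#' @return k-by-k symmetric matrix with unit diagonal; undefined pairs `NA`.
#' @export
spearman_matrix <- function(m) {
  x <- if (inherits(m, "community_matrix")) m$counts else as.matrix(m)
  if (nrow(x) < 3L) stop("need >= 3 hosts for rank correlations")
  r <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(r) <- 1
  r
}

#' Quantiles of the off-diagonal correlation distribution
#'
#' Quantiles over the upper-triangle entries of a correlation matrix,
#' excluding undefined (`NA`) pairs, with the linear-interpolation
#' convention between order statistics.
#'
#' @param corr Symmetric correlation matrix (as from [spearman_matrix()]).
#' @param levels Quantile levels, e.g. `c(0.2, 0.8)`.
#' @return Named numeric vector, one value per level, with attribute
#'   `"n_pairs"` giving the number of defined pairs used.
#' @export
correlation_quantiles <- function(corr, levels = c(0.2, 0.8)) {
  vals <- corr[upper.tri(corr)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no defined species pairs")
  q <- stats::quantile(vals, probs = levels, type = 7, names = FALSE)
  names(q) <- paste0("q", formatC(100 * levels, format = "d"))
  attr(q, "n_pairs") <- length(vals)
  q
}

#' Test empirical correlation quantiles against the neutral null
#'
#' The package's core inference. The Dirichlet-multinomial neutral model is
#' fitted to the data; `B` structure-matched data sets (same hosts, same
#' per-host totals) are simulated from the fit; and the chosen quantiles of
#' the pairwise Spearman correlation distribution are compared between data
#' and null. With the default 20th/80th levels:
#' `p_lower` is the fraction of simulated data sets whose 20th quantile is
#' lower than the empirical one (evidence of excess negative correlation,
#' e.g. competition), and `p_upper` the fraction whose 80th quantile is
#' higher than the empirical one (evidence of excess positive correlation).
#'
#' @param m A [community_matrix()].
#' @param B Number of simulated data sets (10,000 for production use;
#'   smaller for exploration).
#' @param levels Two quantile levels, lower then upper.
#' @param seed Integer seed making the whole test reproducible.
#' @param inclusive If `FALSE` (default) the p-value counts strict
#'   inequalities, following the "lower"/"higher" reading; if `TRUE`, ties
#'   count as extreme and a +1 correction is applied to numerator and
#'   denominator (the conservative permutation convention), for
#'   sensitivity analysis.
#' @param fit Optionally a pre-computed `dm_fit` to reuse.
#' @return Object of class `null_test_result`: list with `quantile_levels`,
#'   `empirical_q`, `null_q` (B-by-2 matrix), `p_lower`, `p_upper`, `B`,
#'   `n_pairs_used` (empirical), `null_n_pairs` (per simulation), `seed`,
#'   and the `fit`.
#' @export
neutral_correlation_test <- function(m, B = 10000L, levels = c(0.2, 0.8),
                                     seed = 1L, inclusive = FALSE,
                                     fit = NULL) {
  stopifnot(inherits(m, "community_matrix"))
  if (B < 1L) stop("B must be >= 1")
  if (length(levels) != 2L || levels[1L] >= levels[2L]) {
    stop("levels must be two increasing quantile levels")
  }
  if (is.null(fit)) fit <- fit_dmn(m)
  emp <- correlation_quantiles(spearman_matrix(m), levels)
  totals <- m$totals
  set.seed(seed)
  null_q <- matrix(NA_real_, B, 2L,
                   dimnames = list(NULL, names(emp)))
  null_pairs <- integer(B)
  for (b in seq_len(B)) {
    sim <- .r_dirichlet_multinomial(totals, fit$gamma)
    r <- suppressWarnings(stats::cor(sim, method = "spearman"))
    vals <- r[upper.tri(r)]
    vals <- vals[!is.na(vals)]
    null_pairs[b] <- length(vals)
    if (length(vals) > 0L) {
      null_q[b, ] <- stats::quantile(vals, probs = levels, type = 7,
                                     names = FALSE)
    }
  }
  lo <- null_q[, 1L]
  hi <- null_q[, 2L]
  if (inclusive) {
    p_lower <- (sum(lo <= emp[1L], na.rm = TRUE) + 1) / (B + 1)
    p_upper <- (sum(hi >= emp[2L], na.rm = TRUE) + 1) / (B + 1)
  } else {
    p_lower <- sum(lo < emp[1L], na.rm = TRUE) / B
    p_upper <- sum(hi > emp[2L], na.rm = TRUE) / B
  }
  structure(
    list(quantile_levels = levels,
         empirical_q = as.numeric(emp),
         null_q = null_q,
         p_lower = p_lower, p_upper = p_upper,
         B = B, n_pairs_used = attr(emp, "n_pairs"),
         null_n_pairs = null_pairs,
         seed = seed, inclusive = inclusive, fit = fit),
    class = "null_test_result"
  )
}

#' @export
print.null_test_result <- function(x, ...) {
  lv <- x$quantile_levels
  cat(sprintf("Neutral correlation quantile test (B = %d, seed = %d)\n",
              x$B, x$seed))
  cat(sprintf("  empirical q%d = %.4f, q%d = %.4f (%d species pairs)\n",
              round(100 * lv[1L]), x$empirical_q[1L],
              round(100 * lv[2L]), x$empirical_q[2L], x$n_pairs_used))
  cat(sprintf("  p(null q%d lower)  = %.4g\n", round(100 * lv[1L]), x$p_lower))
  cat(sprintf("  p(null q%d higher) = %.4g\n", round(100 * lv[2L]), x$p_upper))
  invisible(x)
}
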