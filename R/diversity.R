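#' Shannon diversity of one host's counts
#'
#' \eqn{H = -\sum_j p_j \ln p_j} over species proportions
#' \eqn{p_j = x_j / \sum x}, natural log, with the limit convention
#' \eqn{p \ln p \to 0} for absent species. The maximum for k species is
#' \eqn{\ln k} (e.g. \eqn{\ln 8 \approx 2.08} for an eight-species
#' community), attained at the uniform composition.
#'
#' @param counts Nonnegative numeric vector of one host's species counts,
#'   with positive total.
#' @return Scalar diversity in nats.
#' @examples
#' shannon(rep(5, 8))  # log(8)
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total <= 0) stop("all-zero host: diversity undefined")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Per-host Shannon diversity and log10 community size
#'
#' @param m A [community_matrix()].
#' @return Data frame with `host_id`, `lineage`, `H`, `log10_total`.
#' @export
diversity_table <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (any(m$totals <= 0)) stop("all hosts must have positive totals")
  data.frame(
    host_id = m$host_ids,
    lineage = m$lineage,
    H = apply(m$counts, 1L, shannon),
    log10_total = log10(m$totals)
  )
}

# ML Gaussian log-likelihood of a least-squares fit (variance = SSE/n)
.gauss_loglik <- function(sse, n) {
  -n / 2 * (log(2 * pi) + log(sse / n) + 1)
}

#' Linear fit of Shannon diversity on log10 community size
#'
#' Ordinary least squares of per-host diversity \eqn{H} on
#' \eqn{\log_{10}}(total CFU per host) — the diversity-population-size
#' relationship summarizing successional state of the communities.
#'
#' @param m A [community_matrix()].
#' @return Object of class `diversity_fit`: list with `slope`, `intercept`,
#'   `residual_variance` (ML, SSE/n), `r2_adjusted`, `p_slope`, `n`,
#'   `loglik` (Gaussian, at the MLE), and the underlying `lm` object.
#' @export
diversity_size_fit <- function(m) {
  tab <- diversity_table(m)
  if (nrow(tab) < 3L) stop("need >= 3 hosts")
  if (stats::var(tab$log10_total) == 0) stop("zero variance in log10 totals")
  fit <- stats::lm(H ~ log10_total, data = tab)
  s <- summary(fit)
  sse <- sum(stats::residuals(fit)^2)
  n <- nrow(tab)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         residual_variance = sse / n,
         r2_adjusted = s$adj.r.squared,
         p_slope = s$coefficients[2L, 4L],
         n = n,
         loglik = .gauss_loglik(sse, n),
         lm = fit),
    class = "diversity_fit"
  )
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat(sprintf("H = %.3f %+.3f * log10(CFU/host)   [n = %d]\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("R2(adj) = %.3f, slope p = %.3g, logLik = %.3f\n",
              x$r2_adjusted, x$p_slope, x$loglik))
  invisible(x)
}

#' Likelihood-ratio test: one shared line versus per-group lines
#'
#' Compares H0, a single regression of y on x fitted to the pooled points
#' (one slope, one intercept, one Gaussian variance), against H1, separate
#' fits per group. By default H1 also frees the residual variance per
#' group, so the statistic has 3(G-1) degrees of freedom for G groups;
#' `common_variance = TRUE` keeps a single pooled variance under H1
#' (2(G-1) df). The statistic is
#' \eqn{2(\ell_1 - \ell_0)} referred to its chi-squared distribution.
#'
#' @param x,y Numeric vectors of points.
#' @param group Group label per point (2 or more groups).
#' @param common_variance Share one residual variance across groups under
#'   H1?
#' @return Object of class `lrt_result`: `loglik_h0`, `loglik_h1`,
#'   `statistic`, `df`, `p_value`, `n`, `groups`.
#' @export
pooled_vs_separate_lrt <- function(x, y, group, common_variance = FALSE) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (length(x) != length(y) || length(x) != length(group)) {
    stop("x, y, group must have equal length")
  }
  n <- length(x)
  fit0 <- stats::lm(y ~ x)
  ll0 <- .gauss_loglik(sum(stats::residuals(fit0)^2), n)
  if (common_variance) {
    fit1 <- stats::lm(y ~ x * group)
    ll1 <- .gauss_loglik(sum(stats::residuals(fit1)^2), n)
    df <- 2L * (nlevels(group) - 1L)
  } else {
    ll1 <- 0
    for (g in levels(group)) {
      idx <- group == g
      if (sum(idx) < 3L) stop("each group needs >= 3 points")
      fg <- stats::lm(y[idx] ~ x[idx])
      ll1 <- ll1 + .gauss_loglik(sum(stats::residuals(fg)^2), sum(idx))
    }
    df <- 3L * (nlevels(group) - 1L)
  }
  stat <- 2 * (ll1 - ll0)
  structure(
    list(loglik_h0 = ll0, loglik_h1 = ll1, statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         n = n, groups = levels(group)),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT pooled vs per-group lines: chi2 = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  logLik H0 = %.3f, H1 = %.3f (groups: %s)\n",
              x$loglik_h0, x$loglik_h1, paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Likelihood-ratio test of diversity-size relationships between lineages
#'
#' Do two host lineages share one diversity-population-size line? H0 pools
#' their (log10 total, H) points into a single fit; H1 fits each lineage
#' separately (separate variances by default, df = 3).
#'
#' @param m_a,m_b [community_matrix()] objects, one per lineage.
#' @inheritParams pooled_vs_separate_lrt
#' @return An `lrt_result` (see [pooled_vs_separate_lrt()]).
#' @export
diversity_size_lrt <- function(m_a, m_b, common_variance = FALSE) {
  ta <- diversity_table(m_a)
  tb <- diversity_table(m_b)
  pooled_vs_separate_lrt(
    x = c(ta$log10_total, tb$log10_total),
    y = c(ta$H, tb$H),
    group = rep(c("a", "b"), c(nrow(ta), nrow(tb))),
    common_variance = common_variance
  )
}
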