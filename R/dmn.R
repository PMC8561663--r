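#' Dirichlet-multinomial log-likelihood of a count table
#'
#' The neutral sampling model for per-host community counts: each host's
#' composition is drawn from a Dirichlet with concentration
#' \eqn{\gamma_j = \pi_j (1-\theta)/\theta}, and counts from a multinomial
#' with that composition and the host's observed total. \eqn{\pi} is the
#' expected relative abundance per species and \eqn{\theta \in (0,1)} the
#' overdispersion: \eqn{\theta \to 0} recovers the plain multinomial with
#' probabilities \eqn{\pi}, larger \eqn{\theta} means more between-host
#' compositional variance.
#'
#' @param m A [community_matrix()] (or a plain integer matrix of counts).
#' @param pi Numeric vector on the probability simplex, one entry per
#'   species.
#' @param theta Overdispersion, strictly inside (0, 1).
#' @param include_coef Include the multinomial coefficients
#'   \eqn{\log N_i! - \sum_j \log x_{ij}!}? `TRUE` gives the normalized pmf
#'   (the package default everywhere). `FALSE` omits this data-only
#'   constant, the convention of some published maximum-likelihood tables;
#'   the two differ by an additive term that does not depend on
#'   (\eqn{\pi}, \eqn{\theta}).
#' @return Scalar: \eqn{\sum_i \log P(x_i \mid N_i, \pi, \theta)} (natural
#'   log).
#' @examples
#' m <- community_matrix(matrix(c(1, 1), 1), lineage = "N2")
#' dm_log_likelihood(m, pi = c(0.5, 0.5), theta = 0.5)  # log(0.25)
#' @export
dm_log_likelihood <- function(m, pi, theta, include_coef = TRUE) {
  x <- if (inherits(m, "community_matrix")) m$counts else as.matrix(m)
  k <- ncol(x)
  if (length(pi) != k) stop("length(pi) must equal the number of species")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("pi must lie on the simplex")
  if (theta <= 0 || theta >= 1) stop("theta must be strictly inside (0, 1)")
  if (k == 1L) return(0)
  gamma <- pi * (1 - theta) / theta
  .dm_loglik_gamma(x, gamma, include_coef = include_coef)
}

# log-likelihood in the concentration parameterization; lgamma throughout
# so totals ~ 1e5 stay stable
.dm_loglik_gamma <- function(x, gamma, include_coef = TRUE) {
  n_tot <- rowSums(x)
  gsum <- sum(gamma)
  ll <- sum(lgamma(gsum) - lgamma(gsum + n_tot)) +
    sum(lgamma(sweep(x, 2L, gamma, "+")) ) - nrow(x) * sum(lgamma(gamma))
  if (include_coef) {
    ll <- ll + sum(lgamma(n_tot + 1)) - sum(lgamma(x + 1))
  }
  ll
}

# score and Hessian in eta = log(gamma); returns list(grad, hess)
.dm_score_hess <- function(x, gamma) {
  n_tot <- rowSums(x)
  gsum <- sum(gamma)
  k <- length(gamma)
  a <- sum(digamma(gsum) - digamma(gsum + n_tot))
  d <- colSums(digamma(sweep(x, 2L, gamma, "+"))) - nrow(x) * digamma(gamma)
  grad_g <- a + d
  b <- sum(trigamma(gsum) - trigamma(gsum + n_tot))
  t_j <- colSums(trigamma(sweep(x, 2L, gamma, "+"))) - nrow(x) * trigamma(gamma)
  hess_g <- matrix(b, k, k)
  diag(hess_g) <- diag(hess_g) + t_j
  # chain rule to eta = log gamma
  grad <- gamma * grad_g
  hess <- (gamma %o% gamma) * hess_g
  diag(hess) <- diag(hess) + grad
  list(grad = grad, hess = hess)
}

# method-of-moments initializer: pi from mean proportions, theta from the
# average excess variance of per-host proportions
.dm_moment_init <- function(x) {
  props <- x / rowSums(x)
  p_bar <- colMeans(props)
  v <- apply(props, 2L, stats::var)
  nbar <- mean(rowSums(x))
  denom <- p_bar * (1 - p_bar)
  ok <- denom > 0 & v > 0
  theta0 <- if (any(ok)) {
    est <- (v[ok] / denom[ok] - 1 / nbar) / (1 - 1 / nbar)
    stats::median(est)
  } else 0.1
  theta0 <- min(max(theta0, 1e-4), 0.9)
  list(pi = p_bar, theta = theta0)
}

#' Fit the Dirichlet-multinomial neutral model by maximum likelihood
#'
#' Maximizes the [dm_log_likelihood()] over (\eqn{\pi}, \eqn{\theta}).
#' Optimization works in the unconstrained coordinates
#' \eqn{\eta_j = \log \gamma_j} (so no simplex or boundary constraints),
#' initialized by the method of moments and ascended by damped
#' Newton-Raphson with step-halving; the estimates are recovered as
#' \eqn{\pi = \gamma/\gamma_+}, \eqn{\theta = 1/(1+\gamma_+)}.
#' Species with zero counts in every host carry no information about their
#' concentration parameter (the likelihood is maximized at the boundary
#' \eqn{\gamma_j \to 0}); they are dropped with a warning and listed in
#' `dropped_species`.
#'
#' @param m A [community_matrix()].
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Iteration cap.
#' @return An object of class `dm_fit`: list with `pi` (named), `theta`,
#'   `gamma`, `loglik` (with multinomial coefficients), `se_theta`,
#'   `se_pi` (delta-method standard errors from the observed information),
#'   `n_hosts`, `converged`, `iterations`, `dropped_species`,
#'   `species_names`.
#' @export
fit_dmn <- function(m, tol = 1e-9, max_iter = 500L) {
  stopifnot(inherits(m, "community_matrix"))
  x <- m$counts[m$totals > 0, , drop = FALSE]
  if (nrow(x) < 2L) stop("insufficient samples: need >= 2 hosts with positive totals")
  zero_sp <- colSums(x) == 0
  dropped <- colnames(x)[zero_sp]
  if (length(dropped) > 0L) {
    warning("dropping all-zero species before fitting: ",
            paste(dropped, collapse = ", "))
    x <- x[, !zero_sp, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need >= 2 species with nonzero counts")
  x <- matrix(as.numeric(x), nrow(x), dimnames = dimnames(x))

  init <- .dm_moment_init(x)
  gamma <- init$pi * (1 - init$theta) / init$theta
  gamma <- pmax(gamma, 1e-8)
  eta <- log(gamma)
  ll <- .dm_loglik_gamma(x, gamma)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sh <- .dm_score_hess(x, exp(eta))
    # damp the Hessian until it is negative definite
    step <- NULL
    lambda <- 0
    for (try in 0:8) {
      h <- sh$hess
      if (lambda > 0) diag(h) <- diag(h) - lambda
      ch <- tryCatch(chol(-h), error = function(e) NULL)
      if (!is.null(ch)) {
        step <- backsolve(ch, forwardsolve(t(ch), sh$grad))
        break
      }
      lambda <- if (lambda == 0) max(abs(diag(sh$hess))) * 1e-6 else lambda * 10
    }
    if (is.null(step)) step <- sh$grad / max(abs(sh$grad))  # gradient fallback
    # step-halving line search on the log-likelihood
    ll_new <- -Inf
    for (half in 0:30) {
      eta_try <- eta + step / 2^half
      ll_try <- .dm_loglik_gamma(x, exp(eta_try))
      if (is.finite(ll_try) && ll_try >= ll) {
        eta <- eta_try
        ll_new <- ll_try
        break
      }
    }
    if (!is.finite(ll_new)) break  # no ascent direction left
    if (abs(ll_new - ll) <= tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  gamma <- exp(eta)
  gsum <- sum(gamma)
  pi_hat <- gamma / gsum
  theta_hat <- 1 / (1 + gsum)
  # delta-method SEs from the observed information in eta
  vcov_eta <- tryCatch(solve(-.dm_score_hess(x, gamma)$hess),
                       error = function(e) NULL)
  se_theta <- se_pi <- NA_real_
  if (!is.null(vcov_eta)) {
    dtheta <- -gamma / (1 + gsum)^2
    se_theta <- sqrt(max(drop(t(dtheta) %*% vcov_eta %*% dtheta), 0))
    jac_pi <- (diag(gamma) - (gamma %o% gamma) / gsum) / gsum  # d pi_j / d eta_k
    se_pi <- sqrt(pmax(diag(jac_pi %*% vcov_eta %*% t(jac_pi)), 0))
    names(se_pi) <- colnames(x)
  }
  names(pi_hat) <- names(gamma) <- colnames(x)
  structure(
    list(pi = pi_hat, theta = theta_hat, gamma = gamma, loglik = ll,
         se_theta = se_theta, se_pi = se_pi, n_hosts = nrow(x),
         converged = converged, iterations = iter,
         dropped_species = dropped, species_names = colnames(x)),
    class = "dm_fit"
  )
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf("Dirichlet-multinomial fit: %d hosts, %d species\n",
              x$n_hosts, length(x$pi)))
  cat(sprintf("theta = %.4f (se %.4f), logLik = %.6g, %s in %d iterations\n",
              x$theta, x$se_theta, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$pi, 4))
  if (length(x$dropped_species) > 0L) {
    cat("dropped all-zero species:", paste(x$dropped_species, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a structure-matched community data set
#'
#' Draws a synthetic count table from a fitted (or constructed)
#' Dirichlet-multinomial, replicating the structure of a real data set:
#' the same number of hosts and the same total count per host. For each
#' host, a composition is drawn from Dirichlet(\eqn{\gamma}) and counts
#' from a multinomial with the host's total.
#'
#' @param fit A `dm_fit` (from [fit_dmn()]), or any list with elements
#'   `pi` and `theta`.
#' @param totals Nonnegative integer vector of per-host totals, typically
#'   taken verbatim from the empirical table.
#' @param seed Optional integer; when given, the R generator is seeded so
#'   the same seed always yields the identical matrix. `NULL` continues
#'   the current RNG stream (used inside replicate loops).
#' @param lineage Lineage label stamped on the simulated hosts.
#' @return A [community_matrix()] whose row sums equal `totals` exactly.
#' @export
simulate_structure_matched <- function(fit, totals, seed = NULL,
                                       lineage = "simulated") {
  if (is.null(fit$gamma)) {
    fit$gamma <- fit$pi * (1 - fit$theta) / fit$theta
  }
  if (any(totals < 0) || any(totals != round(totals))) {
    stop("totals must be nonnegative integers")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- .r_dirichlet_multinomial(as.integer(round(totals)), fit$gamma)
  colnames(x) <- if (!is.null(names(fit$pi))) names(fit$pi) else
    paste0("sp_", seq_along(fit$pi))
  community_matrix(x, lineage = lineage)
}

# hosts x species draws; gamma on the concentration scale
.r_dirichlet_multinomial <- function(totals, gamma) {
  n <- length(totals)
  k <- length(gamma)
  g <- matrix(stats::rgamma(n * k, shape = rep(gamma, each = n)), n, k)
  # guard against all-zero gamma draws for tiny concentrations
  rs <- rowSums(g)
  bad <- rs == 0
  if (any(bad)) {
    g[bad, ] <- matrix(rep(gamma / sum(gamma), sum(bad)),
                       sum(bad), k, byrow = TRUE)
    rs[bad] <- 1
  }
  p <- g / rs
  x <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    if (totals[i] > 0L) x[i, ] <- stats::rmultinom(1L, totals[i], p[i, ])[, 1L]
  }
  x
}
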