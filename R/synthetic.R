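#' Specification for a synthetic community data set
#'
#' Describes everything needed to generate per-host count data with the
#' statistical structure the analysis assumes: a neutral
#' (Dirichlet-multinomial) community, or an interacting community drawn
#' from a logistic-normal-multinomial (latent Gaussian log-abundances with
#' an arbitrary covariance, softmaxed to a composition), plus a model for
#' per-host total community size.
#'
#' @param n_hosts Number of hosts to generate.
#' @param model `"neutral"` or `"interacting"`.
#' @param pi Simplex vector of expected relative abundances (neutral
#'   model).
#' @param theta Overdispersion in (0, 1) (neutral model).
#' @param mu Latent mean vector (interacting model); `softmax(mu)` is the
#'   composition at `sigma = 0`.
#' @param sigma Species covariance matrix, symmetric positive
#'   semi-definite (interacting model).
#' @param species_names Labels, defaulting to the 8 isolates of the
#'   C. elegans minimal community (MYb27 ... MYb238).
#' @param total_model Either a list
#'   `list(type = "lognormal", meanlog =, sdlog =, min =, max =)` for
#'   truncated log-normal totals, or `list(type = "fixed", totals = ...)`
#'   to use a vector verbatim.
#' @param lineage Lineage label stamped on generated hosts.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_hosts,
                           model = c("neutral", "interacting"),
                           pi = NULL, theta = NULL,
                           mu = NULL, sigma = NULL,
                           species_names = NULL,
                           total_model = list(type = "lognormal",
                                              meanlog = log(13000),
                                              sdlog = 0.75,
                                              min = 1680, max = 67200),
                           lineage = "synthetic",
                           seed = 1L) {
  model <- match.arg(model)
  if (model == "neutral") {
    if (is.null(pi) || is.null(theta)) stop("neutral model needs pi and theta")
    if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("pi must lie on the simplex")
    if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
    k <- length(pi)
  } else {
    if (is.null(mu) || is.null(sigma)) stop("interacting model needs mu and sigma")
    sigma <- as.matrix(sigma)
    if (!isSymmetric(sigma, tol = 1e-8)) stop("sigma must be symmetric")
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("sigma must be positive semi-definite")
    if (length(mu) != nrow(sigma)) stop("mu and sigma dimensions differ")
    k <- length(mu)
  }
  if (is.null(species_names)) {
    species_names <- if (k == 8L) {
      c("MYb27", "MYb45", "MYb53", "MYb56", "MYb71", "MYb120", "MYb181",
        "MYb238")
    } else paste0("sp_", seq_len(k))
  }
  if (length(species_names) != k) stop("species_names length must match")
  tm <- total_model
  if (identical(tm$type, "lognormal")) {
    if (tm$min <= 0 || tm$min > tm$max) stop("invalid total bounds")
  } else if (identical(tm$type, "fixed")) {
    if (any(tm$totals < 0)) stop("fixed totals must be nonnegative")
  } else stop("total_model$type must be 'lognormal' or 'fixed'")
  structure(
    list(n_hosts = as.integer(n_hosts), model = model, pi = pi,
         theta = theta, mu = mu, sigma = sigma,
         species_names = species_names, total_model = tm,
         lineage = lineage, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Representative lineage presets for the synthetic generator
#'
#' Neutral-model parameterizations representative of the eight-species
#' C. elegans gut communities the package targets: maximum-likelihood
#' Dirichlet-multinomial parameters for wild-type (N2) and two DAF-2/IGF
#' pathway mutant lineages, with per-host totals spanning roughly
#' 1,680-67,200 CFU (median near 10^4). The daf-2 preset carries 7
#' species: MYb181 is absent from that lineage's communities.
#'
#' @param lineage One of `"N2"`, `"daf-16"`, `"daf-2"`.
#' @param n_hosts Number of hosts (defaults to the lineage's empirical
#'   sample size: 164, 100, 98).
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
lineage_preset <- function(lineage = c("N2", "daf-16", "daf-2"),
                           n_hosts = NULL, seed = 1L) {
  lineage <- match.arg(lineage)
  sp <- c("MYb120", "MYb181", "MYb238", "MYb27", "MYb45", "MYb53",
          "MYb56", "MYb71")
  par <- switch(lineage,
    "N2" = list(pi = c(0.0096, 0.0015, 0.0384, 0.0866, 0.0290, 0.0828,
                       0.0903, 0.6619),
                theta = 0.1698, n = 164L, meanlog = log(13000)),
    "daf-16" = list(pi = c(0.0063, 0.0040, 0.0594, 0.2409, 0.0237, 0.0738,
                           0.0592, 0.5327),
                    theta = 0.1597, n = 100L, meanlog = log(20000)),
    "daf-2" = list(pi = c(0.0006, NA, 0.0616, 0.0440, 0.0133, 0.1099,
                          0.0719, 0.6986),
                   theta = 0.2524, n = 98L, meanlog = log(3000))
  )
  keep <- !is.na(par$pi)
  pi <- par$pi[keep] / sum(par$pi[keep])
  synthetic_spec(
    n_hosts = if (is.null(n_hosts)) par$n else n_hosts,
    model = "neutral", pi = pi, theta = par$theta,
    species_names = sp[keep],
    total_model = list(type = "lognormal", meanlog = par$meanlog,
                       sdlog = 0.75, min = 1680, max = 67200),
    lineage = lineage, seed = seed
  )
}

#' Generate per-host total community sizes
#'
#' Fixed totals are returned verbatim; log-normal totals are drawn and
#' redrawn until inside `[min, max]` (truncation by rejection), then
#' rounded to integers.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional override of `spec$seed`; `NULL` inside a
#'   generation pipeline continues the current RNG stream.
#' @return Integer vector of length `n_hosts`.
#' @export
generate_totals <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tm <- spec$total_model
  if (identical(tm$type, "fixed")) {
    tot <- rep_len(as.integer(round(tm$totals)), spec$n_hosts)
    return(tot)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_hosts
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(2L * (n - length(out)) + 8L,
                          meanlog = tm$meanlog, sdlog = tm$sdlog)
    out <- c(out, draw[draw >= tm$min & draw <= tm$max])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Generate a neutral (Dirichlet-multinomial) community data set
#'
#' Per host: composition ~ Dirichlet(\eqn{\pi (1-\theta)/\theta}), counts
#' ~ Multinomial(total, composition). Row sums equal the generated totals
#' exactly.
#'
#' @inheritParams generate_totals
#' @return A [community_matrix()].
#' @export
generate_neutral <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$model != "neutral") stop("spec$model must be 'neutral'")
  if (!is.null(seed)) set.seed(seed)
  totals <- generate_totals(spec, seed = NULL)
  gamma <- spec$pi * (1 - spec$theta) / spec$theta
  x <- .r_dirichlet_multinomial(totals, gamma)
  colnames(x) <- spec$species_names
  community_matrix(x, lineage = spec$lineage)
}

#' Generate an interacting community data set
#'
#' The logistic-normal-multinomial alternative the neutral test is meant
#' to detect: per host, latent log-abundances
#' \eqn{z \sim N(\mu, \Sigma)}, composition = softmax(z), counts ~
#' Multinomial(total, composition). Off-diagonal structure in
#' \eqn{\Sigma} induces true interspecies correlations; \eqn{\Sigma = 0}
#' collapses to a fixed composition softmax(\eqn{\mu}).
#'
#' @inheritParams generate_totals
#' @return A [community_matrix()].
#' @export
generate_interacting <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$model != "interacting") stop("spec$model must be 'interacting'")
  if (!is.null(seed)) set.seed(seed)
  totals <- generate_totals(spec, seed = NULL)
  n <- spec$n_hosts
  k <- length(spec$mu)
  z <- if (all(spec$sigma == 0)) {
    matrix(spec$mu, n, k, byrow = TRUE)
  } else {
    matrix(MASS::mvrnorm(n, mu = spec$mu, Sigma = spec$sigma), n, k)
  }
  ez <- exp(z - apply(z, 1L, max))
  p <- ez / rowSums(ez)
  x <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    if (totals[i] > 0L) x[i, ] <- stats::rmultinom(1L, totals[i], p[i, ])[, 1L]
  }
  colnames(x) <- spec$species_names
  community_matrix(x, lineage = spec$lineage)
}

#' Generate a community data set from a spec
#'
#' Dispatches to [generate_neutral()] or [generate_interacting()].
#'
#' @inheritParams generate_totals
#' @return A [community_matrix()].
#' @export
generate_community <- function(spec, seed = spec$seed) {
  if (spec$model == "neutral") generate_neutral(spec, seed)
  else generate_interacting(spec, seed)
}
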