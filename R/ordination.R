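#' Log-transform and standardize a count table
#'
#' The pre-ordination transform: counts to \eqn{\ln(x + 1)} (the
#' pseudo-count accommodates zeros; the log base only rescales), then each
#' species column centered to mean 0 and scaled to unit variance.
#' Constant columns cannot be scaled and are set to 0 with a warning.
#'
#' @param m A [community_matrix()] or nonnegative numeric matrix.
#' @param standardize One of `"zscore"` (default), `"total"` (rows summed
#'   to 1 after the log), `"hellinger"` (square root of row proportions,
#'   applied to raw counts), or `"none"` (log only).
#' @return Numeric hosts-by-species matrix.
#' @export
log_standardize <- function(m, standardize = c("zscore", "total",
                                               "hellinger", "none")) {
  standardize <- match.arg(standardize)
  x <- if (inherits(m, "community_matrix")) m$counts else as.matrix(m)
  if (any(x < 0)) stop("counts must be nonnegative")
  if (standardize == "hellinger") {
    rs <- rowSums(x)
    rs[rs == 0] <- 1
    return(sqrt(x / rs))
  }
  lx <- log(x + 1)
  switch(standardize,
    none = lx,
    total = {
      rs <- rowSums(lx)
      rs[rs == 0] <- 1
      lx / rs
    },
    zscore = {
      sds <- apply(lx, 2L, stats::sd)
      const <- sds == 0
      if (any(const)) {
        warning("constant species column(s) set to 0: ",
                paste(colnames(lx)[const], collapse = ", "))
        sds[const] <- 1
      }
      out <- scale(lx, center = TRUE, scale = sds)
      out[, const] <- 0
      attr(out, "scaled:center") <- NULL
      attr(out, "scaled:scale") <- NULL
      out
    }
  )
}

#' Principal-component analysis of a transformed community table
#'
#' Centered eigendecomposition of the covariance of the (already
#' transformed) hosts-by-species matrix. Component signs are fixed so that
#' each component's largest-magnitude species loading is positive, making
#' scores reproducible across platforms.
#'
#' @param x Numeric hosts-by-species matrix (e.g. from
#'   [log_standardize()]).
#' @param n_components Number of components to return; truncated to the
#'   matrix rank with a warning if larger.
#' @return Object of class `ordination_result`: `scores` (hosts x
#'   components), `loadings` (species x components), `variance_fraction`
#'   (over all components, summing to 1; the first `n_components` are
#'   returned alongside `variance_fraction_all`).
#' @export
pca_ordination <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 hosts and >= 2 species")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components = %d exceeds rank %d; truncating",
                    n_components, rank))
    n_components <- rank
  }
  keep <- seq_len(n_components)
  rot <- pc$rotation[, keep, drop = FALSE]
  sco <- pc$x[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in keep) {
    mx <- which.max(abs(rot[, j]))
    if (rot[mx, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  frac <- ev / sum(ev)
  structure(
    list(scores = sco, loadings = rot,
         variance_fraction = frac[keep],
         variance_fraction_all = frac),
    class = "ordination_result"
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u, v) = \sum_j |u_j - v_j| / \sum_j (u_j + v_j)} between
#' nonnegative abundance rows — conventionally applied here to
#' \eqn{\ln(\mathrm{count}+1)} values (see [log_standardize()] with
#' `standardize = "none"`), not to z-scored values, which can be negative.
#' A pair of all-zero rows has no defined numerator or denominator; its
#' distance is set to 0 with a warning.
#'
#' @param x Nonnegative hosts-by-species matrix, or a
#'   [community_matrix()] (raw counts).
#' @return A `dist` object with host labels.
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "community_matrix")) x <- x$counts
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires nonnegative entries")
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (anyNA(d)) {
    warning("all-zero row pair(s): distance set to 0")
    d[is.na(d)] <- 0
  }
  d
}

.check_groups <- function(d, groups) {
  n <- attr(d, "Size")
  if (is.null(n)) n <- nrow(as.matrix(d))
  if (length(groups) != n) stop("one group label per host required")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 members")
  groups
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities:
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with M the number of host
#' pairs; the p-value is the fraction of label permutations (observed
#' configuration included) attaining \eqn{R_{perm} \ge R_{obs}}.
#'
#' @param d A `dist` of dissimilarities (e.g. [bray_curtis()]).
#' @param groups Group (lineage) label per host.
#' @param n_perm Number of permutations (conventionally 9,999).
#' @param seed Integer seed for the permutation stream.
#' @return List with `R`, `p`, `n_perm`, `seed`.
#' @export
anosim_test <- function(d, groups, n_perm = 9999L, seed = 1L) {
  groups <- .check_groups(d, groups)
  set.seed(seed)
  a <- vegan::anosim(d, groups, permutations = n_perm)
  list(R = unname(a$statistic), p = a$signif, n_perm = n_perm, seed = seed)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor pseudo-F from the distance-based sum-of-squares
#' decomposition (Gower-centered), F = (SS_between/df_between) /
#' (SS_within/df_within), with a permutation p-value computed as
#' (number of permuted F >= observed F + 1)/(n_perm + 1) — so the smallest
#' attainable p at 999 permutations is 0.001.
#'
#' @inheritParams anosim_test
#' @param n_perm Number of permutations (conventionally 999).
#' @return List with `F`, `p`, `R2`, `df_between`, `df_within`, `n_perm`,
#'   `seed`.
#' @export
permanova_test <- function(d, groups, n_perm = 999L, seed = 1L) {
  groups <- .check_groups(d, groups)
  set.seed(seed)
  tab <- vegan::adonis2(d ~ g, data = data.frame(g = groups),
                        permutations = n_perm)
  list(F = tab$F[1L], p = tab$`Pr(>F)`[1L], R2 = tab$R2[1L],
       df_between = tab$Df[1L], df_within = tab$Df[2L],
       n_perm = n_perm, seed = seed)
}
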