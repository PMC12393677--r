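# Multivariate association machinery: RV coefficient with permutation test,
# distance-based PERMANOVA, DiSTATIS compromise analysis, and variable
# correlation circles.

#' RV coefficient between two sample-aligned tables
#'
#' A multivariate generalization of the squared Pearson correlation:
#' \deqn{RV = \mathrm{tr}(XX'YY') / \sqrt{\mathrm{tr}((XX')^2)\,\mathrm{tr}((YY')^2)}}
#' computed on column-centered matrices.
#'
#' @param x,y Numeric matrices with the same samples in the same row order.
#' @return Scalar in `[0, 1]`.
#' @export
rv_coefficient <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("tables must share samples")
  if (nrow(x) < 3L) stop("fewer than 3 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  a <- tcrossprod(xc); b <- tcrossprod(yc)
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Permutation test for the RV coefficient
#'
#' Rows of `y` are permuted; the p-value uses the add-one estimator
#' p = (1 + #\{RV_perm >= RV_obs\}) / (1 + n_perm) so it is never zero.
#'
#' @param x,y Numeric matrices with shared samples.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for reproducibility.
#' @return List with `rv`, `p_value`, `n_permutations`, `permuted` (the null
#'   RV values), `seed`.
#' @export
rv_permutation_test <- function(x, y, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("tables must share samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  a <- tcrossprod(xc); b <- tcrossprod(yc)
  den <- sqrt(sum(a * a) * sum(b * b))
  rv_obs <- sum(a * b) / den
  n <- nrow(a)
  # permuting rows of Y permutes B symmetrically; denominators are invariant
  perm_rv <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      sum(a[p, p] * b) / den
    }, numeric(1))
  })
  list(rv = rv_obs, p_value = (1 + sum(perm_rv >= rv_obs)) / (1 + n_perm),
       n_permutations = n_perm, permuted = perm_rv, seed = seed)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance of a grouping factor,
#' delegated to [vegan::adonis2()] (pseudo-F from among/within sums of
#' squares on the Gower-centered distance matrix; p-value by label
#' permutation).
#'
#' @param d A `dist` object or square symmetric distance matrix.
#' @param grouping Factor with >= 2 levels, no singleton groups.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `f_statistic`, `r_squared`, `p_value`, `table`.
#' @export
permanova <- function(d, grouping, n_perm = 999L, seed = NULL) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
      stop("distance matrix must be square and symmetric")
    }
    d <- stats::as.dist(d)
  }
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop("grouping needs >= 2 levels")
  if (any(table(grouping) < 2L)) stop("singleton group")
  df <- data.frame(g = grouping)
  tab <- with_seed(seed, vegan::adonis2(d ~ g, data = df, permutations = n_perm))
  list(f_statistic = tab$F[1], r_squared = tab$R2[1],
       p_value = tab$`Pr(>F)`[1], table = tab)
}

# Double-center a dissimilarity matrix into a cross-product matrix:
# S = -1/2 J M J with J = I - 11'/n, where M is the squared dissimilarity
# matrix (mode "squared", for metric inputs) or the dissimilarity itself
# (mode "direct", appropriate for semimetrics such as Bray-Curtis).
double_center <- function(d, mode = c("squared", "direct")) {
  mode <- match.arg(mode)
  d <- as.matrix(d)
  n <- nrow(d)
  m <- if (mode == "squared") d^2 else d
  j <- diag(n) - matrix(1 / n, n, n)
  -0.5 * j %*% m %*% j
}

#' DiSTATIS compromise analysis of several distance matrices
#'
#' Each dissimilarity matrix is double-centered into a cross-product matrix
#' and normalized by its first eigenvalue; the inter-table congruence matrix
#' of RV coefficients gives table weights (first eigenvector, rescaled
#' nonnegative and summing to 1); the compromise is the weighted sum, and
#' its eigendecomposition yields sample factor scores. Negative compromise
#' eigenvalues (possible for semimetric inputs) are truncated at zero for
#' the scores.
#'
#' @param distances Named list of `dist` objects or square matrices over the
#'   same samples.
#' @param n_dims Number of factor-score dimensions to return.
#' @param mode `"squared"` (default, metric inputs) or `"direct"`
#'   (Bray-Curtis-type semimetrics).
#' @param normalize `"first_eigenvalue"` (MFA-style, default) or `"trace"`.
#' @return List with per-table cross-products, `congruence`, `weights`,
#'   `compromise`, `eigenvalues`, and `scores` (samples x n_dims).
#' @export
distatis <- function(distances, n_dims = 4L,
                     mode = c("squared", "direct"),
                     normalize = c("first_eigenvalue", "trace")) {
  mode <- match.arg(mode); normalize <- match.arg(normalize)
  mats <- lapply(distances, function(d) as.matrix(d))
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1L || any(vapply(mats, ncol, integer(1)) != n)) {
    stop("all matrices must be square over the same samples")
  }
  for (m in mats) if (max(abs(m - t(m))) > 1e-8) stop("non-symmetric input")
  s_list <- lapply(mats, function(d) {
    s <- double_center(d, mode)
    sc <- if (normalize == "first_eigenvalue") {
      eigen(s, symmetric = TRUE, only.values = TRUE)$values[1]
    } else sum(diag(s))
    if (sc <= 0) stop("degenerate table: nonpositive normalization constant")
    s / sc
  })
  k <- length(s_list)
  congruence <- diag(1, k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      congruence[i, j] <- congruence[j, i] <-
        sum(s_list[[i]] * s_list[[j]]) /
          sqrt(sum(s_list[[i]]^2) * sum(s_list[[j]]^2))
    }
  }
  dimnames(congruence) <- list(names(mats), names(mats))
  ev1 <- eigen(congruence, symmetric = TRUE)$vectors[, 1]
  if (sum(ev1) < 0) ev1 <- -ev1
  if (any(ev1 < -1e-8)) stop("negative table weights: degenerate congruence")
  weights <- pmax(ev1, 0); weights <- weights / sum(weights)
  names(weights) <- names(mats)
  compromise <- Reduce(`+`, Map(`*`, s_list, weights))
  eg <- eigen(compromise, symmetric = TRUE)
  lam <- eg$values
  n_dims <- min(n_dims, n)
  scores <- eg$vectors[, seq_len(n_dims), drop = FALSE] %*%
    diag(sqrt(pmax(lam[seq_len(n_dims)], 0)), n_dims)
  rownames(scores) <- rownames(mats[[1]])
  colnames(scores) <- paste0("dim", seq_len(n_dims))
  list(cross_products = s_list, congruence = congruence, weights = weights,
       compromise = compromise, eigenvalues = lam, scores = scores,
       mode = mode, normalize = normalize)
}

#' Correlations of original variables with latent factor scores
#'
#' @param variables Samples x variables table (rows aligned with `scores`).
#' @param scores Samples x dimensions factor scores.
#' @param dims Which dimensions to correlate with (default all).
#' @return Variables x dimensions matrix of Pearson correlations in
#'   `[-1, 1]`; constant variables yield `NA` with a warning.
#' @export
correlation_circle <- function(variables, scores, dims = seq_len(ncol(scores))) {
  variables <- as.matrix(variables)
  scores <- as.matrix(scores)[, dims, drop = FALSE]
  if (nrow(variables) != nrow(scores)) stop("rows must align")
  sds <- apply(variables, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant variable(s): correlations reported as NA")
  }
  out <- suppressWarnings(stats::cor(variables, scores))
  out[sds == 0, ] <- NA_real_
  out
}
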