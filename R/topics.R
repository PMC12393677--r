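# Constrained microbiome topic model: latent Dirichlet allocation fitted to
# the non-Lactobacillus species counts, pure Lactobacillus topics defined by
# a dominance rule, and rescaling of the non-Lactobacillus topic proportions
# to the whole community.
#
# Notation: for sample i, pi_hat[k, i-th row] are the topic proportions
# within the non-Lactobacillus fraction (rows sum to 1), Pi_hat[i] is the
# total non-Lactobacillus proportion of the sample, and the whole-community
# topic proportions are p_hat = pi_hat * Pi_hat.

#' Define pure Lactobacillus topics by the dominance rule
#'
#' A *Lactobacillus* species gets its own pure topic when its relative
#' abundance reaches the dominance threshold (50%) in at least `min_samples`
#' samples (both thresholds inclusive). All remaining *Lactobacillus*
#' species are pooled into a single "Other L." topic whose composition is
#' their mean relative abundance across the cohort (renormalized).
#'
#' @param proportions Samples x species proportion matrix.
#' @param taxonomy Data frame as from [make_taxonomy()].
#' @param dominance_threshold Relative-abundance threshold (default 0.5).
#' @param min_samples Minimum qualifying samples (default 10).
#' @return List with `pure` (character vector of species with their own
#'   topic), `other_composition` (probability vector over the pooled
#'   species; NULL if none), and `proportions` (samples x lacto-topics
#'   matrix of per-sample topic proportions: the species proportions, pooled
#'   for "Other L.").
#' @export
define_lactobacillus_topics <- function(proportions, taxonomy,
                                        dominance_threshold = 0.5,
                                        min_samples = 10L) {
  proportions <- as.matrix(proportions)
  lacto_sp <- taxonomy$species[taxonomy$is_lacto]
  lacto_sp <- intersect(colnames(proportions), lacto_sp)
  if (!length(lacto_sp)) stop("no Lactobacillus species in taxonomy")
  lp <- proportions[, lacto_sp, drop = FALSE]
  qualifies <- colSums(lp >= dominance_threshold) >= min_samples
  pure <- lacto_sp[qualifies]
  pooled <- lacto_sp[!qualifies]
  other_comp <- NULL
  if (length(pooled)) {
    avg <- colMeans(lp[, pooled, drop = FALSE])
    other_comp <- if (sum(avg) > 0) avg / sum(avg) else
      stats::setNames(rep(1 / length(pooled), length(pooled)), pooled)
  }
  topic_props <- lp[, pure, drop = FALSE]
  if (length(pooled)) {
    topic_props <- cbind(topic_props, `Other L.` = rowSums(lp[, pooled, drop = FALSE]))
  }
  list(pure = pure, other_composition = other_comp, proportions = topic_props)
}

# Expected exp(E[log Dirichlet]) rows from a matrix of variational
# parameters: exp(digamma(x) - digamma(rowSums(x))).
exp_elog <- function(x) exp(digamma(x) - digamma(rowSums(x)))

# Variational bound for LDA (up to constants in the data), used to monitor
# convergence; non-decreasing over full coordinate-ascent sweeps.
lda_bound <- function(x, gamma, lambda, alpha, eta) {
  el_theta <- digamma(gamma) - digamma(rowSums(gamma))
  el_beta <- digamma(lambda) - digamma(rowSums(lambda))
  phinorm <- exp(el_theta) %*% exp(el_beta)
  score <- sum(x * log(phinorm + 1e-300))
  # E[log p(theta | alpha)] - E[log q(theta | gamma)]
  score <- score + sum((alpha - gamma) * el_theta) +
    sum(lgamma(gamma)) - sum(lgamma(rowSums(gamma))) +
    nrow(gamma) * (lgamma(ncol(gamma) * alpha) - ncol(gamma) * lgamma(alpha))
  # E[log p(beta | eta)] - E[log q(beta | lambda)]
  score <- score + sum((eta - lambda) * el_beta) +
    sum(lgamma(lambda)) - sum(lgamma(rowSums(lambda))) +
    nrow(lambda) * (lgamma(ncol(lambda) * eta) - ncol(lambda) * lgamma(eta))
  score
}

#' Fit LDA to non-Lactobacillus counts by variational Bayes
#'
#' Batch variational inference with symmetric Dirichlet priors: document
#' (sample) topic proportions theta ~ Dir(alpha), topics beta ~ Dir(eta).
#' The E step iterates the mean-field updates for the per-sample variational
#' Dirichlet parameters gamma; the M step updates the per-topic parameters
#' lambda from the expected sufficient statistics. The variational bound is
#' tracked and non-decreasing over sweeps.
#'
#' Samples with zero total count are excluded from the fit (their topic
#' proportions are undefined); K = 1 has the closed-form solution where the
#' single topic is the prior-smoothed pooled species distribution.
#'
#' @param counts Samples x species count matrix restricted to
#'   non-*Lactobacillus* species.
#' @param K Number of topics (must not exceed the number of species).
#' @param alpha,eta Symmetric Dirichlet hyperparameters; defaults 1/K and
#'   0.1.
#' @param seed Integer seed for the topic initialization.
#' @param n_starts Number of random restarts; the fit with the best
#'   variational bound is kept (restart seeds derive from `seed`).
#' @param max_iter,tol Convergence controls (relative bound change).
#' @return List with `beta` (K x V, rows sum to 1), `pi_hat` (samples x K,
#'   rows sum to 1; `NA` rows for excluded samples), `bound` (trace),
#'   `K`, `alpha`, `eta`, `seed`, `fitted_samples`.
#' @export
fit_nonlacto_lda <- function(counts, K, alpha = 1 / K, eta = 0.1, seed = 1L,
                             n_starts = 4L, max_iter = 500L, tol = 1e-6) {
  if (n_starts > 1L) {
    fits <- lapply(seq_len(n_starts), function(s) {
      fit_nonlacto_lda(counts, K, alpha = alpha, eta = eta,
                       seed = child_seed(seed, 1000L + s), n_starts = 1L,
                       max_iter = max_iter, tol = tol)
    })
    bounds <- vapply(fits, function(f) {
      if (length(f$bound)) utils::tail(f$bound, 1) else 0
    }, numeric(1))
    best <- fits[[which.max(bounds)]]
    best$seed <- seed
    best$restart_bounds <- bounds
    return(best)
  }
  x_all <- as.matrix(counts)
  if (K > ncol(x_all)) stop("K exceeds the number of non-Lactobacillus species")
  fitted <- rowSums(x_all) > 0
  x <- x_all[fitted, , drop = FALSE]
  d <- nrow(x); v <- ncol(x)
  pi_hat_all <- matrix(NA_real_, nrow(x_all), K,
                       dimnames = list(rownames(x_all), paste0("topic", seq_len(K))))
  if (K == 1L) {
    lam <- eta + colSums(x)
    beta <- matrix(lam / sum(lam), 1, v, dimnames = list("topic1", colnames(x)))
    pi_hat_all[fitted, 1] <- 1
    return(list(beta = beta, pi_hat = pi_hat_all, bound = numeric(0),
                K = 1L, alpha = alpha, eta = eta, seed = seed,
                fitted_samples = rownames(x_all)[fitted]))
  }
  lambda <- with_seed(seed, matrix(stats::rgamma(K * v, 100, 100), K, v)) + eta
  gamma <- matrix(1, d, K)
  bound <- numeric(0)
  for (it in seq_len(max_iter)) {
    e_beta <- exp_elog(lambda)
    # E step: mean-field updates for gamma until stable
    for (inner in seq_len(200L)) {
      e_theta <- exp_elog(gamma)
      phinorm <- e_theta %*% e_beta + 1e-100
      gamma_new <- alpha + e_theta * ((x / phinorm) %*% t(e_beta))
      delta <- mean(abs(gamma_new - gamma))
      gamma <- gamma_new
      if (delta < 1e-3) break
    }
    e_theta <- exp_elog(gamma)
    phinorm <- e_theta %*% e_beta + 1e-100
    # M step
    lambda <- eta + e_beta * (t(e_theta) %*% (x / phinorm))
    b <- lda_bound(x, gamma, lambda, alpha, eta)
    bound <- c(bound, b)
    if (it > 1L) {
      rel <- abs(b - bound[it - 1L]) / (abs(bound[it - 1L]) + 1e-12)
      if (rel < tol) break
    }
  }
  beta <- lambda / rowSums(lambda)
  dimnames(beta) <- list(paste0("topic", seq_len(K)), colnames(x))
  pi_hat <- gamma / rowSums(gamma)
  pi_hat_all[fitted, ] <- pi_hat
  list(beta = beta, pi_hat = pi_hat_all, bound = bound, K = K,
       alpha = alpha, eta = eta, seed = seed,
       fitted_samples = rownames(x_all)[fitted])
}

#' Rescale non-Lactobacillus topic proportions to the whole community
#'
#' p_hat[i, k] = pi_hat[i, k] * Pi_hat[i], where Pi_hat[i] is the total
#' non-*Lactobacillus* proportion of sample i. Samples with Pi_hat = 0
#' (fully *Lactobacillus*) get all-zero rows.
#'
#' @param pi_hat Samples x K matrix, rows summing to 1 (or `NA` rows for
#'   samples with no non-*Lactobacillus* counts).
#' @param Pi_hat Numeric vector of total non-*Lactobacillus* proportions in
#'   `[0, 1]`, one per sample.
#' @return Samples x K matrix with `rowSums(p_hat) == Pi_hat`.
#' @export
scale_topic_proportions <- function(pi_hat, Pi_hat) {
  pi_hat <- as.matrix(pi_hat)
  if (nrow(pi_hat) != length(Pi_hat)) stop("shape mismatch")
  if (any(Pi_hat < -1e-12 | Pi_hat > 1 + 1e-12)) stop("Pi_hat outside [0, 1]")
  p_hat <- pi_hat * Pi_hat
  p_hat[Pi_hat == 0, ] <- 0
  p_hat[is.na(p_hat)] <- 0
  p_hat
}

#' Fit the full constrained topic model
#'
#' Splits the count table into *Lactobacillus* and non-*Lactobacillus*
#' species, defines the pure *Lactobacillus* topics, fits the LDA on the
#' non-*Lactobacillus* counts, and rescales to whole-community proportions.
#' Every sample's *Lactobacillus* topic proportions plus rescaled
#' non-*Lactobacillus* topic proportions sum to 1.
#'
#' @param counts Samples x species count matrix (all species).
#' @param taxonomy Data frame as from [make_taxonomy()].
#' @param K Number of non-*Lactobacillus* topics.
#' @param ... Passed to [fit_nonlacto_lda()].
#' @return List with the LDA fit (`beta`, `pi_hat`), `Pi_hat`, `p_hat`,
#'   `lacto` (from [define_lactobacillus_topics()]), and `topic_proportions`
#'   (samples x all-topics matrix, rows sum to 1).
#' @export
fit_topic_model <- function(counts, taxonomy, K, ...) {
  counts <- as.matrix(counts)
  prop <- relative_abundance(counts)
  is_lacto <- taxonomy$is_lacto[match(colnames(counts), taxonomy$species)]
  if (anyNA(is_lacto)) stop("taxonomy missing species present in counts")
  lacto <- define_lactobacillus_topics(prop, taxonomy)
  nl_counts <- counts[, !is_lacto, drop = FALSE]
  Pi_hat <- rowSums(prop[, !is_lacto, drop = FALSE])
  fit <- fit_nonlacto_lda(nl_counts, K, ...)
  p_hat <- scale_topic_proportions(fit$pi_hat, Pi_hat)
  all_props <- cbind(lacto$proportions, p_hat)
  list(beta = fit$beta, pi_hat = fit$pi_hat, Pi_hat = Pi_hat, p_hat = p_hat,
       lacto = lacto, topic_proportions = all_props, K = K, fit = fit)
}
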