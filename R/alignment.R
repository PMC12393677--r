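# Topic alignment across resolutions: pairing topics between models fitted
# with consecutive K, building paths of matched topics, scoring topic
# coherence, and selecting K where the path count plateaus.
#
# Alignment weights between two models use the product scheme: the weight of
# a topic pair is proportional to the sample-summed product of their topic
# proportions (normalized to sum 1 over all pairs). Path construction and
# coherence additionally use the cosine similarity between topic-proportion
# vectors across samples, which distinguishes duplicated topics (shared
# sample support, cosine near 1) from genuine splits of an under-resolved
# topic (partitioned sample support, cosine well below 1).

# Product-scheme alignment weights between two pi_hat matrices on the same
# samples; returned matrix sums to 1.
alignment_weights <- function(pi_a, pi_b) {
  w <- crossprod(pi_a, pi_b)   # K_a x K_b, entries sum_i p_ki q_li
  w / sum(w)
}

cosine_matrix <- function(pi_a, pi_b) {
  na <- sqrt(colSums(pi_a^2)); nb <- sqrt(colSums(pi_b^2))
  crossprod(pi_a, pi_b) / outer(na, nb)
}

# Greedy maximum-weight one-to-one matching: repeatedly take the largest
# remaining weight. Returns a data frame of matched (row, col) pairs.
greedy_matching <- function(w) {
  w <- as.matrix(w)
  pairs <- data.frame(row = integer(), col = integer(), weight = numeric())
  repeat {
    if (!nrow(w) || !ncol(w) || all(!is.finite(w))) break
    idx <- which(w == max(w), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(row = as.integer(rownames(w)[idx[1]]),
                                     col = as.integer(colnames(w)[idx[2]]),
                                     weight = w[idx[1], idx[2]]))
    w <- w[-idx[1], -idx[2], drop = FALSE]
    if (!nrow(w) || !ncol(w)) break
  }
  pairs
}

#' Align topic models fitted across a grid of resolutions
#'
#' Topics of models at consecutive K are paired by greedy maximum-weight
#' matching of the product-scheme alignment weights. Matched topics continue
#' their partner's path; an unmatched topic at the finer resolution joins
#' its best partner's path when its sample-support cosine similarity to the
#' path's continuing topic is at least `attach_threshold` (a duplicate),
#' and starts a new path otherwise (a genuine new subcommunity). The
#' coherence of a topic is its one-step persistence: the best cosine
#' similarity between its sample-proportion vector and any topic of the
#' next, finer resolution (backward, to the coarser resolution, for topics
#' of the finest model). A robust subcommunity reappears nearly unchanged
#' at the next resolution; spurious topics (transient blends, split noise)
#' do not.
#'
#' @param models List of fits from [fit_nonlacto_lda()] (or any list with
#'   elements `pi_hat` and `K`), ordered by increasing K, all fitted on the
#'   same samples.
#' @param attach_threshold Cosine similarity above which an unmatched topic
#'   is treated as a duplicate and attached to an existing path.
#' @param link_floor Minimum cosine similarity for a greedy match to count
#'   as a path continuation; weaker pairings leave the child unmatched.
#' @return List of class `topic_alignment` with per-resolution `topics`
#'   (data frame: resolution K, topic index, path ID, coherence), `weights`
#'   (list of consecutive-pair weight matrices), `n_paths` (named vector:
#'   for each resolution below the finest, the number of live paths — topics
#'   claimed as best parent by at least one topic of the next resolution;
#'   for the finest resolution, the number of distinct paths among its
#'   topics), and `K_grid`.
#' @export
align_topics <- function(models, attach_threshold = 0.85, link_floor = 0.3) {
  if (length(models) < 2L) stop("need at least two fitted models")
  ks <- vapply(models, function(m) m$K, numeric(1))
  if (is.unsorted(ks, strictly = TRUE)) stop("models must be ordered by increasing K")
  pis <- lapply(models, function(m) {
    p <- as.matrix(m$pi_hat)
    p[stats::complete.cases(p), , drop = FALSE]
  })
  ns <- vapply(pis, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("models fitted on different sample sets")
  r <- length(models)
  weights <- vector("list", r - 1L)
  cosines <- vector("list", r - 1L)
  # path id per topic per resolution
  path_of <- vector("list", r)
  path_of[[1]] <- seq_len(ks[1])
  n_paths_total <- ks[1]
  # edge similarity of each topic to its path predecessor (NA for path roots)
  link_sim <- vector("list", r)
  link_sim[[1]] <- rep(NA_real_, ks[1])
  for (j in seq_len(r - 1L)) {
    w <- alignment_weights(pis[[j]], pis[[j + 1L]])
    cs <- cosine_matrix(pis[[j]], pis[[j + 1L]])
    dimnames(w) <- dimnames(cs) <- list(seq_len(ks[j]), seq_len(ks[j + 1L]))
    weights[[j]] <- w; cosines[[j]] <- cs
    matched <- greedy_matching(w)
    paths_next <- integer(ks[j + 1L])
    sims_next <- rep(NA_real_, ks[j + 1L])
    for (i in seq_len(nrow(matched))) {
      parent <- matched$row[i]; child <- matched$col[i]
      if (cs[parent, child] < link_floor) next   # too dissimilar to continue
      paths_next[child] <- path_of[[j]][parent]
      sims_next[child] <- cs[parent, child]
    }
    leftover <- which(paths_next == 0L)
    for (child in leftover) {
      parent <- which.max(w[, child])
      sim <- cs[parent, child]
      if (is.finite(sim) && sim >= attach_threshold) {
        paths_next[child] <- path_of[[j]][parent]
        sims_next[child] <- sim
      } else {
        n_paths_total <- n_paths_total + 1L
        paths_next[child] <- n_paths_total
        sims_next[child] <- sim   # recorded, but starts a new path
      }
    }
    path_of[[j + 1L]] <- paths_next
    link_sim[[j + 1L]] <- sims_next
  }
  # coherence: one-step persistence similarity; redundancy: similarity of a
  # topic's species profile to another topic of the same model (a split or
  # duplicated topic shadows a sibling; genuinely distinct subcommunities
  # have well-separated profiles)
  topics <- do.call(rbind, lapply(seq_len(r), function(j) {
    coh <- if (j < r) {
      apply(cosines[[j]], 1, max)      # best forward match
    } else {
      apply(cosines[[r - 1L]], 2, max) # finest resolution: backward
    }
    red <- rep(NA_real_, ks[j])
    beta <- models[[j]]$beta
    if (!is.null(beta) && ks[j] > 1L) {
      bn <- beta / sqrt(rowSums(beta^2))
      bc <- tcrossprod(bn)
      diag(bc) <- 0
      red <- apply(bc, 1, max)
    }
    data.frame(K = ks[j], topic = seq_len(ks[j]), path = path_of[[j]],
               coherence = as.numeric(coh), redundancy = as.numeric(red))
  }))
  # live paths per resolution: topics claimed as best parent (by alignment
  # weight) by at least one topic of the next, finer resolution
  n_paths <- integer(r)
  for (j in seq_len(r - 1L)) {
    claimed <- unique(apply(weights[[j]], 2, which.max))
    n_paths[j] <- length(unique(path_of[[j]][claimed]))
  }
  n_paths[r] <- length(unique(path_of[[r]]))
  names(n_paths) <- ks
  structure(list(topics = topics, weights = weights, cosines = cosines,
                 n_paths = n_paths, K_grid = ks,
                 attach_threshold = attach_threshold, link_floor = link_floor),
            class = "topic_alignment")
}

#' Select the number of topics from an alignment
#'
#' A topic is flagged spurious when it is transient (coherence below
#' `coherence_floor`: it does not reappear at the next resolution) or
#' redundant (species-profile cosine to a sibling topic of the same model
#' at or above `redundancy_ceiling`: the model split or duplicated an
#' existing subcommunity). The selected K is the smallest resolution at
#' which (a) no topic is spurious and (b) the next resolution introduces at
#' least one spurious topic — the point where the count of genuine paths
#' plateaus and further resolution only manufactures spurious topics. If no
#' resolution satisfies both, falls back to the K with the fewest spurious
#' topics, with a warning.
#'
#' @param alignment A `topic_alignment` from [align_topics()].
#' @param coherence_floor Persistence similarity below which a topic is
#'   flagged transient (default 0.6).
#' @param redundancy_ceiling Within-model profile cosine at or above which
#'   a topic is flagged redundant (default 0.7; genuinely distinct
#'   subcommunities have well-separated profiles).
#' @return The selected K (integer).
#' @export
select_K <- function(alignment, coherence_floor = 0.6, redundancy_ceiling = 0.7) {
  ks <- alignment$K_grid
  if (length(ks) < 3L) stop("alignment must cover at least 3 resolutions")
  topics <- alignment$topics
  spurious <- vapply(ks, function(k) {
    t_k <- topics[topics$K == k, ]
    flag <- t_k$coherence < coherence_floor
    if (!is.null(t_k$redundancy)) {
      flag <- flag | (!is.na(t_k$redundancy) & t_k$redundancy >= redundancy_ceiling)
    }
    sum(flag)
  }, integer(1))
  for (j in seq_len(length(ks) - 1L)) {
    if (spurious[j] == 0L && spurious[j + 1L] > 0L) return(as.integer(ks[j]))
  }
  warning("no spurious-topic plateau; falling back to minimal spurious-topic count")
  as.integer(ks[which.min(spurious)])
}

#' Match estimated topics to reference topics
#'
#' Finds the topic permutation minimizing the mean total-variation distance
#' between rows of `beta` and rows of `reference`. Exhaustive over
#' permutations for K <= 7, greedy otherwise.
#'
#' @param beta Estimated K x V topic-species matrix (rows sum to 1).
#' @param reference Reference K x V matrix, same species order.
#' @return List with `permutation` (reference row assigned to each estimated
#'   row), `tv` (per-topic total-variation distances after matching), and
#'   `mean_tv`.
#' @export
match_topics <- function(beta, reference) {
  beta <- as.matrix(beta); reference <- as.matrix(reference)
  stopifnot(nrow(beta) == nrow(reference), ncol(beta) == ncol(reference))
  k <- nrow(beta)
  tvmat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    tvmat[i, j] <- 0.5 * sum(abs(beta[i, ] - reference[j, ]))
  }
  if (k <= 7L) {
    perms <- permutations_of(k)
    costs <- vapply(perms, function(p) sum(tvmat[cbind(seq_len(k), p)]), numeric(1))
    best <- perms[[which.min(costs)]]
  } else {
    best <- integer(k); taken <- logical(k)
    for (i in order(apply(tvmat, 1, min))) {
      j <- setdiff(order(tvmat[i, ]), which(taken))[1]
      best[i] <- j; taken[j] <- TRUE
    }
  }
  tv <- tvmat[cbind(seq_len(k), best)]
  list(permutation = best, tv = tv, mean_tv = mean(tv))
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Fit models over a K grid and align them
#'
#' @param counts Non-*Lactobacillus* count matrix.
#' @param k_grid Integer vector of resolutions (increasing).
#' @param seed Base seed; each resolution uses a derived child seed.
#' @param n_starts Random restarts per resolution (over-resolved models are
#'   prone to local optima that destabilize the alignment, so the grid uses
#'   more restarts than a single fit).
#' @param ... Passed to [fit_nonlacto_lda()].
#' @return List with `models` and `alignment`.
#' @export
fit_topic_grid <- function(counts, k_grid = 2:8, seed = 1L, n_starts = 8L, ...) {
  k_grid <- sort(unique(as.integer(k_grid)))
  models <- lapply(k_grid, function(k) {
    fit_nonlacto_lda(counts, k, seed = child_seed(seed, k), n_starts = n_starts, ...)
  })
  list(models = models, alignment = align_topics(models))
}
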