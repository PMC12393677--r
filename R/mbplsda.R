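# Multiblock PLS discriminant analysis (MB-PLS-DA): super-block NIPALS with
# block importance, block residualization, cross-validated component
# selection, and bootstrap confidence intervals for the relative cumulative
# block importance index.
#
# Variables are standardized; each block is then scaled to unit total
# variance (divided by the square root of its column count) so large blocks
# do not dominate the super score. The one-hot response is column-centered.
# Per component, block scores are combined through super weights maximizing
# covariance with the response score; deflation acts on the super score.

#' One-hot encode categorical variables with sparse-level jitter
#'
#' Every level becomes a 0/1 column. Columns with fewer positives than
#' `sparse_min` receive Gaussian noise with variance `1e-3 * S^2` (S^2 the
#' empirical column variance), which keeps downstream fits from degenerating
#' on near-constant indicator columns while leaving dense levels exact.
#'
#' @param data Data frame of factor/character variables.
#' @param seed Integer seed for the jitter.
#' @param sparse_min Positives below which a level is flagged sparse
#'   (default 5).
#' @param noise_var_ratio Jitter variance as a fraction of the column
#'   variance (default 1e-3).
#' @return Numeric matrix of encoded columns (named `variable.level`);
#'   single-level variables are dropped with a warning.
#' @export
one_hot_jitter <- function(data, seed = NULL, sparse_min = 5L,
                           noise_var_ratio = 1e-3) {
  data <- as.data.frame(data)
  cols <- list()
  for (v in names(data)) {
    f <- factor(data[[v]])
    if (nlevels(f) < 2L) {
      warning("dropping single-level variable: ", v)
      next
    }
    for (lev in levels(f)) {
      cols[[paste(v, lev, sep = ".")]] <- as.numeric(f == lev)
    }
  }
  if (!length(cols)) stop("no usable categorical variables")
  m <- do.call(cbind, cols)
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      if (sum(m[, j]) < sparse_min || sum(1 - m[, j]) < sparse_min) {
        s2 <- stats::var(m[, j])
        m[, j] <- m[, j] + stats::rnorm(nrow(m), 0, sqrt(noise_var_ratio * s2))
      }
    }
    m
  })
}

# NIPALS PLS2 on (pre-scaled) X and centered Y. Returns scores, weights,
# loadings, and Y-loadings for n_components.
nipals_pls2 <- function(x, y, n_components, tol = 1e-10, max_iter = 500L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  a <- n_components
  T_ <- matrix(0, n, a); W <- matrix(0, ncol(x), a)
  P <- matrix(0, ncol(x), a); C <- matrix(0, ncol(y), a)
  for (h in seq_len(a)) {
    u <- y[, which.max(apply(y, 2, stats::var)), drop = FALSE]
    t_old <- 0
    for (it in seq_len(max_iter)) {
      w <- crossprod(x, u); w <- w / sqrt(sum(w^2))
      t_ <- x %*% w
      cvec <- crossprod(y, t_) / sum(t_^2)
      u <- y %*% cvec / sum(cvec^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    p <- crossprod(x, t_) / sum(t_^2)
    cvec <- crossprod(y, t_) / sum(t_^2)
    x <- x - t_ %*% t(p)
    y <- y - t_ %*% t(cvec)
    T_[, h] <- t_; W[, h] <- w; P[, h] <- p; C[, h] <- cvec
  }
  list(scores = T_, weights = W, loadings = P, y_loadings = C)
}

#' Residualize one block on another with a PLS regression
#'
#' The target block is regressed on the predictor block by NIPALS PLS2 with
#' `n_components` latent components; the residuals (observed minus
#' predicted) replace the observed values. Residuals are orthogonal to the
#' extracted predictor scores.
#'
#' @param target,predictor Numeric matrices over the same samples.
#' @param n_components Number of PLS components (must not exceed the
#'   predictor rank).
#' @return Residual matrix, same shape as `target`, with attribute
#'   `scores` (the predictor scores used).
#' @export
residualize_block <- function(target, predictor, n_components = 2L) {
  target <- as.matrix(target); predictor <- as.matrix(predictor)
  if (nrow(target) != nrow(predictor)) stop("blocks must share samples")
  if (n_components > min(dim(predictor))) stop("components exceed predictor rank")
  xs <- scale(predictor, center = TRUE, scale = FALSE)
  ys <- scale(target, center = TRUE, scale = FALSE)
  fit <- nipals_pls2(xs, ys, n_components)
  pred <- fit$scores %*% t(fit$y_loadings)
  res <- ys - pred
  res <- sweep(res, 2, attr(ys, "scaled:center"), "+")
  dimnames(res) <- dimnames(target)
  attr(res, "scores") <- fit$scores
  res
}

#' Fit a multiblock PLS discriminant analysis
#'
#' @param blocks Named list of numeric matrices (samples x variables), all
#'   with the same rows.
#' @param response Factor of class labels (one per sample).
#' @param n_components Number of latent components (default 2).
#' @return Object of class `mbplsda` with super scores (unit norm), block
#'   weights/scores, super weights, response loadings, per-component and
#'   cumulative block importance, and everything needed for prediction.
#' @export
fit_mbplsda <- function(blocks, response, n_components = 2L) {
  if (!length(blocks)) stop("need at least one block")
  if (is.null(names(blocks)) || any(names(blocks) == "")) stop("blocks must be named")
  response <- factor(response)
  xs <- lapply(blocks, as.matrix)
  n <- unique(vapply(xs, nrow, integer(1)))
  if (length(n) != 1L || n != length(response)) stop("blocks and response must share samples")
  # standardize variables, then scale each block to unit total variance
  sts <- lapply(xs, standardize_cols)
  xb <- lapply(sts, function(s) s$x / sqrt(ncol(s$x)))
  p_b <- vapply(xs, ncol, integer(1))
  y <- stats::model.matrix(~ 0 + response)
  colnames(y) <- levels(response)
  y_center <- colMeans(y)
  y <- sweep(y, 2, y_center, "-")
  y0_ss <- sum(y^2)
  nb <- length(xb)
  a <- n_components
  super_scores <- matrix(0, n, a)
  super_weights <- matrix(0, nb, a, dimnames = list(names(blocks), NULL))
  block_weights <- lapply(p_b, function(p) matrix(0, p, a))
  block_scores <- lapply(seq_len(nb), function(b) matrix(0, n, a))
  y_loadings <- matrix(0, ncol(y), a, dimnames = list(colnames(y), NULL))
  x_loadings <- lapply(seq_len(nb), function(b) matrix(0, p_b[b], a))
  w_global <- matrix(0, sum(p_b), a)
  p_global <- matrix(0, sum(p_b), a)
  expl_y <- numeric(a)
  offsets <- c(0, cumsum(p_b))
  xcur <- xb; ycur <- y
  for (h in seq_len(a)) {
    u <- ycur[, which.max(apply(ycur, 2, stats::var)), drop = FALSE]
    t_super <- 0
    for (it in seq_len(500L)) {
      wb <- vector("list", nb); tb <- matrix(0, n, nb)
      for (b in seq_len(nb)) {
        w <- crossprod(xcur[[b]], u)
        nw <- sqrt(sum(w^2))
        w <- if (nw > 0) w / nw else w
        wb[[b]] <- w
        tb[, b] <- xcur[[b]] %*% w
      }
      ws <- crossprod(tb, u)
      ws <- ws / sqrt(sum(ws^2))
      t_new <- tb %*% ws
      t_new <- t_new / sqrt(sum(t_new^2))
      q <- crossprod(ycur, t_new)
      u_new <- ycur %*% q / sum(q^2)
      if (sum((t_new - t_super)^2) < 1e-12) { t_super <- t_new; u <- u_new; break }
      t_super <- t_new; u <- u_new
    }
    cvec <- crossprod(ycur, t_super)            # t_super has unit norm
    for (b in seq_len(nb)) {
      pl <- crossprod(xcur[[b]], t_super)
      x_loadings[[b]][, h] <- pl
      block_weights[[b]][, h] <- wb[[b]]
      block_scores[[b]][, h] <- tb[, b]
      w_global[(offsets[b] + 1):offsets[b + 1], h] <- wb[[b]] * ws[b]
      p_global[(offsets[b] + 1):offsets[b + 1], h] <- pl
      xcur[[b]] <- xcur[[b]] - t_super %*% t(pl)
    }
    expl_y[h] <- sum((t_super %*% t(cvec))^2) / y0_ss
    ycur <- ycur - t_super %*% t(cvec)
    super_scores[, h] <- t_super
    super_weights[, h] <- ws
    y_loadings[, h] <- cvec
  }
  # block importance: squared super weights per component, accumulated over
  # components with weights proportional to the response variance explained
  bip <- super_weights^2
  wts <- expl_y / sum(expl_y)
  bipc <- as.vector(bip %*% wts)
  names(bipc) <- names(blocks)
  structure(list(
    blocks = names(blocks), p_b = p_b, n_components = a,
    super_scores = super_scores, super_weights = super_weights,
    block_weights = block_weights, block_scores = block_scores,
    x_loadings = x_loadings, y_loadings = y_loadings,
    w_global = w_global, p_global = p_global,
    expl_y = expl_y, bip = bip, bipc = bipc,
    centers = lapply(sts, `[[`, "center"), scales = lapply(sts, `[[`, "scale"),
    y_center = y_center, levels = levels(response)
  ), class = "mbplsda")
}

#' Relative cumulative block importance
#'
#' The cumulative block importance (BIPC) divided by the block's share of
#' the total variable count — the expected BIPC if every variable carried
#' the same importance. A value of 1 marks importance proportional to block
#' size; the variable-share-weighted mean of the indices is 1 by
#' construction.
#'
#' @param fit An `mbplsda` fit.
#' @return Named numeric vector, one index per block.
#' @export
relative_block_importance <- function(fit) {
  stopifnot(inherits(fit, "mbplsda"))
  share <- fit$p_b / sum(fit$p_b)
  fit$bipc / share
}

#' Predict class labels from an `mbplsda` fit
#'
#' @param object An `mbplsda` fit.
#' @param newdata Named list of blocks matching the fit.
#' @param n_components Number of components to use (default all fitted).
#' @param ... Unused.
#' @return List with `scores` (predicted response scores) and `class`
#'   (argmax label).
#' @export
predict.mbplsda <- function(object, newdata, n_components = object$n_components, ...) {
  h <- seq_len(n_components)
  xb <- lapply(seq_along(object$blocks), function(b) {
    nm <- object$blocks[b]
    x <- as.matrix(newdata[[nm]])
    x <- sweep(sweep(x, 2, object$centers[[b]], "-"), 2, object$scales[[b]], "/")
    x / sqrt(object$p_b[b])
  })
  x <- do.call(cbind, xb)
  w <- object$w_global[, h, drop = FALSE]
  p <- object$p_global[, h, drop = FALSE]
  wstar <- w %*% solve(crossprod(p, w))
  t_new <- x %*% wstar
  yhat <- t_new %*% t(object$y_loadings[, h, drop = FALSE])
  yhat <- sweep(yhat, 2, object$y_center, "+")
  colnames(yhat) <- object$levels
  cls <- factor(object$levels[max.col(yhat, ties.method = "first")],
                levels = object$levels)
  list(scores = yhat, class = cls)
}

macro_f1 <- function(truth, predicted) {
  truth <- factor(truth); predicted <- factor(predicted, levels = levels(truth))
  f1 <- vapply(levels(truth), function(l) {
    tp <- sum(truth == l & predicted == l)
    fp <- sum(truth != l & predicted == l)
    fn <- sum(truth == l & predicted != l)
    if (tp == 0 && (fp > 0 || fn > 0)) return(0)
    if (tp == 0) return(NA_real_)   # class absent and never predicted
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

#' Cross-validated selection of the number of components
#'
#' Repeated stratified 75/25 calibration/validation splits; per split and
#' candidate component count, the model is fitted on the calibration set and
#' validation classes are predicted by the maximum predicted response score;
#' performance is the macro-averaged F1. The component count maximizing the
#' mean validation F1 is selected (ties go to the smaller count).
#'
#' @param blocks Named list of blocks.
#' @param response Factor of class labels.
#' @param component_grid Candidate component counts (default 1:4).
#' @param n_splits Number of random splits (default 40).
#' @param calib_frac Calibration fraction (default 0.75).
#' @param seed Integer seed.
#' @return List of class `mbplsda_cv` with `f1` (splits x grid matrix),
#'   `mean_f1`, and `selected`.
#' @export
cross_validate <- function(blocks, response, component_grid = 1:4,
                           n_splits = 40L, calib_frac = 0.75, seed = NULL) {
  response <- factor(response)
  n <- length(response)
  idx_by_class <- split(seq_len(n), response)
  if (any(lengths(idx_by_class) < 2L)) stop("need >= 2 samples per class")
  f1 <- matrix(NA_real_, n_splits, length(component_grid),
               dimnames = list(NULL, component_grid))
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      repeat {
        calib <- sort(unlist(lapply(idx_by_class, function(i) {
          sample(i, max(1L, round(calib_frac * length(i))))
        })))
        if (nlevels(droplevels(response[calib])) == nlevels(response)) break
        message("redrawing split: class absent from calibration set")
      }
      valid <- setdiff(seq_len(n), calib)
      cb <- lapply(blocks, function(x) as.matrix(x)[calib, , drop = FALSE])
      vb <- lapply(blocks, function(x) as.matrix(x)[valid, , drop = FALSE])
      fit <- fit_mbplsda(cb, response[calib], n_components = max(component_grid))
      for (g in seq_along(component_grid)) {
        pr <- predict(fit, vb, n_components = component_grid[g])
        f1[s, g] <- macro_f1(response[valid], pr$class)
      }
    }
  })
  mean_f1 <- colMeans(f1)
  sel <- component_grid[which.max(mean_f1)]
  structure(list(f1 = f1, mean_f1 = mean_f1, selected = sel,
                 component_grid = component_grid, n_splits = n_splits,
                 calib_frac = calib_frac, seed = seed),
            class = "mbplsda_cv")
}

#' Bootstrap confidence intervals for relative block importance
#'
#' Samples are resampled with replacement (resamples in which a class
#' vanishes are redrawn), the model is refitted, and percentile intervals
#' of the relative cumulative importance index are returned per block.
#'
#' @param blocks Named list of blocks.
#' @param response Factor of class labels.
#' @param n_components Components per refit.
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with per-block point estimate and percentile bounds.
#' @export
bootstrap_block_importance <- function(blocks, response, n_components = 2L,
                                       n_boot = 200L, seed = NULL, conf = 0.95) {
  if (n_boot < 200L) stop("n_boot must be >= 200")
  response <- factor(response)
  n <- length(response)
  point <- relative_block_importance(fit_mbplsda(blocks, response, n_components))
  draws <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(i) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (nlevels(droplevels(response[idx])) == nlevels(response)) break
      }
      bb <- lapply(blocks, function(x) as.matrix(x)[idx, , drop = FALSE])
      ok <- tryCatch(
        relative_block_importance(fit_mbplsda(bb, response[idx], n_components)),
        error = function(e) rep(NA_real_, length(blocks))
      )
      ok
    }, numeric(length(blocks))))
  })
  alpha <- (1 - conf) / 2
  data.frame(
    block = names(point),
    estimate = as.numeric(point),
    lower = apply(draws, 2, stats::quantile, alpha, na.rm = TRUE),
    upper = apply(draws, 2, stats::quantile, 1 - alpha, na.rm = TRUE),
    row.names = NULL
  )
}
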