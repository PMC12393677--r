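sim_blocks <- function(n = 90, seed = 1) {
  # three classes separated in a 2-dimensional latent space; one informative
  # block carries the latent structure, one is pure noise
  withr::with_seed(seed, {
    cls <- factor(rep(c("a", "b", "c"), length.out = n))
    mu <- rbind(a = c(2, 0), b = c(-1, 2), c = c(-1, -2))
    lat <- mu[cls, ] + matrix(rnorm(n * 2, 0, 0.6), n)
    load <- matrix(rnorm(2 * 6), 2)
    signal <- lat %*% load + matrix(rnorm(n * 6, 0, 0.4), n)
    noise <- matrix(rnorm(n * 8), n)
    colnames(signal) <- paste0("s", 1:6); colnames(noise) <- paste0("n", 1:8)
    list(blocks = list(signal = signal, noise = noise), class = cls)
  })
}

test_that("one-hot encoding jitters only sparse levels and is reproducible", {
  d <- data.frame(
    balanced = rep(c("x", "y"), 50),
    sparse = c(rep("rare", 2), rep("common", 98))
  )
  m1 <- one_hot_jitter(d, seed = 4)
  m2 <- one_hot_jitter(d, seed = 4)
  expect_identical(m1, m2)
  # balanced variable stays an exact 0/1 encoding
  expect_true(all(m1[, "balanced.x"] %in% c(0, 1)))
  # sparse level receives noise with sd sqrt(1e-3 * S^2)
  raw <- as.numeric(d$sparse == "rare")
  jit <- m1[, "sparse.rare"] - raw
  expect_gt(sd(jit), 0)
  expect_equal(sd(jit), sqrt(1e-3 * var(raw)), tolerance = 0.5)
  expect_warning(one_hot_jitter(data.frame(a = rep("z", 10), b = rep(c("u", "v"), 5))),
                 "single-level")
})

test_that("single-block fit coincides with an ordinary PLS-DA (oracle NIPALS)", {
  sim <- sim_blocks()
  x <- scale(sim$blocks$signal)
  y <- model.matrix(~ 0 + sim$class)
  fit <- fit_mbplsda(list(only = sim$blocks$signal), sim$class, n_components = 2)
  orc <- oracle_pls2(x / sqrt(ncol(x)), scale(y, scale = FALSE), 2)
  # super scores equal the PLS2 scores up to normalization and sign
  for (h in 1:2) {
    a <- fit$super_scores[, h]
    b <- orc$scores[, h] / sqrt(sum(orc$scores[, h]^2))
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-6)
  }
  # super scores orthonormal
  g <- crossprod(fit$super_scores)
  expect_equal(g, diag(2), tolerance = 1e-8)
})

test_that("block importance finds the informative block and averages to 1", {
  sim <- sim_blocks(seed = 7)
  fit <- fit_mbplsda(sim$blocks, sim$class, n_components = 2)
  ri <- relative_block_importance(fit)
  expect_gt(ri[["signal"]], 1)
  expect_lt(ri[["noise"]], 1)
  expect_gt(ri[["signal"]], ri[["noise"]])
  share <- fit$p_b / sum(fit$p_b)
  expect_equal(sum(ri * share), 1, tolerance = 1e-10)
  # consistent sample permutation leaves the fit unchanged
  ord <- sample(length(sim$class))
  fit2 <- fit_mbplsda(lapply(sim$blocks, function(b) b[ord, ]),
                      sim$class[ord], n_components = 2)
  expect_equal(abs(fit2$super_weights), abs(fit$super_weights), tolerance = 1e-6)
})

test_that("residualization matches the oracle and nulls keep the target intact", {
  withr::with_seed(11, {
    n <- 60
    pred <- matrix(rnorm(n * 3), n)
    target_lin <- pred %*% matrix(c(1, -1, 0.5, 0.3, 2, -0.2), 3, 2)
    target_null <- matrix(rnorm(n * 2), n)
  })
  # target exactly linear in the predictor: residuals vanish
  r_lin <- residualize_block(target_lin, pred, n_components = 3)
  expect_lt(max(abs(scale(r_lin, scale = FALSE))), 1e-8)
  # independent target: essentially unchanged
  r_null <- residualize_block(target_null, pred, n_components = 2)
  expect_gt(cor(as.vector(r_null), as.vector(target_null)), 0.9)
  # brute-force NIPALS deflation oracle on a toy case
  withr::with_seed(12, {
    x10 <- matrix(rnorm(30), 10, 3)
    y10 <- x10 %*% matrix(rnorm(6), 3, 2) + matrix(rnorm(20, 0, 0.2), 10)
  })
  mine <- residualize_block(y10, x10, n_components = 2)
  orc <- oracle_pls2(x10, y10, 2)
  expect_equal(unname(scale(mine, scale = FALSE)), unname(orc$residuals),
               tolerance = 1e-6, ignore_attr = TRUE)
  # residuals orthogonal to extracted scores
  expect_lt(max(abs(crossprod(attr(mine, "scores"), scale(mine, scale = FALSE)))), 1e-6)
  expect_error(residualize_block(y10, x10, n_components = 9), "rank")
})

test_that("cross-validation selects two components for a two-component structure", {
  sim <- sim_blocks(n = 120, seed = 21)
  cv <- cross_validate(sim$blocks, sim$class, component_grid = 1:4,
                       n_splits = 15, seed = 5)
  expect_equal(cv$selected, 2)
  expect_true(all(cv$f1 >= 0 & cv$f1 <= 1, na.rm = TRUE))
  cv2 <- cross_validate(sim$blocks, sim$class, component_grid = 1:4,
                        n_splits = 15, seed = 5)
  expect_identical(cv$f1, cv2$f1)
  # pure-noise predictors hover near chance macro-F1
  withr::with_seed(30, {
    nb <- list(x = matrix(rnorm(120 * 6), 120))
    cls <- factor(rep(c("a", "b", "c"), 40))
  })
  cv0 <- cross_validate(nb, cls, component_grid = 2, n_splits = 15, seed = 6)
  expect_lt(mean(cv0$f1), 0.55)
})

test_that("bootstrap importance intervals separate signal from size-share null", {
  sim <- sim_blocks(n = 90, seed = 3)
  bi <- bootstrap_block_importance(sim$blocks, sim$class, n_components = 2,
                                   n_boot = 200, seed = 8)
  expect_equal(bi$block, c("signal", "noise"))
  expect_true(all(bi$lower <= bi$estimate & bi$estimate <= bi$upper))
  expect_gt(bi$lower[bi$block == "signal"], 1)
  bi2 <- bootstrap_block_importance(sim$blocks, sim$class, n_components = 2,
                                    n_boot = 200, seed = 8)
  expect_identical(bi, bi2)
  expect_error(bootstrap_block_importance(sim$blocks, sim$class, n_boot = 50),
               ">= 200")
})
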