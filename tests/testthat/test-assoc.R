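test_that("RV coefficient matches direct trace arithmetic and self-congruence", {
  withr::with_seed(10, x <- matrix(rnorm(18), 6, 3))
  expect_equal(rv_coefficient(x, x), 1)
  # scaled, column-permuted copy against brute-force trace computation
  y <- x[, c(2, 3, 1)] %*% diag(c(2, 0.5, 3))
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  a <- xc %*% t(xc); b <- yc %*% t(yc)
  brute <- sum(diag(a %*% b)) / sqrt(sum(diag(a %*% a)) * sum(diag(b %*% b)))
  expect_equal(rv_coefficient(x, y), brute, tolerance = 1e-12)
  expect_error(rv_coefficient(x[1:2, ], x[1:2, ]), "fewer than 3")
  # invariance to orthogonal rotation of either table
  withr::with_seed(11, {
    z <- matrix(rnorm(40), 10, 4)
    w <- matrix(rnorm(30), 10, 3)
    q <- qr.Q(qr(matrix(rnorm(16), 4)))
  })
  expect_equal(rv_coefficient(z %*% q, w), rv_coefficient(z, w), tolerance = 1e-10)
  # independence: RV shrinks toward 0 at large n
  withr::with_seed(12, {
    xa <- matrix(rnorm(500 * 4), 500)
    xb <- matrix(rnorm(500 * 4), 500)
  })
  expect_lt(rv_coefficient(xa, xb), 0.05)
})

test_that("RV permutation test is reproducible and maximal for Y = X", {
  withr::with_seed(20, x <- matrix(rnorm(60), 20, 3))
  r1 <- rv_permutation_test(x, x, n_perm = 99, seed = 4)
  expect_equal(r1$p_value, 1 / 100)
  r2 <- rv_permutation_test(x, x, n_perm = 99, seed = 4)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$permuted, r2$permuted)
  expect_error(rv_permutation_test(x, x, n_perm = 50), ">= 99")
})

test_that("PERMANOVA separates planted groups and is calibrated-ish under the null", {
  withr::with_seed(30, {
    g <- rep(c("a", "b"), each = 15)
    x0 <- matrix(rnorm(30 * 5), 30)
    x1 <- x0 + 4 * (g == "b")   # large planted separation
  })
  d1 <- dist(x1)
  out <- permanova(d1, g, n_perm = 199, seed = 1)
  expect_equal(out$p_value, 1 / 200)
  expect_gt(out$f_statistic, 10)
  out0 <- permanova(dist(x0), g, n_perm = 199, seed = 1)
  expect_gt(out0$p_value, 0.05)
  expect_error(permanova(d1, c("a", rep("b", 29))), "singleton")
})

test_that("DiSTATIS compromise matches a brute-force computation on a toy pair", {
  withr::with_seed(40, {
    x1 <- matrix(rnorm(10), 5, 2)
    x2 <- x1 + matrix(rnorm(10, 0, 0.3), 5, 2)
  })
  d1 <- as.matrix(dist(x1)); d2 <- as.matrix(dist(x2))
  res <- distatis(list(a = d1, b = d2), n_dims = 2)
  # brute force: double-center squared distances, normalize, RV weights
  dc <- function(d) {
    n <- nrow(d); j <- diag(n) - 1 / n
    s <- -0.5 * j %*% (d^2) %*% j
    s / eigen(s)$values[1]
  }
  s1 <- dc(d1); s2 <- dc(d2)
  rv12 <- sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2))
  cmat <- matrix(c(1, rv12, rv12, 1), 2)
  ev <- eigen(cmat)$vectors[, 1]; ev <- abs(ev) / sum(abs(ev))
  comp <- ev[1] * s1 + ev[2] * s2
  expect_equal(res$weights, c(a = ev[1], b = ev[2]), tolerance = 1e-10)
  expect_equal(res$compromise, comp, tolerance = 1e-10)
  eg <- eigen(comp, symmetric = TRUE)
  expect_equal(unname(abs(res$scores[, 1])),
               abs(eg$vectors[, 1] * sqrt(eg$values[1])), tolerance = 1e-8)
  # identical tables: equal weights, compromise equals either normalized table
  res2 <- distatis(list(a = d1, b = d1), n_dims = 2)
  expect_equal(unname(res2$weights), c(0.5, 0.5))
  expect_equal(res2$compromise, s1, tolerance = 1e-10)
  # eigenvalues sorted, scores real for Euclidean-embeddable input
  expect_true(all(diff(res$eigenvalues) <= 1e-10))
  expect_error(distatis(list(d1, d1[, 5:1])), "symmetric")
})

test_that("correlation circle reproduces Pearson correlations and flags constants", {
  withr::with_seed(50, {
    scores <- matrix(rnorm(60), 30, 2)
    v <- cbind(lin = scores[, 1], noise = rnorm(30), const = rep(1, 30))
  })
  expect_warning(cc <- correlation_circle(v, scores), "constant")
  expect_equal(unname(cc["lin", 1]), 1)
  expect_equal(unname(cc["noise", 1]), cor(v[, "noise"], scores[, 1]))
  expect_true(all(is.na(cc["const", ])))
  expect_true(all(abs(cc[!is.na(cc)]) <= 1))
})

test_that("first DiSTATIS dimension separates Lactobacillus dominance on synthetic data", {
  co <- generate_cohort(cohort_config(n_participants = 80, seed = 33,
                                      missing_visit_prob = 0))
  prop <- relative_abundance(co$counts)
  fit <- fit_topic_model(co$counts, co$taxonomy, K = 4, seed = 2, n_starts = 2)
  prep <- preprocess_cytokines(co$cytokines)
  shared <- intersect(rownames(prop), rownames(prep$matrix))
  topics <- fit$topic_proportions[shared, ]
  d_mb <- as.matrix(vegan::vegdist(prop[shared, ], "bray"))
  d_ck <- as.matrix(dist(scale(prep$matrix[shared, ])))
  res <- distatis(list(microbiota = d_mb, cytokines = d_ck), n_dims = 4,
                  mode = "squared")
  lacto <- co$truth$samples$lacto_prop[match(shared, co$truth$samples$sample)]
  # dimension 1 tracks the Lactobacillus gradient
  expect_gt(abs(cor(res$scores[, 1], lacto)), 0.7)
  cc <- correlation_circle(cbind(topics, prep$matrix[shared, ]), res$scores)
  sgn <- sign(cor(res$scores[, 1], lacto))
  # pro-inflammatory analytes load opposite to the Lactobacillus direction
  expect_lt(sgn * cc["IL-1b", 1], 0)
  expect_lt(sgn * cc["TNF-a", 1], 0)
  expect_gt(sgn * cc["MIG", 1], 0)
})
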