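make_panel <- function(values, lloq = 1, uloq = 1e4) {
  # values: samples x analytes matrix of linear concentrations
  data.frame(
    sample = rep(rownames(values), ncol(values)),
    analyte = rep(colnames(values), each = nrow(values)),
    concentration = as.vector(values),
    flag = ifelse(as.vector(values) < lloq, "below_lloq",
                  ifelse(as.vector(values) > uloq, "above_uloq", "in_range")),
    lloq = lloq, uloq = uloq
  )
}

test_that("LOQ imputation follows the half-LLOQ / ULOQ rule", {
  p <- data.frame(sample = c("a", "b", "c"), analyte = "IL-6",
                  concentration = c(2, 50, 20000),
                  flag = c("below_lloq", "in_range", "above_uloq"),
                  lloq = 3.2, uloq = 10000)
  out <- impute_out_of_range(p)
  expect_equal(out$imputed, c(1.6, 50, 10000))
  expect_equal(out$log10_conc[1], 0.2041, tolerance = 1e-4)
  # no censoring: pure log10
  clean <- p; clean$flag <- "in_range"
  expect_equal(impute_out_of_range(clean)$log10_conc, log10(p$concentration))
  bad <- p; bad$lloq <- 2e4
  expect_error(impute_out_of_range(bad), "inverted")
})

test_that("analyte exclusion thresholds are inclusive", {
  flag_frac <- function(n_below, n_above, n) {
    c(rep("below_lloq", n_below), rep("above_uloq", n_above),
      rep("in_range", n - n_below - n_above))
  }
  p <- data.frame(
    analyte = rep(c("heavy_low", "edge_high", "clean"), each = 100),
    flag = c(flag_frac(61, 0, 100), flag_frac(0, 30, 100), flag_frac(0, 0, 100))
  )
  out <- exclude_analytes(p)
  expect_false(out$included[out$analyte == "heavy_low"])
  expect_false(out$included[out$analyte == "edge_high"])   # exactly 30% above
  expect_true(out$included[out$analyte == "clean"])
})

test_that("pc1_subtract annihilates rank-1 structure and matches the outer-product oracle", {
  withr::with_seed(12, {
    n <- 40; p <- 6
    # exact rank-1 structure in standardized space
    s <- rnorm(n)
    x1 <- outer(s, runif(p, 0.5, 2))
    adj <- pc1_subtract(x1 + matrix(rnorm(n * p, 0, 1e-8), n))
    expect_lt(max(abs(scale(adj, scale = FALSE))), 1e-5)
    # two-component data: adjusted equals X_std - t1 p1' computed by brute force
    x <- outer(rnorm(n), runif(p, 0.5, 2)) + outer(rnorm(n), rep(c(1, -1), 3)) +
      matrix(rnorm(n * p, 0, 0.05), n)
    xs <- scale(x)
    e <- eigen(crossprod(xs) / (n - 1), symmetric = TRUE)
    p1 <- e$vectors[, 1]
    brute <- xs - (xs %*% p1) %*% t(p1)
    adj2 <- pc1_subtract(x)
    adj2_std <- sweep(sweep(adj2, 2, colMeans(x), "-"), 2, apply(x, 2, sd), "/")
    expect_equal(unname(adj2_std), unname(brute), tolerance = 1e-8,
                 ignore_attr = TRUE)
  })
})

test_that("variance fractions are nonincreasing, sum to 1, and detect rank-1 data", {
  withr::with_seed(3, {
    x <- matrix(rnorm(200 * 8), 200)
    ve <- variance_explained(x)
    expect_equal(sum(ve), 1)
    expect_true(all(diff(ve) <= 1e-12))
    r1 <- outer(rnorm(50), runif(5, 1, 2)) + matrix(rnorm(250, 0, 1e-9), 50)
    expect_equal(variance_explained(r1)[1], 1, tolerance = 1e-6)
  })
})

test_that("baseline deltas subtract the preMTZ visit and drop incomplete participants", {
  vals <- matrix(c(1, 2, 3, 10, 12, 30), nrow = 6, ncol = 1,
                 dimnames = list(c("A_preMTZ", "A_wk4", "A_wk12",
                                   "B_wk4", "B_wk12", "C_preMTZ"), "IL-6"))
  md <- data.frame(
    sample = rownames(vals),
    participant = c("A", "A", "A", "B", "B", "C"),
    visit = c("preMTZ", "wk4", "wk12", "wk4", "wk12", "preMTZ")
  )
  expect_message(d <- baseline_delta(vals, md), "1 participant")
  expect_equal(d$delta[d$participant == "A" & d$visit == "wk4"], 1)
  expect_equal(d$delta[d$participant == "A" & d$visit == "wk12"], 2)
  expect_false("B" %in% d$participant)   # no baseline
  expect_false(any(d$visit == "preMTZ")) # baseline rows carry no delta
})

test_that("preprocessing recovers a planted arm effect in deltas", {
  co <- generate_cohort(cohort_config(n_participants = 200, seed = 14,
                                      missing_visit_prob = 0))
  prep <- preprocess_cytokines(co$cytokines)
  # heavily censored analytes are excluded by the 60% rule
  expect_false(all(prep$inclusion$included))
  d <- baseline_delta(prep$matrix, co$metadata)
  # IL-1b decreases with Lactobacillus: LBP arm (higher Lactobacillus at
  # wk24) has lower IL-1b deltas than placebo
  arm <- co$metadata$arm[match(paste0(d$participant, "_wk24"), co$metadata$sample)]
  il1b <- d$analyte == "IL-1b" & d$visit == "wk24"
  diff_arm <- mean(d$delta[il1b & arm == "LBP"]) - mean(d$delta[il1b & arm == "placebo"])
  expect_lt(diff_arm, 0)
})

test_that("pc1_subtract commutes with sample reordering", {
  withr::with_seed(6, x <- matrix(rnorm(30 * 5), 30) + outer(rnorm(30), rep(1, 5)))
  adj <- pc1_subtract(x)
  ord <- sample(30)
  adj_perm <- pc1_subtract(x[ord, ])
  expect_equal(unname(adj_perm), unname(adj[ord, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
})
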