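test_that("configuration validation rejects malformed inputs", {
  expect_error(cohort_config(n_participants = 0), "zero participants")
  expect_error(cohort_config(arm_ratio = c(2.5, 1)), "non-integer")
  expect_error(cohort_config(lbp_colonization_prob = 1.2), "probabilities")
  expect_error(cohort_config(topic_species_profiles = matrix(0.5, 4, 3)),
               "sum to 1")
  cfg <- cohort_config()
  expect_s3_class(cfg, "cohort_config")
  expect_true(all(abs(rowSums(cfg$topic_species_profiles) - 1) < 1e-8))
})

test_that("generation is deterministic given a seed and internally consistent", {
  cfg <- cohort_config(n_participants = 30, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cytokines, b$cytokines)
  expect_identical(a$strains, b$strains)
  expect_identical(a$truth$participants, b$truth$participants)
  # every count row has a metadata row; truth covers every participant
  expect_setequal(rownames(a$counts), a$metadata$sample)
  expect_setequal(a$truth$participants$participant,
                  unique(a$metadata$participant))
  # depth invariant: fixed depth makes all row sums equal
  cf <- generate_cohort(cohort_config(n_participants = 10, fixed_depth = 20000,
                                      seed = 1))
  expect_true(all(rowSums(cf$counts) == 20000))
  # 2:1 randomization
  arms <- table(a$truth$participants$arm)
  expect_equal(unname(arms[["LBP"]]), 20)
})

test_that("null configuration yields arm-wise rates differing only by noise", {
  cfg <- cohort_config(n_participants = 400, lbp_colonization_prob = 0.2,
                       placebo_colonization_prob = 0.2,
                       missing_visit_prob = 0, seed = 55)
  co <- generate_cohort(cfg)
  lc <- co$truth$categories[, "wk4"] == "LC_DOM"
  arm <- co$truth$participants$arm
  p1 <- mean(lc[arm == "LBP"]); p2 <- mean(lc[arm == "placebo"])
  se <- sqrt(0.2 * 0.8 * (1 / sum(arm == "LBP") + 1 / sum(arm == "placebo")))
  expect_lt(abs(p1 - p2), 3 * se)
})

test_that("benefit ratio at week 12 matches the binomial oracle band", {
  cfg <- cohort_config(n_participants = 300, lbp_colonization_prob = 0.30,
                       placebo_colonization_prob = 0.09,
                       missing_visit_prob = 0, seed = 202)
  co <- generate_cohort(cfg)
  lc <- co$truth$categories[, "wk12"] == "LC_DOM"
  arm <- co$truth$participants$arm
  n1 <- sum(arm == "LBP"); n2 <- sum(arm == "placebo")
  br <- (sum(lc[arm == "LBP"]) / n1) / (sum(lc[arm == "placebo"]) / n2)
  # brute-force Monte-Carlo band of the same binomial benefit ratio
  withr::with_seed(1, {
    sims <- replicate(4000, {
      (rbinom(1, n1, 0.30) / n1) / max(rbinom(1, n2, 0.09), 0.5) * n2
    })
  })
  band <- quantile(sims, c(0.025, 0.975))
  expect_gte(br, band[[1]])
  expect_lte(br, band[[2]])
})

test_that("cytokine generator obeys its contracts", {
  cfg <- cohort_config(n_participants = 60, seed = 31, missing_visit_prob = 0)
  co <- generate_cohort(cfg)
  ck <- co$cytokines
  expect_true(all(ck$flag %in% c("in_range", "below_lloq", "above_uloq")))
  # censored entries are reported at the limit value
  below <- ck$flag == "below_lloq"
  expect_equal(ck$concentration[below], ck$lloq[below])
  # no size factor and zero effects: analytes essentially uncorrelated
  cfg0 <- cohort_config(n_participants = 120, size_factor_sd = 0,
                        cytokine_effects = setNames(rep(0, 4), c("A", "B", "C", "D")),
                        missing_visit_prob = 0, seed = 32)
  co0 <- generate_cohort(cfg0)
  m <- preprocess_cytokines(co0$cytokines, adjust = FALSE)$matrix
  cm <- cor(m)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.15)
  # dominant size factor: PC1 variance fraction approaches its share
  cfg1 <- cohort_config(n_participants = 120, size_factor_sd = 2,
                        missing_visit_prob = 0, seed = 33)
  co1 <- generate_cohort(cfg1)
  panel1 <- impute_out_of_range(co1$cytokines)
  m1 <- panel_matrix(panel1)
  ve <- variance_explained(m1)
  # brute-force eigendecomposition of the standardized matrix
  ev <- eigen(cor(m1), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ve[1], ev[1] / sum(ev), tolerance = 1e-10)
  expect_gt(ve[1], 0.8)
})

test_that("sequencing depth is log-normal around the configured median", {
  co <- generate_cohort(cohort_config(n_participants = 150, seed = 41))
  depth <- rowSums(co$counts)
  expect_gt(median(depth), 31000 * 0.9)
  expect_lt(median(depth), 31000 * 1.1)
  expect_equal(co$truth$samples$depth[match(rownames(co$counts),
                                            co$truth$samples$sample)],
               unname(depth))
})

test_that("written cohort round-trips through plain-text files", {
  co <- generate_cohort(cohort_config(n_participants = 8, seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  cnt <- read.delim(paths[["counts"]], check.names = FALSE)
  expect_equal(nrow(cnt), nrow(co$counts))
  expect_equal(as.matrix(cnt[, -1]), co$counts, ignore_attr = TRUE)
  ck <- read.csv(paths[["cytokines"]])
  expect_equal(nrow(ck), nrow(co$cytokines))
})
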