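test_that("benefit ratio reproduces the trial's printed 2x2 results", {
  # primary endpoint, L. crispatus dominance at week 12
  br <- benefit_ratio(37, 123, 5, 56)
  expect_equal(round(br$ratio, 2), 3.37)
  expect_equal(round(br$ci_low, 2), 1.40)
  expect_equal(round(br$ci_high, 2), 8.11)
  expect_lt(br$p_value, 0.005)
  # week 24
  br <- benefit_ratio(39, 113, 4, 52)
  expect_equal(round(c(br$ratio, br$ci_low, br$ci_high), 2), c(4.49, 1.69, 11.90))
  # equal rates give ratio exactly 1
  expect_equal(benefit_ratio(10, 20, 10, 20)$ratio, 1)
})

test_that("benefit ratio signals degenerate tables", {
  expect_warning(br0 <- benefit_ratio(5, 20, 0, 20), "infinite")
  expect_equal(br0$ratio, Inf)
  expect_error(benefit_ratio(0, 20, 0, 20), "undefined")
})

test_that("wilson interval matches the closed form and prop.test oracle", {
  w <- wilson_ci(5, 10)
  expect_equal(round(unname(w[2:3]), 4), c(0.2366, 0.7634))
  expect_equal(unname(wilson_ci(0, 10)[["lower"]]), 0)
  expect_equal(unname(wilson_ci(10, 10)[["upper"]]), 1)
  for (kn in list(c(1, 7), c(5, 10), c(19, 20), c(12, 40))) {
    w <- wilson_ci(kn[1], kn[2])
    pt <- suppressWarnings(prop.test(kn[1], kn[2], correct = FALSE))$conf.int
    expect_equal(unname(w[["lower"]]), pt[1], tolerance = 1e-10)
    expect_equal(unname(w[["upper"]]), pt[2], tolerance = 1e-10)
    expect_gte(kn[1] / kn[2], w[["lower"]])
    expect_lte(kn[1] / kn[2], w[["upper"]])
  }
  # width shrinks with n at fixed rate
  expect_lt(diff(wilson_ci(50, 100)[2:3]), diff(wilson_ci(5, 10)[2:3]))
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.1, 0.5)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("stratified rates exclude sparse strata and difference CIs behave", {
  withr::with_seed(2, outcome <- rbinom(60, 1, 0.4))
  arm <- rep(c("placebo", "LBP"), 30)
  stratum <- c(rep("big1", 28), rep("big2", 28), rep("tiny", 4))
  # tiny stratum: 3 LBP but a single placebo participant -> excluded
  arm[stratum == "tiny"] <- c("LBP", "LBP", "LBP", "placebo")
  expect_message(out <- stratified_rates(outcome, arm, stratum), "excluded")
  expect_false("tiny" %in% out$rates$stratum)
  expect_equal(sort(unique(out$rates$stratum)), c("big1", "big2"))
  # identical arms give zero differences
  oc <- rep(c(1, 0), 20)
  res <- stratified_rates(oc, rep(c("LBP", "placebo"), each = 20),
                          rep("all", 40))
  expect_equal(res$differences$difference, 0)
})

test_that("heterogeneity F test detects a planted interaction and respects labels", {
  withr::with_seed(31, {
    n <- 240
    arm <- factor(rep(c("LBP", "placebo"), n / 2))
    stratum <- factor(sample(c("a", "b"), n, TRUE))
    eta <- -0.5 + 1.0 * (arm == "LBP") - 2.2 * (arm == "LBP") * (stratum == "b")
    y <- rbinom(n, 1, plogis(eta))
  })
  ht <- heterogeneity_test(y, arm, data.frame(stratum = stratum))
  expect_lt(ht$p_value, 0.05)
  expect_false(ht$separation)
  # relabeling strata leaves the F statistic unchanged
  relab <- factor(ifelse(stratum == "a", "zz", "aa"))
  ht2 <- heterogeneity_test(y, arm, data.frame(stratum = relab))
  expect_equal(ht$f_statistic, ht2$f_statistic, tolerance = 1e-10)
  expect_equal(ht$df, ht2$df)
})

test_that("counterfactual predictions match closed forms", {
  withr::with_seed(5, {
    n <- 150
    d <- data.frame(arm = relevel(factor(rep(c("placebo", "LBP"), length.out = n)),
                                  "placebo"),
                    x = rnorm(n))
    d$y <- rbinom(n, 1, plogis(0.7 * (d$arm == "LBP")))
  })
  fit <- glm(y ~ arm + x, binomial(), data = d)
  cf <- counterfactual_predictions(fit, d, "arm", "LBP", "placebo")
  b <- coef(fit)[["armLBP"]]
  # no interaction: every participant's odds ratio is exp(beta_arm)
  expect_equal(cf$odds_ratio, rep(exp(b), n), tolerance = 1e-10)
  expect_true(all(cf$prob_intervention > 0 & cf$prob_intervention < 1))
  expect_true(all(cf$prob_intervention_low <= cf$prob_intervention))
  # planted covariate-dependent effect recovers the generative OR gradient
  withr::with_seed(8, {
    n2 <- 600
    d2 <- data.frame(arm = factor(rep(c("placebo", "LBP"), length.out = n2)),
                     x = rnorm(n2))
    eta <- -0.3 + 0.4 * (d2$arm == "LBP") + 0.5 * d2$x +
      1.1 * (d2$arm == "LBP") * d2$x
    d2$y <- rbinom(n2, 1, plogis(eta))
  })
  fit2 <- glm(y ~ arm * x, binomial(), data = d2)
  cf2 <- counterfactual_predictions(fit2, d2, "arm", "LBP", "placebo")
  true_or <- exp(0.4 + 1.1 * d2$x)
  expect_gt(cor(log(cf2$odds_ratio), log(true_or)), 0.99)
})

test_that("printed arm percentages reproduce under round-half-even", {
  tab <- benefit_ratio_table(data.frame(
    label = c("lc12", "lc24", "lacto12", "lacto24"),
    a = c(37, 39, 69, 65), n1 = c(123, 113, 123, 113),
    b = c(5, 4, 27, 17), n2 = c(56, 52, 56, 52)
  ))
  expect_equal(tab$pct_arm1, c(30, 35, 56, 58))
  expect_equal(tab$pct_arm2, c(9, 8, 48, 33))
})
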