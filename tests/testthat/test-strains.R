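strain_rows <- function(sample, fracs, lbp = names(fracs) == "CTV-05",
                        status = "ok") {
  data.frame(sample = sample, strain_id = names(fracs),
             fraction = as.numeric(fracs), is_lbp = lbp, status = status)
}

test_that("strain categories follow the threshold rules including boundaries", {
  rows <- rbind(
    strain_rows("s_high", c("CTV-05" = 0.95, "N1" = 0.05)),
    strain_rows("s_mid", c("CTV-05" = 0.50, "N1" = 0.50)),
    strain_rows("s_b90", c("CTV-05" = 0.90, "N1" = 0.10)),   # exactly 0.9 -> MIXED
    strain_rows("s_b10", c("CTV-05" = 0.10, "N1" = 0.90)),   # exactly 0.1 -> MIXED
    strain_rows("s_low", c("CTV-05" = 0.05, "N1" = 0.95)),
    strain_rows("s_fail", c("CTV-05" = 1), status = "failed"),
    strain_rows("s_ineligible", c("CTV-05" = 1))
  )
  lc <- c(s_high = 0.40, s_mid = 0.30, s_b90 = 0.20, s_b10 = 0.20,
          s_low = 0.60, s_fail = 0.50, s_ineligible = 0.03)
  out <- categorize_strains(rows, lc)
  got <- setNames(as.character(out$category), out$sample)
  expect_equal(got[["s_high"]], "HIGH_CTV05")
  expect_equal(got[["s_mid"]], "MIXED")
  expect_equal(got[["s_b90"]], "MIXED")
  expect_equal(got[["s_b10"]], "MIXED")
  expect_equal(got[["s_low"]], "LOW_CTV05")
  expect_equal(got[["s_fail"]], "UNDETERMINED")
  expect_equal(got[["s_ineligible"]], "LC_LT5")
  # eligibility boundary: exactly 5% is eligible
  out5 <- categorize_strains(strain_rows("s", c("CTV-05" = 1)), c(s = 0.05))
  expect_equal(as.character(out5$category), "HIGH_CTV05")
  # raising the floor only moves samples toward ineligibility
  out_hi <- categorize_strains(rows, lc, eligibility = 0.45)
  determined <- c("HIGH_CTV05", "MIXED", "LOW_CTV05")
  was_det <- got[out_hi$sample] %in% determined
  now_det <- as.character(out_hi$category) %in% determined
  expect_true(all(!now_det | was_det))
  # fractions must sum to one
  expect_error(
    categorize_strains(strain_rows("s", c("CTV-05" = 0.5)), c(s = 0.5)),
    "sum to 1"
  )
})

test_that("strain transitions pair consecutive visits and drop failed inference", {
  cats <- data.frame(
    participant = c("A", "A", "A", "B", "B", "B"),
    visit = c("wk4", "wk8", "wk12", "wk4", "wk8", "wk12"),
    category = c("HIGH_CTV05", "HIGH_CTV05", "LC_LT5",
                 "MIXED", "UNDETERMINED", "LOW_CTV05")
  )
  tt <- strain_transitions(cats)
  expect_equal(tt$counts["HIGH_CTV05", "HIGH_CTV05"], 1)
  expect_equal(tt$counts["HIGH_CTV05", "LC_LT5"], 1)
  # B's pairs both touch the failed visit and are excluded
  expect_equal(sum(tt$counts), 2)
  expect_warning(empty <- strain_transitions(cats[0, ]), "no usable")
  expect_equal(sum(empty$counts), 0)
})

test_that("native strain histogram deduplicates within participant", {
  rows <- rbind(
    cbind(strain_rows("A_wk4", c("CTV-05" = 1)), participant = "A"),
    cbind(strain_rows("B_wk4", c("CTV-05" = 0.5, "S14" = 0.5)), participant = "B"),
    cbind(strain_rows("B_wk8", c("CTV-05" = 0.3, "S14" = 0.7)), participant = "B"),
    cbind(strain_rows("C_wk4", c("CTV-05" = 0.2, "N1" = 0.3, "N2" = 0.3, "N3" = 0.2)),
          participant = "C"),
    cbind(strain_rows("D_wk4", c("CTV-05" = 0.95, "N1" = 0.05)), participant = "D")
  )
  h <- native_strain_histogram(rows)
  # A: no natives; D: native below the 10% detection floor
  expect_equal(unname(h), c(2, 1, 0, 1))
})

test_that("generator takeover probability is visible in transition proportions", {
  cfg <- cohort_config(n_participants = 400, native_takeover_prob = 0.35,
                       missing_visit_prob = 0, strain_fail_prob = 0, seed = 9)
  co <- generate_cohort(cfg)
  st <- attr(co$strains, "states")
  st$value <- st$state
  pairs <- lbptrial:::consecutive_pairs(
    st[c("participant", "visit", "value")],
    visits = c("postMTZ", "wk4", "wk8", "wk12", "wk24")
  )
  mixed <- pairs[pairs$from == "MIXED", ]
  expect_gt(nrow(mixed), 20)
  k <- sum(mixed$to == "LOW"); n <- nrow(mixed)
  band <- qbinom(c(0.005, 0.995), n, 0.35) / n
  expect_gte(k / n, band[1])
  expect_lte(k / n, band[2])
  # no takeover means mixed states never resolve to native dominance
  co0 <- generate_cohort(cohort_config(n_participants = 150, native_takeover_prob = 0,
                                       missing_visit_prob = 0, seed = 10))
  st0 <- attr(co0$strains, "states")
  st0$value <- st0$state
  p0 <- lbptrial:::consecutive_pairs(st0[c("participant", "visit", "value")],
                                     visits = c("postMTZ", "wk4", "wk8", "wk12", "wk24"))
  expect_equal(sum(p0$from %in% c("MIXED", "HIGH") & p0$to == "LOW"), 0)
  # placebo with zero false positives never contains the LBP strain
  plc <- co$strains$participant %in%
    co$truth$participants$participant[co$truth$participants$arm == "placebo"]
  expect_equal(sum(co$strains$is_lbp[plc]), 0)
})
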