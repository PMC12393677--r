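# Treatment-effect estimation: Wald benefit ratios, Wilson intervals,
# stratified heterogeneity, nested logistic deviance F tests with BH
# correction, and counterfactual predictions.

#' Benefit ratio from a 2x2 table (Wald method)
#'
#' The benefit ratio is the ratio of success proportions between the
#' intervention and comparator arms (a risk ratio where the event is a
#' favorable outcome). The confidence interval is the Wald interval on the
#' log-ratio scale,
#' \deqn{\exp(\log RR \pm z \sqrt{1/a - 1/n_1 + 1/b - 1/n_2}),}
#' and the two-sided p-value is the Pearson chi-square test of the 2x2
#' table (the p-value conventionally reported alongside Wald ratio
#' intervals in epidemiological software).
#'
#' @param a,n1 Successes and total in the intervention arm.
#' @param b,n2 Successes and total in the comparator arm.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with `ratio`, `ci_low`, `ci_high`, `p_value`, `method`.
#' @export
benefit_ratio <- function(a, n1, b, n2, conf = 0.95) {
  stopifnot(a >= 0, b >= 0, n1 >= 1, n2 >= 1, a <= n1, b <= n2)
  if (a == 0 && b == 0) stop("no successes in either arm: ratio undefined")
  if (b == 0) {
    warning("zero successes in comparator arm: infinite ratio")
    return(data.frame(ratio = Inf, ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, method = "wald"))
  }
  rr <- (a / n1) / (b / n2)
  if (a == 0) {
    warning("zero successes in intervention arm: degenerate lower bound")
    return(data.frame(ratio = 0, ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, method = "wald"))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  tab <- rbind(c(a, n1 - a), c(b, n2 - b))
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  data.frame(ratio = rr, ci_low = rr * exp(-z * se), ci_high = rr * exp(z * se),
             p_value = p, method = "wald")
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (n >= 1).
#' @param conf Confidence level.
#' @return Named numeric vector `c(estimate, lower, upper)`, contained in
#'   `[0, 1]`; the lower bound is exactly 0 when `k = 0` and the upper bound
#'   exactly 1 when `k = n`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(k >= 0, n >= 1, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  lo <- max(0, center - half)
  hi <- min(1, center + half)
  if (k == 0) lo <- 0
  if (k == n) hi <- 1
  c(estimate = p, lower = lo, upper = hi)
}

# Newcombe hybrid interval for a difference of proportions, built from the
# Wilson bounds of each arm (the standard "Wilson score method" for rate
# differences in small strata).
newcombe_diff_ci <- function(k1, n1, k2, n2, conf = 0.95) {
  w1 <- wilson_ci(k1, n1, conf)
  w2 <- wilson_ci(k2, n2, conf)
  d <- k1 / n1 - k2 / n2
  c(estimate = d,
    lower = d - sqrt((w1[["estimate"]] - w1[["lower"]])^2 + (w2[["upper"]] - w2[["estimate"]])^2),
    upper = d + sqrt((w1[["upper"]] - w1[["estimate"]])^2 + (w2[["estimate"]] - w2[["lower"]])^2))
}

#' Per-stratum success rates and between-arm rate differences
#'
#' Rates carry Wilson intervals; differences (intervention minus comparator)
#' carry Newcombe hybrid Wilson intervals. Strata with fewer than two
#' participants in either arm are excluded (with a message).
#'
#' @param outcome Logical/0-1 vector of successes.
#' @param arm Factor or character; the first level (or `ref`) is the
#'   comparator.
#' @param stratum Factor or character stratification variable.
#' @param ref Comparator arm label; default the first factor level.
#' @param conf Confidence level.
#' @param min_per_arm Minimum participants per arm for a stratum to be kept.
#' @return List with `rates` (per stratum x arm) and `differences`
#'   (per stratum), plus `excluded` strata labels.
#' @export
stratified_rates <- function(outcome, arm, stratum, ref = NULL, conf = 0.95,
                             min_per_arm = 2L) {
  arm <- factor(arm)
  if (nlevels(arm) != 2L) stop("exactly two arms required")
  if (!is.null(ref)) arm <- stats::relevel(arm, ref = ref)
  comparator <- levels(arm)[1]; intervention <- levels(arm)[2]
  stratum <- factor(stratum)
  outcome <- as.integer(outcome)
  keep <- character(); excl <- character()
  for (s in levels(stratum)) {
    ns <- table(arm[stratum == s])
    if (all(ns >= min_per_arm)) keep <- c(keep, s) else excl <- c(excl, s)
  }
  if (!length(keep)) stop("all strata excluded")
  if (length(excl)) {
    message("excluded ", length(excl), " stratum/strata with < ", min_per_arm,
            " participants per arm: ", paste(excl, collapse = ", "))
  }
  rates <- do.call(rbind, lapply(keep, function(s) {
    do.call(rbind, lapply(levels(arm), function(a) {
      i <- stratum == s & arm == a
      w <- wilson_ci(sum(outcome[i]), sum(i), conf)
      data.frame(stratum = s, arm = a, k = sum(outcome[i]), n = sum(i),
                 rate = w[["estimate"]], lower = w[["lower"]], upper = w[["upper"]])
    }))
  }))
  differences <- do.call(rbind, lapply(keep, function(s) {
    i1 <- stratum == s & arm == intervention
    i2 <- stratum == s & arm == comparator
    d <- newcombe_diff_ci(sum(outcome[i1]), sum(i1), sum(outcome[i2]), sum(i2), conf)
    data.frame(stratum = s, difference = d[["estimate"]],
               lower = d[["lower"]], upper = d[["upper"]])
  }))
  list(rates = rates, differences = differences, excluded = excl)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"` so the
#' correction used across the effect-heterogeneity family is explicit.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (step-up with monotonicity enforcement).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Heterogeneity-of-treatment-effect test (analysis of deviance F test)
#'
#' Fits the null logistic model (outcome ~ arm) and the full model
#' (outcome ~ arm * covariates) and compares them with an analysis-of-
#' deviance F test: F = (deviance difference / df difference) divided by the
#' full model's dispersion (Pearson chi-square over residual df), with the
#' p-value from the F distribution on (df difference, residual df of the
#' full model).
#'
#' @param outcome 0/1 outcome vector.
#' @param arm Two-level factor.
#' @param covariates Data frame of baseline covariates (categorical strata or
#'   quantitative topic proportions; agglomerate *Lactobacillus* topics to a
#'   total before calling, as sparse species-level topics impede
#'   convergence).
#' @return List with the two fitted models, `f_statistic`, `df`, `p_value`,
#'   and a `separation` flag. When perfect separation is detected the model
#'   p-value is reported as `NA`.
#' @export
heterogeneity_test <- function(outcome, arm, covariates) {
  outcome <- as.integer(outcome)
  stopifnot(all(outcome %in% 0:1))
  arm <- factor(arm)
  if (nlevels(arm) != 2L) stop("exactly two arms required")
  covariates <- as.data.frame(covariates)
  dat <- data.frame(.y = outcome, .arm = arm, covariates, check.names = TRUE)
  cov_terms <- paste(setdiff(names(dat), c(".y", ".arm")), collapse = " + ")
  null_fit <- stats::glm(.y ~ .arm, family = stats::binomial(), data = dat)
  full_fml <- stats::as.formula(paste0(".y ~ .arm * (", cov_terms, ")"))
  full_fit <- suppressWarnings(stats::glm(full_fml, family = stats::binomial(), data = dat))
  mu <- stats::fitted(full_fit)
  separation <- !full_fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8)
  df_diff <- null_fit$df.residual - full_fit$df.residual
  df_resid <- full_fit$df.residual
  if (df_diff <= 0 || df_resid <= 0) {
    return(list(null_model = null_fit, full_model = full_fit,
                f_statistic = NA_real_, df = c(df_diff, df_resid),
                p_value = NA_real_, separation = separation))
  }
  dispersion <- sum(stats::residuals(full_fit, type = "pearson")^2) / df_resid
  f_stat <- ((null_fit$deviance - full_fit$deviance) / df_diff) / dispersion
  p <- stats::pf(f_stat, df_diff, df_resid, lower.tail = FALSE)
  if (separation) {
    warning("possible separation in full model; model p-value reported as NA")
    p <- NA_real_
  }
  list(null_model = null_fit, full_model = full_fit, f_statistic = f_stat,
       df = c(df_diff, df_resid), p_value = p, separation = separation)
}

#' Counterfactual success probabilities and participant-level odds ratios
#'
#' Predicts, from a fitted logistic model, each participant's probability of
#' success had they received the intervention and had they received the
#' comparator, with delta-method intervals built on the linear-predictor
#' scale and mapped through the inverse logit. The participant-level odds
#' ratio is the ratio of the two predicted odds.
#'
#' @param fit A converged [stats::glm()] logistic fit whose formula includes
#'   an arm variable.
#' @param data Data frame of participants (the arm column is overwritten).
#' @param arm_var Name of the arm variable in the model frame.
#' @param intervention,comparator Arm labels.
#' @param conf Confidence level for the probability intervals.
#' @return Data frame with predicted probabilities (and intervals) under
#'   each arm and the per-participant odds ratio.
#' @export
counterfactual_predictions <- function(fit, data, arm_var,
                                       intervention, comparator, conf = 0.95) {
  if (!isTRUE(fit$converged)) stop("model did not converge")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  pred_under <- function(label) {
    nd <- data
    lv <- levels(factor(fit$model[[arm_var]] %||% fit$data[[arm_var]]))
    nd[[arm_var]] <- factor(label, levels = lv)
    pr <- stats::predict(fit, newdata = nd, type = "link", se.fit = TRUE)
    list(eta = pr$fit, lo = pr$fit - z * pr$se.fit, hi = pr$fit + z * pr$se.fit)
  }
  pi_ <- pred_under(intervention)
  pc <- pred_under(comparator)
  data.frame(
    prob_intervention = stats::plogis(pi_$eta),
    prob_intervention_low = stats::plogis(pi_$lo),
    prob_intervention_high = stats::plogis(pi_$hi),
    prob_comparator = stats::plogis(pc$eta),
    prob_comparator_low = stats::plogis(pc$lo),
    prob_comparator_high = stats::plogis(pc$hi),
    odds_ratio = exp(pi_$eta - pc$eta)
  )
}

#' Reproduce a benefit-ratio summary table from 2x2 counts
#'
#' @param rows Data frame with columns `label`, `a`, `n1`, `b`, `n2`.
#' @param conf Confidence level.
#' @return Data frame with per-row ratios, intervals, p-values, and printed
#'   percentages (round-half-even at integer precision).
#' @export
benefit_ratio_table <- function(rows, conf = 0.95) {
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    br <- benefit_ratio(r$a, r$n1, r$b, r$n2, conf)
    data.frame(label = r$label, a = r$a, n1 = r$n1, b = r$b, n2 = r$n2,
               pct_arm1 = round_percent(r$a / r$n1), pct_arm2 = round_percent(r$b / r$n2),
               br, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
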