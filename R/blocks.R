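# Assembly of thematic predictor blocks for the multiblock discriminant
# analysis of colonization categories.

#' Assemble predictor blocks for a trial phase
#'
#' Builds, for participants of the chosen arm observed at both the
#' predictor visit and the outcome visit, the thematic blocks used to
#' explain colonization categories: the previous-visit vaginal environment
#' (pH, log10 bacterial load, alpha diversity), demographics (age plus
#' one-hot race and education), and behavior (sexual activity, douching,
#' one-hot contraception). The response is the colonization category at the
#' outcome visit.
#'
#' @param cohort A `synthetic_cohort` (or compatible list).
#' @param phase `"initial"` (postMTZ predictors, week-4 outcome),
#'   `"continuation"` (week-4 predictors, week-12 outcome) or
#'   `"followup"` (week-12 predictors, week-24 outcome).
#' @param arm Arm to restrict to (default `"LBP"`, mirroring the trial's
#'   analysis of LBP recipients); `NULL` keeps both arms.
#' @param seed Seed for the sparse-level jitter of one-hot columns.
#' @return List with `blocks` (named list of numeric matrices), `response`
#'   (factor of colonization categories), and `participants`.
#' @export
phase_blocks <- function(cohort, phase = c("initial", "continuation", "followup"),
                         arm = "LBP", seed = 1L) {
  phase <- match.arg(phase)
  visits <- switch(phase,
    initial = c("postMTZ", "wk4"),
    continuation = c("wk4", "wk12"),
    followup = c("wk12", "wk24")
  )
  md <- cohort$metadata
  if (!is.null(arm)) md <- md[md$arm %in% arm, , drop = FALSE]
  prev <- md[md$visit == visits[1], , drop = FALSE]
  outc <- md[md$visit == visits[2], , drop = FALSE]
  ids <- intersect(prev$participant, outc$participant)
  if (length(ids) < 10L) stop("too few participants with both visits")
  prev <- prev[match(ids, prev$participant), ]
  outc <- outc[match(ids, outc$participant), ]
  prop <- relative_abundance(cohort$counts)
  response <- classify_colonization(prop, cohort$taxonomy)[
    match(outc$sample, rownames(prop))]
  adiv <- alpha_diversity(prop)[match(prev$sample, rownames(prop))]
  prev_env <- cbind(ph = prev$ph, log10_load = prev$log10_load,
                    alpha_diversity = unname(adiv))
  demo <- cohort$covariate_blocks$demographics
  demo <- demo[match(ids, demo$participant), ]
  demographics <- cbind(
    age = demo$age,
    one_hot_jitter(demo[c("race", "education")], seed = child_seed(seed, 1L))
  )
  beh <- cohort$covariate_blocks$behavior
  beh <- beh[match(ids, beh$participant), ]
  behavior <- cbind(
    sex_freq = beh$sex_freq, douching = beh$douching,
    one_hot_jitter(beh["condom_use"], seed = child_seed(seed, 2L))
  )
  rownames(prev_env) <- rownames(demographics) <- rownames(behavior) <- ids
  list(
    blocks = list(prev_env = prev_env, demographics = demographics,
                  behavior = behavior),
    response = droplevels(response),
    participants = ids
  )
}
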