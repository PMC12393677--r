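# Synthetic trial cohorts with the statistical structure the downstream
# stages assume: a 2:1-randomized longitudinal cohort with topic-structured
# compositions, post-antibiotic biomass collapse, an arm-dependent
# L. crispatus colonization effect, Markov-persistent community categories,
# cytokines contaminated by a latent swab-size factor and censored at
# limits of quantification, and LBP-strain/native-strain replacement
# dynamics.

#' Default species taxonomy of the synthetic cohort
#'
#' Five *Lactobacillus* species and sixteen BV-associated anaerobes.
#'
#' @return Data frame as from [make_taxonomy()].
#' @export
default_taxonomy <- function() {
  sp <- c(
    "Lactobacillus crispatus", "Lactobacillus iners", "Lactobacillus jensenii",
    "Lactobacillus gasseri", "Lactobacillus mulieris",
    "Gardnerella vaginalis", "Gardnerella swidsinskii", "Gardnerella leopoldii",
    "Ca. Lachnocurva vaginae", "Fannyhessea vaginae",
    "Prevotella bivia", "Prevotella amnii", "Prevotella timonensis",
    "Sneathia amnii", "Sneathia sanguinegens", "Megasphaera lornae",
    "Mobiluncus mulieris", "Dialister micraerophilus",
    "Aerococcus christensenii", "Peptoniphilus lacrimalis", "Finegoldia magna"
  )
  gen <- vapply(strsplit(sp, " "), `[[`, character(1), 1)
  gen[sp == "Ca. Lachnocurva vaginae"] <- "Lachnocurva"
  make_taxonomy(sp, gen)
}

#' Default non-Lactobacillus topic profiles
#'
#' Four subcommunities mirroring the common BV-associated assemblages: a
#' *G. vaginalis*-dominated topic, a *Ca.* Lachnocurva vaginae (BVAB1)
#' topic, a *G. swidsinskii/leopoldii* topic, and a *Prevotella* topic.
#'
#' @param taxonomy Taxonomy table; profiles cover its non-*Lactobacillus*
#'   species.
#' @return K x V matrix of probability rows.
#' @export
default_topic_profiles <- function(taxonomy = default_taxonomy()) {
  nl <- taxonomy$species[!taxonomy$is_lacto]
  prof <- matrix(0.002, nrow = 4, ncol = length(nl),
                 dimnames = list(
                   c("T1 G. vaginalis", "T2 Ca. L. vaginae",
                     "T3 G. swidsinskii/leopoldii", "T4 Prevotella"),
                   nl))
  set_p <- function(topic, ...) {
    v <- c(...)
    prof[topic, names(v)] <<- v
  }
  set_p("T1 G. vaginalis",
        "Gardnerella vaginalis" = 0.50, "Fannyhessea vaginae" = 0.15,
        "Prevotella bivia" = 0.08, "Dialister micraerophilus" = 0.07,
        "Aerococcus christensenii" = 0.05, "Peptoniphilus lacrimalis" = 0.05,
        "Finegoldia magna" = 0.04, "Mobiluncus mulieris" = 0.03)
  set_p("T2 Ca. L. vaginae",
        "Ca. Lachnocurva vaginae" = 0.55, "Sneathia amnii" = 0.13,
        "Sneathia sanguinegens" = 0.08, "Megasphaera lornae" = 0.11,
        "Mobiluncus mulieris" = 0.06)
  set_p("T3 G. swidsinskii/leopoldii",
        "Gardnerella swidsinskii" = 0.36, "Gardnerella leopoldii" = 0.30,
        "Fannyhessea vaginae" = 0.10, "Megasphaera lornae" = 0.06,
        "Gardnerella vaginalis" = 0.08)
  set_p("T4 Prevotella",
        "Prevotella bivia" = 0.32, "Prevotella amnii" = 0.26,
        "Prevotella timonensis" = 0.20, "Dialister micraerophilus" = 0.06,
        "Peptoniphilus lacrimalis" = 0.05)
  prof / rowSums(prof)
}

#' Default per-analyte cytokine effects of Lactobacillus proportion
#'
#' Signed effects (log10 units per unit *Lactobacillus* proportion) mirroring
#' the usual biology: interferon-induced chemokines (MIG, IP-10, ITAC)
#' covary positively with *Lactobacillus*, pro-inflammatory cytokines
#' (IL-1a, IL-1b, TNF-a) negatively.
#'
#' @return Named numeric vector over 18 analytes.
#' @export
default_cytokine_effects <- function() {
  c("IP-10" = 0.5, "MIG" = 0.5, "ITAC" = 0.4,
    "IL-1a" = -0.5, "IL-1b" = -0.6, "TNF-a" = -0.45,
    "IL-8" = -0.3, "IL-6" = 0, "MIP-1a" = -0.2, "MIP-1b" = -0.2,
    "MIP-3a" = -0.25, "IFN-g" = 0.15, "IL-17" = 0.1, "IL-10" = 0,
    "IL-12p70" = 0, "IL-23" = 0.1, "IL-21" = 0, "IL-13" = 0)
}

#' Configuration for a synthetic trial cohort
#'
#' @param n_participants Number of participants (> 0).
#' @param arm_ratio Integer pair, LBP:placebo allocation (default 2:1).
#' @param visits Ordered visit labels (default the six scheduled visits).
#' @param K_topics Number of non-*Lactobacillus* topics.
#' @param topic_species_profiles K x V probability matrix (defaults to
#'   [default_topic_profiles()]).
#' @param lbp_colonization_prob Probability an LBP-arm participant is
#'   *L. crispatus*-dominant at week 4 (default 0.30).
#' @param placebo_colonization_prob Same for placebo (default 0.09).
#' @param persistence_prob Markov self-transition probability of the
#'   colonization category after week 4 (default 0.8).
#' @param native_takeover_prob Per-visit probability that a mixed-strain
#'   state resolves to native dominance (default 0.35).
#' @param size_factor_sd SD of the latent log10-scale swab-size factor
#'   (default 0.5).
#' @param cytokine_effects Named per-analyte effects (see
#'   [default_cytokine_effects()]).
#' @param cytokine_noise_sd Residual SD of log10 concentrations.
#' @param missing_visit_prob Probability a scheduled visit is missing
#'   completely at random (default 0.1).
#' @param depth_median,depth_sdlog Log-normal sequencing depth: median about
#'   31,000 analyzable reads per sample.
#' @param fixed_depth Optional constant depth overriding the log-normal.
#' @param dirichlet_conc Within-category Dirichlet concentration multiplier
#'   on the topic mix (default 50).
#' @param env_effect Log-odds shift of week-4 colonization per unit of the
#'   latent post-antibiotic receptivity factor (default 1.5).
#' @param placebo_fp_rate Probability a placebo strain profile contains the
#'   LBP strain (default 0).
#' @param strain_fail_prob Probability strain inference fails technically.
#' @param seed Master seed; all child generators derive from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 180L,
                          arm_ratio = c(2L, 1L),
                          visits = visit_levels(),
                          K_topics = 4L,
                          topic_species_profiles = default_topic_profiles(),
                          lbp_colonization_prob = 0.30,
                          placebo_colonization_prob = 0.09,
                          persistence_prob = 0.8,
                          native_takeover_prob = 0.35,
                          size_factor_sd = 0.5,
                          cytokine_effects = default_cytokine_effects(),
                          cytokine_noise_sd = 0.15,
                          missing_visit_prob = 0.1,
                          depth_median = 31000,
                          depth_sdlog = 0.35,
                          fixed_depth = NULL,
                          dirichlet_conc = 50,
                          env_effect = 1.5,
                          placebo_fp_rate = 0,
                          strain_fail_prob = 0.05,
                          seed = 1L) {
  if (n_participants <= 0) stop("zero participants")
  if (length(arm_ratio) != 2L || any(arm_ratio != round(arm_ratio)) || any(arm_ratio < 1)) {
    stop("non-integer arm ratio")
  }
  probs <- c(lbp_colonization_prob, placebo_colonization_prob,
             persistence_prob, native_takeover_prob, missing_visit_prob,
             placebo_fp_rate, strain_fail_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (anyDuplicated(visits)) stop("visits must be strictly ordered and unique")
  topic_species_profiles <- as.matrix(topic_species_profiles)
  if (nrow(topic_species_profiles) != K_topics) {
    stop("topic profiles must have K_topics rows")
  }
  if (any(topic_species_profiles < 0) ||
      any(abs(rowSums(topic_species_profiles) - 1) > 1e-8)) {
    stop("topic profiles must be nonnegative and sum to 1")
  }
  rm(probs)
  structure(as.list(environment()), class = "cohort_config")
}

# Category mean topic-mass by colonization category (Lactobacillus part) and
# total non-Lactobacillus mass.
category_lacto_means <- function() {
  list(
    LC_DOM = c(crisp = 0.75, iners = 0.04, jensenii = 0.02, other = 0.02, nonlacto = 0.17),
    OTHER_LACTO_DOM = c(crisp = 0.03, iners = 0.68, jensenii = 0.04, other = 0.03, nonlacto = 0.22),
    NON_LACTO_DOM = c(crisp = 0.01, iners = 0.09, jensenii = 0.01, other = 0.01, nonlacto = 0.88)
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Arm-specific week-4 base category distribution (LC, OTHER_LACTO, NON_LACTO).
arm_base_distribution <- function(p_lc, arm) {
  other_share <- if (arm == "LBP") 0.37 else 0.43
  c(LC_DOM = p_lc,
    OTHER_LACTO_DOM = (1 - p_lc) * other_share,
    NON_LACTO_DOM = (1 - p_lc) * (1 - other_share))
}

#' Generate a synthetic trial cohort
#'
#' Draws, per participant, an arm (2:1 block randomization), a latent
#' post-antibiotic receptivity factor, and a colonization-category sequence
#' (screening mostly non-*Lactobacillus*, randomization mostly *L. iners*,
#' arm- and receptivity-dependent week-4 *L. crispatus*-dominance, then a
#' Markov chain that stays with `persistence_prob` and otherwise jumps to
#' another category in proportion to the arm's base rates). Per observed
#' sample it draws topic weights from a category-conditioned Dirichlet,
#' species counts from a multinomial over the mixed topic profiles at a
#' log-normal depth, plus pH, bacterial load (collapsed and wide after the
#' antibiotic, high and narrow later), a swab-size factor, cytokines and
#' strain profiles.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: `counts`, `taxonomy`,
#'   `metadata`, `cytokines`, `strains`, `covariate_blocks`, `truth`,
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  tax <- default_taxonomy()
  visits <- config$visits
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))

  base <- with_seed(child_seed(config$seed, "cohort"), {
    n_lbp <- round(n * config$arm_ratio[1] / sum(config$arm_ratio))
    arm <- sample(c(rep("LBP", n_lbp), rep("placebo", n - n_lbp)))
    receptivity <- stats::rnorm(n)
    list(arm = arm, receptivity = receptivity)
  })

  cats <- with_seed(child_seed(config$seed, "categories"), {
    lev <- c("LC_DOM", "OTHER_LACTO_DOM", "NON_LACTO_DOM")
    out <- matrix(NA_character_, n, length(visits), dimnames = list(ids, visits))
    for (i in seq_len(n)) {
      p_arm <- if (base$arm[i] == "LBP") config$lbp_colonization_prob else
        config$placebo_colonization_prob
      # logit intercept calibrated (logistic ~ probit/1.7) so the configured
      # probability is the marginal week-4 rate after integrating out the
      # latent receptivity factor
      infl <- sqrt(1 + (config$env_effect / 1.7)^2)
      p_lc4 <- stats::plogis(stats::qlogis(max(p_arm, 1e-6)) * infl +
                               config$env_effect * base$receptivity[i])
      q4 <- arm_base_distribution(p_lc4, base$arm[i])
      q_jump <- arm_base_distribution(p_arm, base$arm[i])
      seqc <- character(length(visits))
      for (j in seq_along(visits)) {
        v <- visits[j]
        seqc[j] <- if (v == "preMTZ") {
          sample(lev, 1, prob = c(0.0, 0.05, 0.95))
        } else if (v == "postMTZ") {
          sample(lev, 1, prob = c(0.02, 0.63, 0.35))
        } else if (v == "wk4" || j == 3L) {
          sample(lev, 1, prob = q4)
        } else {
          prev <- seqc[j - 1L]
          if (stats::runif(1) < config$persistence_prob) prev else {
            others <- setdiff(lev, prev)
            w <- q_jump[others]
            sample(others, 1, prob = w / sum(w))
          }
        }
      }
      out[i, ] <- seqc
    }
    out
  })

  observed <- with_seed(child_seed(config$seed, "missing"), {
    matrix(stats::runif(n * length(visits)) >= config$missing_visit_prob,
           n, length(visits), dimnames = list(ids, visits))
  })

  lacto_means <- category_lacto_means()
  beta_nl <- config$topic_species_profiles
  nl_species <- colnames(beta_nl)
  lacto_species <- tax$species[tax$is_lacto]
  other_lacto_comp <- c("Lactobacillus gasseri" = 0.6, "Lactobacillus mulieris" = 0.4)

  samp <- with_seed(child_seed(config$seed, "counts"), {
    rows <- list(); meta <- list(); truth_s <- list()
    for (i in seq_len(n)) for (j in seq_along(visits)) {
      if (!observed[i, j]) next
      v <- visits[j]; cat_ <- cats[i, j]
      sid <- paste(ids[i], v, sep = "_")
      m <- lacto_means[[cat_]]
      g <- rdirichlet1(rep(0.4, config$K_topics))
      m_full <- c(m[c("crisp", "iners", "jensenii", "other")], m[["nonlacto"]] * g)
      m_full <- pmax(m_full, 0.004); m_full <- m_full / sum(m_full)
      w <- rdirichlet1(config$dirichlet_conc * m_full)
      sp_prob <- stats::setNames(numeric(nrow(tax)), tax$species)
      sp_prob["Lactobacillus crispatus"] <- w[1]
      sp_prob["Lactobacillus iners"] <- w[2]
      sp_prob["Lactobacillus jensenii"] <- w[3]
      sp_prob[names(other_lacto_comp)] <- w[4] * other_lacto_comp
      sp_prob[nl_species] <- sp_prob[nl_species] + colSums(w[4 + seq_len(config$K_topics)] * beta_nl)
      depth <- if (!is.null(config$fixed_depth)) config$fixed_depth else
        max(1000L, round(stats::rlnorm(1, log(config$depth_median), config$depth_sdlog)))
      counts <- as.integer(stats::rmultinom(1, depth, sp_prob))
      ph <- switch(cat_, LC_DOM = 4.0, OTHER_LACTO_DOM = 4.4, NON_LACTO_DOM = 5.2) +
        stats::rnorm(1, 0, 0.25)
      if (v == "postMTZ") ph <- ph - 0.3 * base$receptivity[i]
      load <- if (v == "postMTZ") {
        stats::rnorm(1, 5.0, 1.2) - 0.6 * base$receptivity[i]
      } else if (v == "preMTZ") stats::rnorm(1, 7.2, 0.5) else stats::rnorm(1, 7.0, 0.5)
      bv <- stats::runif(1) < if (cat_ == "NON_LACTO_DOM") 0.8 else 0.08
      size <- stats::rnorm(1, 0, config$size_factor_sd)
      rows[[sid]] <- counts
      meta[[sid]] <- data.frame(
        sample = sid, participant = ids[i], arm = base$arm[i], visit = v,
        bv = bv, ph = ph, log10_load = load, stringsAsFactors = FALSE
      )
      truth_s[[sid]] <- data.frame(
        sample = sid, participant = ids[i], visit = v, category = cat_,
        lacto_prop = sum(sp_prob[lacto_species]),
        lc_prop = sp_prob[["Lactobacillus crispatus"]],
        size_factor = size, depth = depth, stringsAsFactors = FALSE
      )
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- tax$species
    list(counts = counts,
         metadata = do.call(rbind, meta),
         truth_samples = do.call(rbind, truth_s))
  })
  rownames(samp$metadata) <- rownames(samp$truth_samples) <- NULL

  covariates <- with_seed(child_seed(config$seed, "covariates"), {
    demographics <- data.frame(
      participant = ids,
      age = round(stats::rnorm(n, 30, 6)),
      race = sample(c("A", "B", "C", "D"), n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
      education = sample(c("primary", "secondary", "higher"), n, TRUE),
      stringsAsFactors = FALSE
    )
    behavior <- data.frame(
      participant = ids,
      sex_freq = stats::rpois(n, 4),
      douching = stats::rbinom(n, 1, 0.15),
      condom_use = sample(c("never", "sometimes", "always"), n, TRUE),
      stringsAsFactors = FALSE
    )
    list(demographics = demographics, behavior = behavior)
  })

  truth <- list(
    participants = data.frame(
      participant = ids, arm = base$arm, receptivity = base$receptivity,
      stringsAsFactors = FALSE
    ),
    categories = cats,
    observed = observed,
    samples = samp$truth_samples,
    topic_profiles = beta_nl
  )

  cyto <- generate_cytokines(truth, config)
  strains <- generate_strains(truth, config)
  truth$native_strain_counts <- attr(strains, "native_strain_counts")
  truth$strain_states <- attr(strains, "states")

  structure(list(
    counts = samp$counts, taxonomy = tax, metadata = samp$metadata,
    cytokines = cyto, strains = strains, covariate_blocks = covariates,
    truth = truth, config = config
  ), class = "synthetic_cohort")
}

#' Generate raw cytokine measurements from cohort truth
#'
#' log10 concentration = analyte mean + swab-size factor + effect x
#' (*Lactobacillus* proportion - 1/2) + noise. Values outside the
#' quantification limits are reported at the limit with the matching
#' censoring flag.
#'
#' @param truth Truth record of a [generate_cohort()] run (needs per-sample
#'   size factors and *Lactobacillus* proportions).
#' @param config The matching [cohort_config()].
#' @return Long data frame: `sample`, `analyte`, `concentration`, `flag`,
#'   `lloq`, `uloq`, plus the latent `true_log10`.
#' @export
generate_cytokines <- function(truth, config) {
  eff <- config$cytokine_effects
  analytes <- names(eff)
  means <- stats::setNames(seq(1.2, 3.2, length.out = length(analytes)), analytes)
  lloq_log <- means - 2.2
  uloq_log <- means + 2.2
  # two sparse analytes sit near their lower limit: exercised by the
  # >= 60% below-LLOQ exclusion rule
  heavy <- intersect(c("IL-21", "IL-13"), analytes)
  lloq_log[heavy] <- means[heavy] + 0.4
  ts <- truth$samples
  with_seed(child_seed(config$seed, "cytokines"), {
    out <- do.call(rbind, lapply(analytes, function(a) {
      lg <- means[[a]] + ts$size_factor +
        eff[[a]] * (ts$lacto_prop - 0.5) +
        stats::rnorm(nrow(ts), 0, config$cytokine_noise_sd)
      conc <- 10^lg
      flag <- ifelse(lg < lloq_log[[a]], "below_lloq",
                     ifelse(lg > uloq_log[[a]], "above_uloq", "in_range"))
      conc[flag == "below_lloq"] <- 10^lloq_log[[a]]
      conc[flag == "above_uloq"] <- 10^uloq_log[[a]]
      data.frame(sample = ts$sample, analyte = a, concentration = conc,
                 flag = flag, lloq = 10^lloq_log[[a]], uloq = 10^uloq_log[[a]],
                 true_log10 = lg, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate strain-proportion tables from cohort truth
#'
#' LBP-arm samples with >= 5% *L. crispatus* receive CTV-05/native strain
#' mixtures that evolve across visits: high-CTV-05 states occasionally
#' admit natives (becoming mixed), mixed states resolve to native dominance
#' with `native_takeover_prob` per visit (and very rarely back to high
#' CTV-05), and native-dominant states are absorbing. Placebo samples carry
#' native strains only, up to a configurable false-positive rate.
#'
#' @param truth Truth record with per-sample *L. crispatus* proportions.
#' @param config The matching [cohort_config()].
#' @return Long data frame: `sample`, `participant`, `visit`, `strain_id`,
#'   `fraction`, `is_lbp`, `status`; attributes `states` (latent state per
#'   eligible sample) and `native_strain_counts`.
#' @export
generate_strains <- function(truth, config) {
  ts <- truth$samples
  parts <- truth$participants
  post_visits <- setdiff(config$visits, "preMTZ")
  with_seed(child_seed(config$seed, "strains"), {
    n_native <- stats::setNames(
      sample(0:3, nrow(parts), TRUE, prob = c(0.2, 0.5, 0.2, 0.1)),
      parts$participant
    )
    # placebo participants always have at least one native strain available
    n_native[parts$arm == "placebo" & n_native == 0] <- 1L
    rows <- list(); states <- list()
    for (i in seq_len(nrow(parts))) {
      pid <- parts$participant[i]
      arm <- parts$arm[i]
      natives <- if (n_native[[pid]] > 0) paste0(pid, "_N", seq_len(n_native[[pid]])) else character(0)
      state <- NA_character_
      for (v in post_visits) {
        sid <- paste(pid, v, sep = "_")
        row <- ts[ts$sample == sid, ]
        if (!nrow(row)) next
        eligible <- row$lc_prop >= 0.05
        if (!eligible) { state <- NA_character_; next }
        if (arm == "LBP") {
          state <- if (is.na(state)) {
            if (length(natives) && stats::runif(1) < 0.2) "MIXED" else "HIGH"
          } else {
            u <- stats::runif(1)
            switch(state,
              HIGH = if (length(natives) && u < 0.10) "MIXED" else "HIGH",
              MIXED = if (u < config$native_takeover_prob) "LOW"
                      else if (u < config$native_takeover_prob + 0.05) "HIGH"
                      else "MIXED",
              LOW = "LOW")
          }
        } else {
          state <- if (stats::runif(1) < config$placebo_fp_rate) "MIXED" else "LOW"
        }
        failed <- stats::runif(1) < config$strain_fail_prob
        ctv_frac <- switch(state,
          HIGH = stats::runif(1, 0.92, 1.0),
          MIXED = stats::runif(1, 0.15, 0.85),
          LOW = if (arm == "LBP") stats::runif(1, 0, 0.08) else 0)
        if (arm == "LBP" && !length(natives)) ctv_frac <- 1
        frac <- c(`CTV-05` = ctv_frac)
        if (length(natives) && ctv_frac < 1) {
          nat <- rdirichlet1(rep(2, length(natives))) * (1 - ctv_frac)
          frac <- c(frac, stats::setNames(nat, natives))
        }
        frac <- frac[frac > 1e-9]
        rows[[sid]] <- data.frame(
          sample = sid, participant = pid, visit = v,
          strain_id = names(frac), fraction = as.numeric(frac),
          is_lbp = names(frac) == "CTV-05",
          status = if (failed) "failed" else "ok",
          stringsAsFactors = FALSE
        )
        states[[sid]] <- data.frame(sample = sid, participant = pid, visit = v,
                                    state = state, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows) %||% data.frame(
      sample = character(), participant = character(), visit = character(),
      strain_id = character(), fraction = numeric(), is_lbp = logical(),
      status = character()
    )
    rownames(out) <- NULL
    attr(out, "states") <- do.call(rbind, states)
    attr(out, "native_strain_counts") <- n_native
    out
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Counts as TSV (samples x species), metadata/cytokines/strains as tidy
#' CSV, truth and configuration as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    cytokines = file.path(dir, "cytokines.csv"),
    strains = file.path(dir, "strains.csv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json")
  )
  cts <- data.frame(sample = rownames(cohort$counts), cohort$counts,
                    check.names = FALSE)
  utils::write.table(cts, paths["counts"], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$taxonomy, paths["taxonomy"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$metadata, paths["metadata"], row.names = FALSE)
  utils::write.csv(cohort$cytokines, paths["cytokines"], row.names = FALSE)
  utils::write.csv(cohort$strains, paths["strains"], row.names = FALSE)
  truth <- cohort$truth
  truth$categories <- as.data.frame(truth$categories)
  truth$observed <- as.data.frame(truth$observed)
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns", digits = NA)
  cfg <- cohort$config
  cfg$topic_species_profiles <- as.data.frame(cfg$topic_species_profiles)
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
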