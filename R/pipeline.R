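# Orchestration: schema validation of the input tables and an end-to-end
# pipeline run over a synthetic (or user-supplied) cohort.

#' Validate the schemas of the pipeline input tables
#'
#' Checks the count table, metadata, cytokine panel and strain table for the
#' columns and value ranges the pipeline assumes, and lists orphaned samples
#' (present in one table but absent from the metadata). Problems are
#' reported, not raised.
#'
#' @param counts Samples x species count matrix or data frame.
#' @param metadata Data frame with `sample`, `participant`, `arm`, `visit`.
#' @param cytokines Long cytokine table (see [impute_out_of_range()]).
#' @param strains Long strain table (see [categorize_strains()]).
#' @return List with `violations` (character vector) and `tallies`.
#' @export
validate_inputs <- function(counts = NULL, metadata = NULL,
                            cytokines = NULL, strains = NULL) {
  v <- character()
  tallies <- list()
  md_samples <- NULL
  if (!is.null(metadata)) {
    need <- c("sample", "participant", "arm", "visit")
    miss <- setdiff(need, names(metadata))
    if (length(miss)) v <- c(v, paste("metadata missing columns:", paste(miss, collapse = ", ")))
    if (!length(miss)) {
      md_samples <- metadata$sample
      if (anyDuplicated(metadata[c("participant", "visit")])) {
        v <- c(v, "duplicate (participant, visit) rows in metadata")
      }
    }
    tallies$metadata_rows <- nrow(metadata)
  }
  if (!is.null(counts)) {
    m <- as.matrix(counts)
    if (any(m < 0)) v <- c(v, "negative entries in count table")
    if (any(m != round(m))) v <- c(v, "non-integer entries in count table")
    if (!is.null(md_samples)) {
      orphans <- setdiff(rownames(m), md_samples)
      if (length(orphans)) {
        v <- c(v, paste("count samples missing from metadata:", paste(orphans, collapse = ", ")))
      }
    }
    tallies$count_samples <- nrow(m); tallies$count_species <- ncol(m)
  }
  if (!is.null(cytokines)) {
    need <- c("sample", "analyte", "concentration", "flag", "lloq", "uloq")
    miss <- setdiff(need, names(cytokines))
    if (length(miss)) v <- c(v, paste("cytokines missing columns:", paste(miss, collapse = ", ")))
    if (!length(miss) && any(cytokines$lloq >= cytokines$uloq, na.rm = TRUE)) {
      v <- c(v, "inverted LOQ bounds in cytokine table")
    }
    tallies$cytokine_rows <- nrow(cytokines)
  }
  if (!is.null(strains)) {
    need <- c("sample", "strain_id", "fraction", "is_lbp")
    miss <- setdiff(need, names(strains))
    if (length(miss)) v <- c(v, paste("strains missing columns:", paste(miss, collapse = ", ")))
    tallies$strain_rows <- nrow(strains)
  }
  list(violations = v, tallies = tallies)
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes composition classification, the constrained topic model,
#' cytokine preprocessing (with or without the size-effect adjustment),
#' the microbiota-immune RV association, arm-balance PERMANOVA at a
#' baseline visit, benefit ratios at the primary endpoints, strain
#' categorization and transitions, and writes per-stage CSV/JSON outputs
#' plus a run manifest.
#'
#' @param cohort A `synthetic_cohort` (or a list with the same elements
#'   built from user data).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param K Number of non-*Lactobacillus* topics (default 4; set to `NULL`
#'   to select K by topic alignment over `k_grid`).
#' @param k_grid Resolution grid used when `K` is `NULL`.
#' @param adjust_cytokines Apply PC1 subtraction (`TRUE`, default) or run
#'   the unadjusted sensitivity mode.
#' @param n_perm Permutations for RV and PERMANOVA.
#' @param seed Integer seed.
#' @return List of per-stage results (invisible paths in `files` when
#'   `out_dir` is given).
#' @export
run_pipeline <- function(cohort, out_dir = NULL, K = 4L, k_grid = 2:6,
                         adjust_cytokines = TRUE, n_perm = 999L, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop("stage '", name, "' failed: ",
                                            conditionMessage(e), call. = FALSE))
  }
  prop <- stage("composition", relative_abundance(cohort$counts))
  categories <- stage("composition", classify_colonization(prop, cohort$taxonomy))
  cat_df <- data.frame(
    sample = rownames(prop),
    participant = cohort$metadata$participant[match(rownames(prop), cohort$metadata$sample)],
    visit = cohort$metadata$visit[match(rownames(prop), cohort$metadata$sample)],
    category = categories, stringsAsFactors = FALSE
  )
  transitions <- stage("composition", transition_table(cat_df))

  topic_fit <- stage("topics", {
    if (is.null(K)) {
      is_lacto <- cohort$taxonomy$is_lacto[match(colnames(cohort$counts),
                                                 cohort$taxonomy$species)]
      grid <- fit_topic_grid(cohort$counts[, !is_lacto, drop = FALSE],
                             k_grid = k_grid, seed = seed)
      K <- select_K(grid$alignment)
    }
    fit_topic_model(cohort$counts, cohort$taxonomy, K = K, seed = seed)
  })

  cyto <- stage("cytokines", preprocess_cytokines(cohort$cytokines,
                                                  adjust = adjust_cytokines))

  shared <- intersect(rownames(topic_fit$topic_proportions), rownames(cyto$matrix))
  rv <- stage("assoc", rv_permutation_test(
    topic_fit$topic_proportions[shared, , drop = FALSE],
    cyto$matrix[shared, , drop = FALSE],
    n_perm = n_perm, seed = child_seed(seed, 11L)
  ))

  balance <- stage("assoc", {
    base <- cohort$metadata$visit == "preMTZ"
    ids <- cohort$metadata$sample[base]
    ids <- intersect(ids, rownames(prop))
    d <- vegan::vegdist(prop[ids, , drop = FALSE], method = "bray")
    permanova(d, cohort$metadata$arm[match(ids, cohort$metadata$sample)],
              n_perm = n_perm, seed = child_seed(seed, 13L))
  })

  effects <- stage("effects", {
    md <- cohort$metadata
    per_endpoint <- function(visit, kind) {
      i <- md$visit == visit & md$sample %in% rownames(prop)
      cat_i <- categories[match(md$sample[i], rownames(prop))]
      succ <- if (kind == "lc") cat_i == "LC_DOM" else cat_i != "NON_LACTO_DOM"
      arm <- md$arm[i]
      benefit_ratio(sum(succ[arm == "LBP"]), sum(arm == "LBP"),
                    sum(succ[arm == "placebo"]), sum(arm == "placebo"))
    }
    data.frame(
      endpoint = c("lc_wk12", "lc_wk24", "lacto_wk12", "lacto_wk24"),
      rbind(per_endpoint("wk12", "lc"), per_endpoint("wk24", "lc"),
            per_endpoint("wk12", "lacto"), per_endpoint("wk24", "lacto"))
    )
  })

  strain_res <- stage("strains", {
    lc <- prop[, "Lactobacillus crispatus"]
    scat <- categorize_strains(
      cohort$strains[cohort$strains$participant %in%
                       cohort$metadata$participant[cohort$metadata$arm == "LBP"], ,
                     drop = FALSE],
      lc[cohort$metadata$arm[match(names(lc), cohort$metadata$sample)] == "LBP"]
    )
    scat$participant <- cohort$metadata$participant[match(scat$sample, cohort$metadata$sample)]
    scat$visit <- cohort$metadata$visit[match(scat$sample, cohort$metadata$sample)]
    list(categories = scat, transitions = strain_transitions(scat))
  })

  result <- list(
    proportions = prop, categories = cat_df, transitions = transitions,
    topics = topic_fit, cytokines = cyto, rv = rv, balance = balance,
    effects = effects, strains = strain_res,
    manifest = list(K = K, adjusted = adjust_cytokines, n_perm = n_perm,
                    seed = seed, package_version = as.character(utils::packageVersion("lbptrial")))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cat_df, file.path(out_dir, "categories.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(transitions$counts),
                     file.path(out_dir, "transitions.csv"))
    utils::write.csv(effects, file.path(out_dir, "benefit_ratios.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(strain_res$transitions$counts),
                     file.path(out_dir, "strain_transitions.csv"))
    adj_label <- if (adjust_cytokines) "adjusted" else "unadjusted"
    utils::write.csv(data.frame(sample = rownames(cyto$matrix), cyto$matrix,
                                check.names = FALSE),
                     file.path(out_dir, paste0("cytokines_", adj_label, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(manifest = result$manifest,
           rv = list(rv = rv$rv, p_value = rv$p_value),
           permanova = list(f = balance$f_statistic, p = balance$p_value),
           variance_explained = cyto$variance_explained),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
    result$files <- list.files(out_dir, full.names = TRUE)
  }
  result
}
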