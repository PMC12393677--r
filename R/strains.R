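# Strain-category classification and LBP-strain versus native-strain
# transition dynamics from strain-proportion tables.
#
# Strain inference is only attempted on samples with at least 5% overall
# *L. crispatus* relative abundance; within eligible samples, categories are
# keyed to the probiotic (LBP) strain's fractional abundance: > 90% High,
# 10-90% Mixed (both boundaries inclusive to Mixed), < 10% Low.

strain_category_levels <- function() {
  c("HIGH_CTV05", "MIXED", "LOW_CTV05", "UNDETERMINED", "LC_LT5")
}

#' Categorize samples by LBP-strain fractional abundance
#'
#' @param strains Long data frame with columns `sample`, `strain_id`,
#'   `fraction`, `is_lbp`, and optionally `status` (one of `"ok"`,
#'   `"failed"`, `"not_attempted"`; default `"ok"`).
#' @param lc_abundance Named numeric vector: total *L. crispatus* relative
#'   abundance per sample (names = sample IDs).
#' @param eligibility Minimum *L. crispatus* relative abundance for strain
#'   inference (default 0.05).
#' @param high,low Category thresholds on the LBP-strain fraction
#'   (default 0.9 and 0.1; values exactly at a threshold are `MIXED`).
#' @return Data frame with one row per sample: `sample`, `lc_abundance`,
#'   `lbp_fraction`, `category`. Samples below the eligibility floor are
#'   `LC_LT5`; eligible samples with failed inference are `UNDETERMINED`.
#' @export
categorize_strains <- function(strains, lc_abundance, eligibility = 0.05,
                               high = 0.9, low = 0.1) {
  stopifnot(all(c("sample", "strain_id", "fraction", "is_lbp") %in% names(strains)))
  if (is.null(strains$status)) strains$status <- "ok"
  samples <- names(lc_abundance)
  if (is.null(samples)) stop("lc_abundance must be a named vector")
  sp <- split(strains, strains$sample)
  out <- do.call(rbind, lapply(samples, function(s) {
    lc <- lc_abundance[[s]]
    rows <- sp[[s]]
    status <- if (!is.null(rows)) rows$status[1] else "not_attempted"
    if (lc < eligibility) {
      return(data.frame(sample = s, lc_abundance = lc, lbp_fraction = NA_real_,
                        category = "LC_LT5", stringsAsFactors = FALSE))
    }
    if (is.null(rows) || status != "ok") {
      return(data.frame(sample = s, lc_abundance = lc, lbp_fraction = NA_real_,
                        category = "UNDETERMINED", stringsAsFactors = FALSE))
    }
    if (abs(sum(rows$fraction) - 1) > 1e-6) {
      stop("strain fractions do not sum to 1 for sample ", s)
    }
    f <- sum(rows$fraction[rows$is_lbp])
    cat <- if (f > high) "HIGH_CTV05" else if (f < low) "LOW_CTV05" else "MIXED"
    data.frame(sample = s, lc_abundance = lc, lbp_fraction = f,
               category = cat, stringsAsFactors = FALSE)
  }))
  out$category <- factor(out$category, levels = strain_category_levels())
  rownames(out) <- NULL
  out
}

#' Strain-category transitions across consecutive scheduled visits
#'
#' Pairs are formed from consecutive scheduled post-randomization visits both
#' observed for a participant. Pairs whose second (or first) visit had a
#' technically failed strain inference (`UNDETERMINED`) are excluded; the
#' below-eligibility state (`LC_LT5`) is a legitimate destination.
#'
#' @param categories Data frame with `participant`, `visit`, `category`
#'   (levels as in [categorize_strains()]).
#' @param visits Ordered visit labels (default the post-randomization
#'   schedule `postMTZ, wk4, wk8, wk12, wk24`).
#' @return List with `counts`, `proportions` (rows = category at visit t),
#'   and `pairs`. Empty input yields an empty table with a warning.
#' @export
strain_transitions <- function(categories,
                               visits = c("postMTZ", "wk4", "wk8", "wk12", "wk24")) {
  df <- categories
  df$value <- as.character(df$category)
  pairs <- consecutive_pairs(df[c("participant", "visit", "value")], visits)
  pairs <- pairs[pairs$from != "UNDETERMINED" & pairs$to != "UNDETERMINED", , drop = FALSE]
  lev <- strain_category_levels()
  lev <- setdiff(lev, "UNDETERMINED")
  if (!nrow(pairs)) {
    warning("no usable visit pairs")
    counts <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
    return(list(counts = counts, proportions = counts, pairs = pairs))
  }
  counts <- unclass(table(factor(pairs$from, lev), factor(pairs$to, lev)))
  rs <- rowSums(counts)
  list(counts = counts, proportions = counts / ifelse(rs == 0, 1, rs), pairs = pairs)
}

#' Histogram of distinct native strains per participant
#'
#' Counts, for each participant, the number of distinct native (non-LBP)
#' strains ever detected at or above the confident-identification floor
#' (10% fractional abundance) across their samples, bucketed 0/1/2/3+.
#'
#' @param strains Long strain table with `sample`, `strain_id`, `fraction`,
#'   `is_lbp` and a `participant` column.
#' @param detection Detection floor on fractional abundance (default 0.1).
#' @return Named integer vector with buckets `0`, `1`, `2`, `3+`.
#' @export
native_strain_histogram <- function(strains, detection = 0.1) {
  stopifnot(all(c("participant", "strain_id", "fraction", "is_lbp") %in% names(strains)))
  det <- strains[!strains$is_lbp & strains$fraction >= detection, , drop = FALSE]
  n_per <- tapply(det$strain_id, det$participant, function(x) length(unique(x)))
  all_p <- unique(strains$participant)
  counts <- integer(length(all_p))
  names(counts) <- all_p
  counts[names(n_per)] <- as.integer(n_per)
  bucket <- ifelse(counts >= 3, "3+", as.character(counts))
  out <- table(factor(bucket, levels = c("0", "1", "2", "3+")))
  stats::setNames(as.integer(out), names(out))
}
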