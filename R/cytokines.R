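# Cytokine panel preprocessing: log10 transform, limit-of-quantification
# imputation, analyte exclusion, size-effect (PC1) subtraction, and
# baseline deltas.
#
# Luminex-type panels of mucosal swabs carry a "size effect": the amount of
# material collected on a swab inflates all analyte concentrations jointly,
# so the first principal component of the standardized log concentrations
# mostly reflects swab biomass rather than biology. The adjustment zeroes
# the PC1 scores and back-transforms with the transposed rotation matrix.

#' Impute out-of-range cytokine concentrations and log10-transform
#'
#' Entries flagged below the lower limit of quantification (LLOQ) are set to
#' LLOQ/2; entries above the upper limit (ULOQ) are set to the ULOQ;
#' in-range values are untouched. log10 is then applied.
#'
#' @param panel Long-format data frame with columns `sample`, `analyte`,
#'   `concentration`, `flag` (one of `"in_range"`, `"below_lloq"`,
#'   `"above_uloq"`), `lloq`, `uloq`.
#' @return The panel with columns `imputed` (linear scale) and `log10_conc`.
#' @export
impute_out_of_range <- function(panel) {
  need <- c("sample", "analyte", "concentration", "flag", "lloq", "uloq")
  stopifnot(all(need %in% names(panel)))
  if (any(panel$lloq >= panel$uloq, na.rm = TRUE)) stop("inverted LOQ bounds")
  cens <- panel$flag != "in_range"
  if (any(cens & (is.na(panel$lloq) | is.na(panel$uloq)))) {
    stop("missing LOQ for a censored entry")
  }
  imputed <- panel$concentration
  imputed[panel$flag == "below_lloq"] <- panel$lloq[panel$flag == "below_lloq"] / 2
  imputed[panel$flag == "above_uloq"] <- panel$uloq[panel$flag == "above_uloq"]
  panel$imputed <- imputed
  panel$log10_conc <- log10(imputed)
  panel
}

#' Analyte inclusion flags from censoring frequencies
#'
#' An analyte is excluded when at least 60% of its samples fall below the
#' LLOQ or at least 30% fall above the ULOQ (both thresholds inclusive).
#'
#' @param panel Long-format panel with `analyte` and `flag` columns.
#' @param max_below Exclusion threshold for the below-LLOQ fraction.
#' @param max_above Exclusion threshold for the above-ULOQ fraction.
#' @return Data frame with per-analyte censoring fractions and an `included`
#'   flag.
#' @export
exclude_analytes <- function(panel, max_below = 0.6, max_above = 0.3) {
  stopifnot(all(c("analyte", "flag") %in% names(panel)))
  sp <- split(panel$flag, panel$analyte)
  out <- do.call(rbind, lapply(names(sp), function(a) {
    f <- sp[[a]]
    below <- mean(f == "below_lloq")
    above <- mean(f == "above_uloq")
    data.frame(analyte = a, frac_below = below, frac_above = above,
               included = below < max_below & above < max_above,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Long panel to wide sample x analyte matrix of log10 concentrations
#'
#' @param panel Imputed panel (see [impute_out_of_range()]).
#' @param analytes Optional subset of analytes to keep (e.g., the included
#'   set from [exclude_analytes()]).
#' @return Numeric matrix, samples in rows, analytes in columns.
#' @export
panel_matrix <- function(panel, analytes = NULL) {
  stopifnot("log10_conc" %in% names(panel))
  if (!is.null(analytes)) panel <- panel[panel$analyte %in% analytes, , drop = FALSE]
  wide <- stats::reshape(
    panel[c("sample", "analyte", "log10_conc")],
    idvar = "sample", timevar = "analyte", direction = "wide"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^log10_conc\\.", "", colnames(m))
  rownames(m) <- wide$sample
  m
}

#' Subtract the first principal component (size-effect adjustment)
#'
#' Columns are standardized (zero mean, unit variance), the principal
#' components of the standardized matrix are computed, the scores of the
#' first component are re-assigned to zero, and the data are transformed
#' back to variable space with the transposed rotation matrix, then
#' de-standardized back to the log scale.
#'
#' @param log_matrix Samples x analytes matrix of log10 concentrations, no
#'   missing values.
#' @param n_remove Number of leading components to remove (default 1).
#' @return Adjusted matrix on the log scale, with attributes
#'   `variance_explained` (per-component fractions), `rotation`, and
#'   `removed_scores`.
#' @export
pc1_subtract <- function(log_matrix, n_remove = 1L) {
  x <- as.matrix(log_matrix)
  if (nrow(x) < 3L || ncol(x) < 2L) stop("need >= 3 samples and >= 2 analytes")
  if (anyNA(x)) stop("missing values not allowed in the PCA input")
  st <- standardize_cols(x)
  pr <- stats::prcomp(st$x, center = FALSE, scale. = FALSE)
  scores <- pr$x
  removed <- scores[, seq_len(n_remove), drop = FALSE]
  scores[, seq_len(n_remove)] <- 0
  adj_std <- scores %*% t(pr$rotation)
  adj <- sweep(sweep(adj_std, 2, st$scale, "*"), 2, st$center, "+")
  dimnames(adj) <- dimnames(x)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  attr(adj, "variance_explained") <- ve
  attr(adj, "rotation") <- pr$rotation
  attr(adj, "removed_scores") <- removed
  adj
}

#' Per-component variance fractions of the standardized log matrix
#'
#' @param log_matrix Samples x analytes matrix of log10 concentrations.
#' @return Numeric vector of nonincreasing fractions summing to 1.
#' @export
variance_explained <- function(log_matrix) {
  st <- standardize_cols(as.matrix(log_matrix))
  ev <- stats::prcomp(st$x, center = FALSE, scale. = FALSE)$sdev^2
  ev / sum(ev)
}

#' Per-participant deltas from the baseline visit
#'
#' delta(v) = adjusted(v) - adjusted(baseline) for every analyte;
#' participants without a baseline measurement are dropped with a message.
#'
#' @param values Samples x analytes matrix (adjusted or unadjusted).
#' @param metadata Data frame with `sample`, `participant`, `visit`, one row
#'   per row of `values`.
#' @param baseline_visit Baseline visit label (default `"preMTZ"`).
#' @return Long data frame with `participant`, `visit`, `analyte`, `delta`.
#' @export
baseline_delta <- function(values, metadata, baseline_visit = "preMTZ") {
  stopifnot(all(c("sample", "participant", "visit") %in% names(metadata)))
  values <- as.matrix(values)
  md <- metadata[match(rownames(values), metadata$sample), , drop = FALSE]
  if (anyNA(md$participant)) stop("samples missing from metadata")
  base_rows <- md$visit == baseline_visit
  base_of <- rownames(values)[base_rows][match(md$participant, md$participant[base_rows])]
  dropped <- unique(md$participant[is.na(base_of)])
  if (length(dropped)) {
    message("dropped ", length(dropped), " participant(s) without baseline")
  }
  keep <- !is.na(base_of) & !base_rows
  if (!any(keep)) {
    return(data.frame(participant = character(), visit = character(),
                      analyte = character(), delta = numeric()))
  }
  d <- values[keep, , drop = FALSE] - values[base_of[keep], , drop = FALSE]
  long <- data.frame(
    participant = rep(md$participant[keep], times = ncol(d)),
    visit = rep(md$visit[keep], times = ncol(d)),
    analyte = rep(colnames(d), each = nrow(d)),
    delta = as.vector(d), stringsAsFactors = FALSE
  )
  rownames(long) <- NULL
  long
}

#' Full cytokine preprocessing chain
#'
#' Imputation, exclusion, wide-matrix construction, and (optionally) the
#' size-effect PC1 subtraction. The sensitivity mode (`adjust = FALSE`)
#' returns the unadjusted log matrix so downstream analyses can be rerun
#' without the correction.
#'
#' @param panel Raw long-format panel.
#' @param adjust Apply PC1 subtraction? Default `TRUE`.
#' @return List with `matrix` (log10, possibly adjusted), `unadjusted`,
#'   `inclusion` (from [exclude_analytes()]), `variance_explained`, and
#'   `adjusted` flag.
#' @export
preprocess_cytokines <- function(panel, adjust = TRUE) {
  panel <- impute_out_of_range(panel)
  inc <- exclude_analytes(panel)
  keep <- inc$analyte[inc$included]
  if (!length(keep)) stop("all analytes excluded")
  m <- panel_matrix(panel, analytes = keep)
  ve <- variance_explained(m)
  out <- if (adjust) pc1_subtract(m) else m
  list(matrix = out, unadjusted = m, inclusion = inc,
       variance_explained = ve, adjusted = adjust)
}
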