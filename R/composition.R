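# Compositional primitives: relative abundance, colonization categories,
# diversity, Bray-Curtis dissimilarity, and category transition tables.

#' Scheduled visit labels, in trial order
#'
#' The six scheduled visits: screening before metronidazole (preMTZ),
#' randomization after metronidazole (postMTZ), then weeks 4, 8, 12 and 24.
#'
#' @return Character vector of visit labels.
#' @export
visit_levels <- function() c("preMTZ", "postMTZ", "wk4", "wk8", "wk12", "wk24")

#' Build a taxonomy table for a set of species labels
#'
#' @param species Character vector of species labels (unique).
#' @param genus Character vector of genus names, same length.
#' @return Data frame with columns `species`, `genus`, `is_lacto`.
#' @export
make_taxonomy <- function(species, genus) {
  stopifnot(length(species) == length(genus), !anyDuplicated(species))
  if (any(is.na(genus) | genus == "")) stop("every species needs a genus")
  data.frame(
    species = species, genus = genus,
    is_lacto = genus == "Lactobacillus",
    stringsAsFactors = FALSE
  )
}

#' Relative abundance from a count table
#'
#' @param counts Numeric matrix, samples in rows, species in columns;
#'   nonnegative integers.
#' @return Matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  tot <- rowSums(counts)
  bad <- tot == 0
  if (any(bad)) {
    stop("all-zero sample(s): ", paste(rownames(counts)[bad] %||% which(bad), collapse = ", "))
  }
  counts / tot
}

#' Classify samples into colonization categories
#'
#' A sample is *L. crispatus*-dominant (`LC_DOM`) when the *L. crispatus*
#' relative abundance is at least 50%; otherwise other-*Lactobacillus*-
#' dominant (`OTHER_LACTO_DOM`) when the summed *Lactobacillus* genus
#' abundance is at least 50%; otherwise non-*Lactobacillus*-dominant
#' (`NON_LACTO_DOM`). Both thresholds are inclusive.
#'
#' @param proportions Samples x species matrix of relative abundances (raw
#'   counts are accepted; the classification is scale-invariant).
#' @param taxonomy Data frame as from [make_taxonomy()].
#' @param lc_species Label of the *L. crispatus* column.
#' @return Factor of categories, one per sample, levels
#'   `LC_DOM`, `OTHER_LACTO_DOM`, `NON_LACTO_DOM`.
#' @export
classify_colonization <- function(proportions, taxonomy,
                                  lc_species = "Lactobacillus crispatus") {
  proportions <- as.matrix(proportions)
  if (!all(c("species", "is_lacto") %in% names(taxonomy))) {
    stop("taxonomy must have 'species' and 'is_lacto' columns")
  }
  miss <- setdiff(colnames(proportions), taxonomy$species)
  if (length(miss)) stop("taxonomy missing species: ", paste(miss, collapse = ", "))
  is_lacto <- taxonomy$is_lacto[match(colnames(proportions), taxonomy$species)]
  tot <- rowSums(proportions)
  prop <- proportions / tot   # scale invariance
  lc <- if (lc_species %in% colnames(prop)) prop[, lc_species] else rep(0, nrow(prop))
  lacto <- rowSums(prop[, is_lacto, drop = FALSE])
  out <- ifelse(lc >= 0.5, "LC_DOM",
                ifelse(lacto >= 0.5, "OTHER_LACTO_DOM", "NON_LACTO_DOM"))
  factor(out, levels = c("LC_DOM", "OTHER_LACTO_DOM", "NON_LACTO_DOM"))
}

#' Bray-Curtis dissimilarity between two relative-abundance vectors
#'
#' For proportion vectors p and q over the same species, BC = 1 - sum of
#' element-wise minima.
#'
#' @param p,q Named or unnamed numeric proportion vectors over identical
#'   species sets.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) stop("mismatched species sets")
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!identical(sort(names(p)), sort(names(q)))) stop("mismatched species sets")
    q <- q[names(p)]
  }
  1 - sum(pmin(p, q)) / ((sum(p) + sum(q)) / 2)
}

#' Per-sample alpha diversity
#'
#' @param proportions Samples x species proportion matrix.
#' @param index `"shannon"` (natural-log entropy, default), `"simpson"`
#'   (1 - sum p^2) or `"richness"` (count of species present).
#' @return Numeric vector, one value per sample.
#' @export
alpha_diversity <- function(proportions, index = c("shannon", "simpson", "richness")) {
  index <- match.arg(index)
  proportions <- as.matrix(proportions)
  proportions <- proportions / rowSums(proportions)
  switch(index,
    shannon = apply(proportions, 1, function(p) {
      p <- p[p > 0]
      -sum(p * log(p))
    }),
    simpson = 1 - rowSums(proportions^2),
    richness = rowSums(proportions > 0)
  )
}

# Consecutive scheduled-visit pairs for a set of (participant, visit, value)
# rows. Pairs are formed only when both members of a consecutive scheduled
# pair are observed; gaps are never spanned.
consecutive_pairs <- function(df, visits = visit_levels()) {
  stopifnot(all(c("participant", "visit") %in% names(df)))
  if (anyDuplicated(df[c("participant", "visit")])) {
    stop("duplicate (participant, visit) rows")
  }
  df$visit <- as.character(df$visit)
  # unscheduled extra visits are excluded: pairs are defined on the schedule
  df <- df[df$visit %in% visits, , drop = FALSE]
  out <- vector("list", length(visits) - 1L)
  for (j in seq_len(length(visits) - 1L)) {
    a <- df[df$visit == visits[j], , drop = FALSE]
    b <- df[df$visit == visits[j + 1L], , drop = FALSE]
    m <- match(a$participant, b$participant)
    keep <- !is.na(m)
    if (!any(keep)) next
    out[[j]] <- data.frame(
      participant = a$participant[keep],
      visit_from = visits[j], visit_to = visits[j + 1L],
      from = a$value[keep], to = b$value[m[keep]],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out) %||% data.frame(
    participant = character(), visit_from = character(), visit_to = character(),
    from = character(), to = character()
  )
}

#' Category transitions between consecutive scheduled visits
#'
#' Counts, for every pair of consecutive scheduled visits both observed for a
#' participant, the category at visit t against the category at visit t+1.
#'
#' @param categories Data frame with columns `participant`, `visit`,
#'   `category`.
#' @param visits Ordered visit labels defining "consecutive".
#' @return List with `counts` (matrix, rows = category at t), `proportions`
#'   (rows renormalized), and `pairs` (the pair-level data frame).
#' @export
transition_table <- function(categories, visits = visit_levels()) {
  df <- categories
  df$value <- as.character(df$category)
  pairs <- consecutive_pairs(df[c("participant", "visit", "value")], visits)
  lev <- sort(unique(c(pairs$from, pairs$to, as.character(categories$category))))
  counts <- table(factor(pairs$from, lev), factor(pairs$to, lev))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, proportions = props, pairs = pairs)
}
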