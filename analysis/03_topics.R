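#!/usr/bin/env Rscript
# Constrained topic model: pure Lactobacillus topics by the dominance rule,
# LDA on the non-Lactobacillus counts across a grid of resolutions, topic
# alignment to choose K, and whole-community rescaling.

suppressMessages(library(lbptrial))

cohort_dir <- "results/cohort"
counts <- as.matrix(read.delim(file.path(cohort_dir, "counts.tsv"),
                               row.names = 1, check.names = FALSE))
tax <- read.delim(file.path(cohort_dir, "taxonomy.tsv"))

is_lacto <- tax$is_lacto[match(colnames(counts), tax$species)]
grid <- fit_topic_grid(counts[, !is_lacto], k_grid = 2:7, seed = 11)
K <- tryCatch(select_K(grid$alignment), warning = function(w) {
  message("alignment fallback: ", conditionMessage(w))
  suppressWarnings(select_K(grid$alignment))
})
message("alignment diagnostics (min coherence / max redundancy per K):")
tp <- grid$alignment$topics
for (k in grid$alignment$K_grid) {
  message(sprintf("  K=%d  coh>=%.2f  red<=%.2f", k,
                  min(tp$coherence[tp$K == k]), max(tp$redundancy[tp$K == k])))
}
message("selected K = ", K)

fit <- fit_topic_model(counts, tax, K = K, seed = 11)
message("Lactobacillus topics: ",
        paste(c(fit$lacto$pure,
                if (!is.null(fit$lacto$other_composition)) "Other L."),
              collapse = ", "))
stopifnot(max(abs(rowSums(fit$topic_proportions) - 1)) < 1e-10)

write.csv(data.frame(topic = rownames(fit$beta), fit$beta, check.names = FALSE),
          "results/topic_profiles.csv", row.names = FALSE)
write.csv(data.frame(sample = rownames(fit$topic_proportions),
                     fit$topic_proportions, check.names = FALSE),
          "results/topic_proportions.csv", row.names = FALSE)
message("wrote topic profiles (", nrow(fit$beta), " non-Lactobacillus topics) ",
        "and per-sample proportions for ", nrow(fit$topic_proportions), " samples")
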