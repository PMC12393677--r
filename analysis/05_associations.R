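#!/usr/bin/env Rscript
# Microbiota-immune association: RV coefficient between topic proportions
# and adjusted cytokine concentrations (overall and per visit), and a
# DiSTATIS compromise of the two sample-dissimilarity structures with a
# variable correlation circle.

suppressMessages(library(lbptrial))

topics <- read.csv("results/topic_proportions.csv", check.names = FALSE)
rownames(topics) <- topics$sample; topics$sample <- NULL
cyto <- read.csv("results/cytokines_adjusted.csv", check.names = FALSE)
rownames(cyto) <- cyto$sample; cyto$sample <- NULL
md <- read.csv("results/cohort/metadata.csv")
counts <- as.matrix(read.delim("results/cohort/counts.tsv",
                               row.names = 1, check.names = FALSE))

shared <- intersect(rownames(topics), rownames(cyto))
tm <- as.matrix(topics[shared, ]); cm <- as.matrix(cyto[shared, ])

rv <- rv_permutation_test(tm, cm, n_perm = 999, seed = 3)
message(sprintf("overall RV = %.3f (permutation p = %.3g, %d samples)",
                rv$rv, rv$p_value, length(shared)))

per_visit <- do.call(rbind, lapply(visit_levels(), function(v) {
  ids <- intersect(shared, md$sample[md$visit == v])
  if (length(ids) < 10) return(NULL)
  r <- rv_permutation_test(tm[ids, ], cm[ids, ], n_perm = 999, seed = 3)
  data.frame(visit = v, n = length(ids), rv = r$rv, p = r$p_value)
}))
write.csv(per_visit, "results/rv_per_visit.csv", row.names = FALSE)
message("per-visit RV range: ",
        paste(round(range(per_visit$rv), 3), collapse = " - "))

prop <- relative_abundance(counts)[shared, ]
d_mb <- as.matrix(vegan::vegdist(prop, "bray"))
d_ck <- as.matrix(dist(scale(cm)))
res <- distatis(list(microbiota = d_mb, cytokines = d_ck), n_dims = 4)
message("DiSTATIS table weights: ",
        paste(sprintf("%s %.2f", names(res$weights), res$weights), collapse = ", "))

cc <- correlation_circle(cbind(tm, cm), res$scores)
write.csv(data.frame(variable = rownames(cc), cc, check.names = FALSE),
          "results/distatis_correlations.csv", row.names = FALSE)
ord <- order(cc[, 1])
message("strongest negative loadings on dimension 1: ",
        paste(rownames(cc)[head(ord, 3)], collapse = ", "))
message("strongest positive loadings on dimension 1: ",
        paste(rownames(cc)[tail(ord, 3)], collapse = ", "))
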