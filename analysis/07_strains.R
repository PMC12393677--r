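#!/usr/bin/env Rscript
# LBP-strain versus native-strain dynamics among LBP recipients: category
# classification (>90% / 10-90% / <10% CTV-05, >= 5% L. crispatus
# eligibility), transitions across consecutive post-randomization visits,
# and the native-strain histogram.

suppressMessages(library(lbptrial))

strains <- read.csv("results/cohort/strains.csv")
md <- read.csv("results/cohort/metadata.csv")
counts <- as.matrix(read.delim("results/cohort/counts.tsv",
                               row.names = 1, check.names = FALSE))

lbp_ids <- unique(md$participant[md$arm == "LBP"])
prop <- relative_abundance(counts)
lc <- prop[, "Lactobacillus crispatus"]
lc_lbp <- lc[md$arm[match(names(lc), md$sample)] == "LBP"]

cats <- categorize_strains(strains[strains$participant %in% lbp_ids, ], lc_lbp)
cats$participant <- md$participant[match(cats$sample, md$sample)]
cats$visit <- md$visit[match(cats$sample, md$sample)]
write.csv(cats, "results/strain_categories.csv", row.names = FALSE)

det <- cats$category %in% c("HIGH_CTV05", "MIXED", "LOW_CTV05")
for (v in c("wk4", "wk24")) {
  i <- det & cats$visit == v
  if (!any(i)) next
  message(sprintf("%s: %.1f%% of %d analyzable LBP samples high-CTV-05 or mixed",
                  v, 100 * mean(cats$category[i] != "LOW_CTV05"), sum(i)))
}

tt <- strain_transitions(cats)
write.csv(as.data.frame.matrix(tt$counts), "results/strain_transitions.csv")
pr <- tt$proportions
message("per-state outcomes at the next visit (row proportions):")
for (s in c("HIGH_CTV05", "MIXED", "LOW_CTV05")) {
  if (sum(tt$counts[s, ]) == 0) next
  message(sprintf("  %-11s n=%3d: stay %.2f, to LOW %.2f, to <5%% Lc %.2f",
                  s, sum(tt$counts[s, ]), pr[s, s], pr[s, "LOW_CTV05"],
                  pr[s, "LC_LT5"]))
}

hist <- native_strain_histogram(strains[strains$participant %in% lbp_ids, ])
write.csv(data.frame(native_strains = names(hist), participants = hist),
          "results/native_strain_histogram.csv", row.names = FALSE)
message("native strains ever detected per LBP participant: ",
        paste(sprintf("%s:%d", names(hist), hist), collapse = "  "))
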