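#!/usr/bin/env Rscript
# Heterogeneity of the treatment effect with respect to the baseline
# (pre-MTZ) microbiota: stratified rates with Wilson intervals, nested
# logistic deviance F tests with BH correction, and counterfactual
# participant-level odds ratios from the quantitative (topic-based) model.

suppressMessages(library(lbptrial))

md <- read.csv("results/cohort/metadata.csv")
cats <- read.csv("results/categories.csv")
topics <- read.csv("results/topic_proportions.csv", check.names = FALSE)
tax <- read.delim("results/cohort/taxonomy.tsv")
counts <- as.matrix(read.delim("results/cohort/counts.tsv",
                               row.names = 1, check.names = FALSE))

# outcome: L. crispatus dominance at week 12 / 24
outcome_at <- function(v) {
  i <- cats$visit == v
  setNames(cats$category[i] == "LC_DOM", cats$participant[i])
}
# baseline stratum: most predominant genus at preMTZ
prop <- relative_abundance(counts)
pre <- md[md$visit == "preMTZ", ]
genus <- tax$genus[match(colnames(prop), tax$species)]
gen_prop <- t(apply(prop[pre$sample, ], 1, function(p) tapply(p, genus, sum)))
stratum <- setNames(colnames(gen_prop)[max.col(gen_prop)], pre$participant)

results <- list(); pvals <- c()
for (v in c("wk12", "wk24")) {
  oc <- outcome_at(v)
  ids <- intersect(names(oc), names(stratum))
  arm <- md$arm[match(ids, md$participant)]
  sr <- tryCatch(
    stratified_rates(oc[ids], arm, stratum[ids], ref = "placebo"),
    error = function(e) NULL
  )
  if (!is.null(sr)) {
    sr$rates$outcome <- v
    results[[v]] <- sr
    write.csv(sr$differences, sprintf("results/rate_differences_%s.csv", v),
              row.names = FALSE)
  }
  keep <- ids[stratum[ids] %in% (if (is.null(sr)) character() else unique(sr$rates$stratum))]
  ht <- heterogeneity_test(oc[keep], md$arm[match(keep, md$participant)],
                           data.frame(stratum = factor(stratum[keep])))
  pvals[v] <- ht$p_value
  message(sprintf("%s: heterogeneity F = %.2f on (%d, %d) df, raw p = %.3f",
                  v, ht$f_statistic, ht$df[1], ht$df[2], ht$p_value))
}
message("BH-adjusted heterogeneity p-values: ",
        paste(sprintf("%s %.3f", names(pvals), bh_adjust(pvals)), collapse = ", "))

# quantitative model: total Lactobacillus (agglomerated) + non-Lacto topics
oc <- outcome_at("wk12")
ids <- intersect(names(oc), md$participant[md$visit == "preMTZ"])
pre_samp <- paste0(ids, "_preMTZ")
tp <- topics[match(pre_samp, topics$sample), ]
lacto_cols <- grepl("Lactobacillus|Other L", colnames(tp))
quant <- data.frame(total_lacto = rowSums(tp[, lacto_cols, drop = FALSE]))
arm <- relevel(factor(md$arm[match(ids, md$participant)]), "placebo")
fit <- glm(y ~ arm * total_lacto, binomial(),
           data = data.frame(y = as.integer(oc[ids]), arm = arm, quant))
cf <- counterfactual_predictions(fit, data.frame(arm = arm, quant),
                                 "arm", "LBP", "placebo")
write.csv(cbind(participant = ids, cf), "results/counterfactuals_wk12.csv",
          row.names = FALSE)
message(sprintf("counterfactual odds ratios (wk12): median %.2f, IQR %.2f - %.2f",
                median(cf$odds_ratio), quantile(cf$odds_ratio, 0.25),
                quantile(cf$odds_ratio, 0.75)))
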