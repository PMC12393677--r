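#!/usr/bin/env Rscript
# Multiblock PLS-DA of week-4 colonization categories among LBP recipients:
# thematic predictor blocks, cross-validated component count, relative
# cumulative block importance with bootstrap intervals.

suppressMessages(library(lbptrial))

# regenerate the cohort object (deterministic for the fixed seed of
# 01_simulate.R) so the covariate blocks are available in memory
cohort <- generate_cohort(cohort_config(n_participants = 180, seed = 20260927L))

pb <- phase_blocks(cohort, "initial", seed = 5)
message("initial phase: ", length(pb$participants), " LBP participants, ",
        "response classes: ",
        paste(sprintf("%s:%d", levels(pb$response), table(pb$response)),
              collapse = "  "))

cv <- cross_validate(pb$blocks, pb$response, component_grid = 1:4,
                     n_splits = 40, seed = 6)
message("mean validation macro-F1 by components: ",
        paste(sprintf("%d:%.3f", cv$component_grid, cv$mean_f1), collapse = "  "),
        "  -> selected ", cv$selected)

fit <- fit_mbplsda(pb$blocks, pb$response, n_components = 2)
bi <- bootstrap_block_importance(pb$blocks, pb$response, n_components = 2,
                                 n_boot = 200, seed = 7)
write.csv(bi, "results/block_importance_initial.csv", row.names = FALSE)
message("relative cumulative block importance (95% bootstrap CI):")
for (i in order(-bi$estimate)) {
  message(sprintf("  %-13s %.2f [%.2f - %.2f]", bi$block[i], bi$estimate[i],
                  bi$lower[i], bi$upper[i]))
}

cont <- phase_blocks(cohort, "continuation", seed = 8)
ri_cont <- relative_block_importance(
  fit_mbplsda(cont$blocks, cont$response, n_components = 2))
message("continuation phase top block: ", names(which.max(ri_cont)),
        sprintf(" (index %.2f)", max(ri_cont)))
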