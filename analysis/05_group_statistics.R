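#!/usr/bin/env Rscript
# The statistics layer: group comparisons of demographics, cognition,
# sleep, temperature rhythm and state-wise HRV (pooled-variance t-tests,
# chi-square for sex), and the within-O-LOAD Pearson correlation screen
# between HRV physiology and cognitive scores with per-block Bonferroni
# flags.

library(circadia)

cohort <- readRDS("scratch/cohort.rds")
derived <- read.csv("results/hrv_state_summary.csv", stringsAsFactors = FALSE)
derived$group <- NULL

rep <- build_tables(cohort$cohort, derived, alpha = 0.05)
write.csv(rep$comparisons, "results/table_group_comparisons.csv", row.names = FALSE)
write.csv(rep$correlations, "results/table_correlations.csv", row.names = FALSE)

sig <- rep$comparisons[rep$comparisons$p < 0.05, c("variable", "statistic", "p")]
message("group comparisons with p < 0.05:")
for (i in seq_len(nrow(sig)))
  message(sprintf("  %-14s t/chi2 = %6.2f, p = %.4f",
                  sig$variable[i], sig$statistic[i], sig$p[i]))

bb <- rep$correlations[rep$correlations$bonferroni %in% TRUE, ]
message("Bonferroni-surviving correlations (O-LOAD):")
for (i in seq_len(nrow(bb)))
  message(sprintf("  [%s] %s ~ %s: r = %+.3f, p = %.2g (m = %d)",
                  bb$state[i], bb$phys[i], bb$cog[i], bb$r[i], bb$p[i], bb$m[i]))
message("wrote results/table_group_comparisons.csv, results/table_correlations.csv")
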