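#!/usr/bin/env Rscript
# Score sleep/wake from each subject's actigraphy inside the diary in-bed
# windows (Cole-Kripke weighting + rescoring) and tabulate the sleep
# parameters: scored onset/offset clock times, minutes asleep, minutes
# awake in bed, and efficiency.

library(circadia)

cohort <- readRDS("scratch/cohort.rds")
cfg <- run_config()

rows <- lapply(names(cohort$series), function(id) {
  s <- cohort$series[[id]]
  cbind(id = id, sleep_params(score_epochs(s$activity, s$diary, cfg)))
})
sleep_tab <- do.call(rbind, rows)
sleep_tab$group <- cohort$cohort$group[match(sleep_tab$id, cohort$cohort$id)]
write.csv(sleep_tab, "results/sleep_params.csv", row.names = FALSE)

for (g in c("CS", "O-LOAD")) {
  gg <- sleep_tab[sleep_tab$group == g, ]
  message(sprintf(
    "%-6s scored onset %05.2f h, offset %05.2f h, asleep %.0f min, efficiency %.1f%%",
    g, mean(unwrap_clock(gg$start_time, 0)) %% 24,
    mean(gg$end_time), mean(gg$duration_asleep), mean(gg$efficiency)))
}
message("wrote results/sleep_params.csv")
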