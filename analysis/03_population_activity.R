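#!/usr/bin/env Rscript
# Step 3: spontaneously active DA neurons per electrode track, one value
# per rat, compared across groups within each day.

suppressPackageStartupMessages({library(ephystat); library(dplyr)})

grids <- read.csv("results/cohort/grids.csv")
rats <- read.csv("results/cohort/rats.csv")

pop <- grids |>
  group_by(rat_id) |>
  summarise(population_activity = {
    g <- track_grid(rat_id[1], n_active_neurons)
    population_activity(g)
  }, .groups = "drop") |>
  left_join(rats, by = "rat_id")
write.csv(pop, "results/population_activity.csv", row.names = FALSE)

tab <- aggregate_to_rats(pop)
for (d in unique(tab$day)) {
  day_tab <- tab[tab$day == d, ]
  class(day_tab) <- class(tab)
  res <- compare_groups(day_tab, "population_activity", "oneway_anova_bonferroni")
  cat(sprintf("day %2d  population activity  F[%d,%d] = %5.2f, p = %.3f\n",
              d, res$df[1], res$df[2], res$statistic, res$p_value))
  print(as.data.frame(res$posthoc[, c("comparison", "p_adj")]))
}
cat("\nper-rat population activity written to results/population_activity.csv\n")
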