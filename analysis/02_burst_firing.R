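#!/usr/bin/env Rscript
# Step 2: firing rate and ISI burst metrics for every monoamine unit,
# aggregated to one value per rat, then compared across treatment groups
# within each day (one-way ANOVA with Bonferroni post hoc, per the
# between-group design).

suppressPackageStartupMessages({library(ephystat); library(dplyr)})

trains <- read_spiketrains("results/cohort/trains.csv")
rats <- read.csv("results/cohort/rats.csv")

metrics <- bind_rows(lapply(trains, function(tr) {
  br <- detect_bursts(tr)
  tibble::tibble(neuron_id = tr$neuron_id, rat_id = tr$rat_id,
                 neuron_type = tr$neuron_type,
                 firing_rate = mean_firing_rate(tr),
                 pct_spikes_in_burst = br$pct_spikes_in_burst,
                 pct_neurons_with_burst = 100 * br$has_burst)
})) |> left_join(rats, by = "rat_id")
write.csv(metrics, "results/burst_metrics_per_neuron.csv", row.names = FALSE)

for (type in c("DA", "5HT", "NE")) {
  tab <- aggregate_to_rats(filter(metrics, neuron_type == type) |>
                             select(-neuron_id, -neuron_type))
  write.csv(tab, sprintf("results/burst_metrics_per_rat_%s.csv", type),
            row.names = FALSE)
  # metric panels per cell type: DA is summarized by % spikes in burst,
  # 5-HT by % neurons with burst activity, NE by both
  panel <- list(DA = c("firing_rate", "pct_spikes_in_burst"),
                `5HT` = c("firing_rate", "pct_neurons_with_burst"),
                NE = c("firing_rate", "pct_spikes_in_burst",
                       "pct_neurons_with_burst"))[[type]]
  for (d in unique(tab$day)) {
    day_tab <- tab[tab$day == d, ]
    class(day_tab) <- class(tab)
    for (m in panel) {
      if (length(unique(day_tab[[m]])) == 1L) {
        cat(sprintf("%-4s day %2d  %-22s constant at %.1f in all rats; no test\n",
                    type, d, m, day_tab[[m]][1]))
        next
      }
      res <- compare_groups(day_tab, m, "oneway_anova_bonferroni")
      cat(sprintf("%-4s day %2d  %-22s F[%d,%d] = %5.2f, p = %.3f\n",
                  type, d, m, res$df[1], res$df[2], res$statistic, res$p_value))
    }
  }
}
cat("\nper-neuron and per-rat metric tables written under results/\n")
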