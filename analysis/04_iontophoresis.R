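#!/usr/bin/env Rscript
# Step 4: RT50 (transporter activity) and IT50 (receptor sensitivity) from
# the pyramidal-neuron ejection recordings, one neuron per rat and agent.
# Group contrasts at 14 days (5-HT) and both days (NE) against vehicle,
# with two-tailed t and Mann-Whitney comparisons, mirroring the mixed
# usage of parametric and rank tests for these indices.

suppressPackageStartupMessages({library(ephystat); library(dplyr)})

pyr <- read_spiketrains("results/cohort/pyramidal_trains.csv")
epochs <- read.csv("results/cohort/epochs.csv")
rats <- read.csv("results/cohort/rats.csv")

ionto <- bind_rows(lapply(seq_len(nrow(epochs)), function(i) {
  e <- epochs[i, ]
  tr <- pyr[[e$neuron_id]]
  ep <- ionto_epoch(e$onset, e$offset, e$current_nA, e$agent)
  tibble::tibble(rat_id = tr$rat_id, agent = e$agent,
                 rt50_s = as.numeric(rt50(tr, ep, smooth = TRUE)),
                 it50_nc = as.numeric(it50(tr, ep, smooth = TRUE)))
})) |> left_join(rats, by = "rat_id")
write.csv(ionto, "results/ionto_metrics.csv", row.names = FALSE)

summary_tab <- ionto |>
  group_by(agent, group, day) |>
  summarise(rt50_mean = mean(rt50_s), rt50_sem = sd(rt50_s) / sqrt(n()),
            it50_mean = mean(it50_nc), it50_sem = sd(it50_nc) / sqrt(n()),
            n_rats = n(), .groups = "drop")
write.csv(summary_tab, "results/ionto_summary.csv", row.names = FALSE)
print(as.data.frame(summary_tab), digits = 3)

for (ag in c("5HT", "NE")) {
  for (d in c(2, 14)) {
    sub <- ionto |> filter(agent == ag, day == d,
                           group %in% c("vehicle", "venlafaxine", "combination"))
    for (trt in c("venlafaxine", "combination")) {
      two <- sub |> filter(group %in% c("vehicle", trt))
      if (length(unique(two$group)) < 2) next
      tab <- aggregate_to_rats(rename(two, rt50 = rt50_s, it50 = it50_nc) |>
                                 select(rat_id, group, day, rt50, it50))
      t_res <- compare_groups(tab, "rt50", "two_sample_t")
      u_res <- compare_groups(tab, "it50", "mann_whitney")
      cat(sprintf("%-3s day %2d  %-12s vs vehicle:  RT50 t = %5.2f (p = %.3f);  IT50 U = %4.0f (p = %.3f)\n",
                  ag, d, trt, t_res$statistic, t_res$p_value,
                  u_res$statistic, u_res$p_value))
    }
  }
}
cat("\nRT50/IT50 tables written to results/ionto_metrics.csv and results/ionto_summary.csv\n")
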