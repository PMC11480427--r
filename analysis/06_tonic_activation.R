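#!/usr/bin/env Rscript
# Step 6: tonic activation of postsynaptic 5-HT1A receptors — percent
# change in pyramidal firing after cumulative WAY 100635, referenced to
# the pre-first-dose baseline, one neuron per rat; treatment x dose
# repeated-measures ANOVA with Holm-Sidak post hoc.

suppressPackageStartupMessages({library(ephystat); library(dplyr)})

pyr <- read_spiketrains("results/cohort/pyramidal_trains.csv")
doses <- read.csv("results/cohort/doses.csv")
rats <- read.csv("results/cohort/rats.csv")

tonic <- bind_rows(lapply(split(doses, doses$neuron_id), function(dd) {
  tr <- pyr[[dd$neuron_id[1]]]
  dl <- lapply(seq_len(nrow(dd)), function(i) {
    dose_event(dd$time[i], dd$drug[i], dd$dose[i], dd$cumulative_index[i])
  })
  curve <- cumulative_dose_curve(tr, dl)
  tibble::tibble(rat_id = tr$rat_id, curve)
})) |> left_join(rats, by = "rat_id")
write.csv(tonic, "results/tonic_activation.csv", row.names = FALSE)

overall <- tonic |> group_by(rat_id, group, day) |>
  summarise(overall_pct_change = mean(pct_change), .groups = "drop")
print(overall |> group_by(group, day) |>
        summarise(mean = mean(overall_pct_change),
                  sem = sd(overall_pct_change) / sqrt(n()),
                  .groups = "drop") |> as.data.frame(), digits = 3)

# treatment x cumulative dose, repeated measures within rat (14-day cells)
tab <- aggregate_to_rats(tonic |> filter(day == 14) |>
                           select(rat_id, group, day, dose, pct_change),
                         within = "dose")
res <- compare_groups(tab, "pct_change", "twoway_rm_anova_holm_sidak",
                      factor2 = "dose")
cat("\n14-day treatment x dose RM ANOVA on percent change:\n")
print(as.data.frame(res$terms), digits = 3)
print(as.data.frame(res$posthoc[, c("comparison", "p_adj")]), digits = 3)
cat("\ntonic-activation table written to results/tonic_activation.csv\n")
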