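#!/usr/bin/env Rscript
# Step 5: PSTHs of pyramidal neurons around ascending 5-HT pathway
# stimulation, duration of suppression at 1 and 5 Hz on the same neuron,
# and the treatment x frequency repeated-measures comparison (the terminal
# 5-HT1B autoreceptor probe).

suppressPackageStartupMessages({library(ephystat); library(dplyr)})

pyr <- read_spiketrains("results/cohort/pyramidal_trains.csv")
pulses <- read.csv("results/cohort/pulses.csv")
rats <- read.csv("results/cohort/rats.csv")

dos <- bind_rows(lapply(split(pulses, pulses$neuron_id), function(p) {
  tr <- pyr[[p$neuron_id[1]]]
  pro <- stim_protocol(pulse_times = p$pulse_time, frequency = p$frequency_hz[1])
  psth <- suppressWarnings(build_psth(tr, pro))
  d <- duration_of_suppression(psth)
  tibble::tibble(rat_id = tr$rat_id, frequency_hz = p$frequency_hz[1],
                 dos_ms = d$dos_ms, censored = d$censored)
})) |> left_join(rats, by = "rat_id")
write.csv(dos, "results/dos_per_rat.csv", row.names = FALSE)

tab <- aggregate_to_rats(dos |> select(rat_id, group, day, frequency_hz, dos_ms),
                         within = "frequency_hz")
print(tab |> group_by(group, day, frequency_hz) |>
        summarise(dos_mean = mean(dos_ms), sem = sd(dos_ms) / sqrt(n()),
                  .groups = "drop") |> as.data.frame(), digits = 3)

# repeated measures across frequency within rat, treatment as between factor
for (d in unique(tab$day)) {
  day_tab <- tab[tab$day == d, ]
  class(day_tab) <- class(tab)
  res <- compare_groups(day_tab, "dos_ms", "twoway_rm_anova_holm_sidak",
                        factor2 = "frequency_hz")
  cat(sprintf("\nday %d, treatment x frequency RM ANOVA on DOS:\n", d))
  print(as.data.frame(res$terms), digits = 3)
}
cat("\nDOS table written to results/dos_per_rat.csv\n")
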