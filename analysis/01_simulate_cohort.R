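#!/usr/bin/env Rscript
# Step 1: simulate the full experiment cohort and write it out as a
# plain-text bundle. Three treatment groups (vehicle, venlafaxine,
# combination) at 2 and 14 days of administration, 6 rats per cell; every
# rat carries a DA track grid with one two-state bursting train per counted
# neuron, 5-HT and NE units, and one pyramidal neuron with iontophoresis,
# stimulation and cumulative WAY 100635 recordings. Ground truth is written
# alongside in truth.json.

suppressPackageStartupMessages(library(ephystat))

cfg <- sim_config(seed = 20260922)
bundle <- simulate_cohort(cfg)
out <- "results/cohort"
write_cohort(bundle, out)

cat("cohort written to", out, "\n")
cat(sprintf("  rats: %d (%d groups x %d days x %d rats)\n",
            nrow(bundle$rats), length(cfg$groups), length(cfg$days),
            cfg$n_rats_per_group))
cat(sprintf("  monoamine units: %d (DA %d, 5-HT %d, NE %d)\n",
            nrow(bundle$neuron_meta),
            sum(bundle$neuron_meta$neuron_type == "DA"),
            sum(bundle$neuron_meta$neuron_type == "5HT"),
            sum(bundle$neuron_meta$neuron_type == "NE")))
cat(sprintf("  pyramidal recordings per rat: 2 iontophoresis + 2 stimulation + 1 cumulative dosing\n"))
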