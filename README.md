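# ephystat

Spike-train analysis for in vivo pharmaco-electrophysiology in R.

Chronic-antidepressant electrophysiology experiments record extracellular
single-unit activity from ventral tegmental dopamine (DA), dorsal raphe
serotonin (5-HT), locus coeruleus norepinephrine (NE) and hippocampal CA3
pyramidal neurons, and quantify drug effects with a small, standard set of
metrics. `ephystat` implements that entire quantitative layer as tested,
reusable functions, plus point-process simulators that provide ground truth
for every estimator:

* **ISI burst detection** — two-threshold rule: a burst opens at
  ISI < 0.08 s (DA/NE; 0.01 s for 5-HT) and closes at ISI > 0.16 s
  (DA/NE; 0.01 s for 5-HT); per-neuron `%` spikes in burst and per-rat
  summaries.
* **Population activity** — mean number of spontaneously active DA neurons
  per electrode track over a 6–9 track grid.
* **Microiontophoresis indices** — RT50, the seconds from ejection offset
  to 50% recovery of baseline firing (a reuptake-transporter index), and
  IT50 = current (nA) × seconds to 50% inhibition (nC; a receptor
  sensitivity index).
* **PSTH / duration of suppression (DOS)** — 2-ms-bin peristimulus
  histograms over 200 pulses; DOS runs from the first bin ≤ 50% of the
  prestimulation mean to the first bin back at ≥ 90% of it, compared at
  1 vs 5 Hz on the same neuron.
* **Tonic activation** — percent change in pyramidal firing after an
  intravenous antagonist (e.g. cumulative WAY 100635), referenced to the
  pre-first-dose baseline.
* **Per-rat statistics** — data points for each rat are averaged before
  testing (enforced by type); one-/two-way and repeated-measures ANOVA,
  t / Mann–Whitney, Bonferroni and Holm–Šidák post-hoc families.
* **Simulators** — gamma-renewal tonic trains, two-state bursting trains
  with exact ground-truth labels, inhomogeneous-Poisson iontophoresis /
  stimulation recordings with closed-form RT50/IT50/DOS, Poisson track
  grids, and full multi-rat treatment cohorts.

## Worked example

```r
library(ephystat)

# burst detection on a hand-built DA train
st <- spike_train(c(0, 0.05, 0.10, 0.50, 1.00), 0, 2, "DA")
detect_bursts(st)
#> <burst_result> 1 bursts; 60.0% of 5 spikes in bursts

# RT50 on a simulated ejection with known truth (tau = 30 s -> 30*ln2 = 20.8 s)
ep <- ionto_epoch(100, 160, current = 20, agent = "5HT")
prof <- ionto_profile(12, ep, inhibition = "exponential",
                      recovery = "exponential", tau_recovery = 30)
tr <- simulate_iontophoresis(prof, duration = 400, seed = 1)
rt50(tr, ep, smooth = TRUE)
#> [1] 26.81429

# a full cohort: simulate -> analyze -> per-rat statistics
cfg <- sim_config(seed = 20260922)
res <- analyze_cohort(simulate_cohort(cfg))
compare_groups(res$rat_metrics, "firing_rate", "oneway_anova_bonferroni")
#> <group_comparison> oneway_anova_bonferroni on firing_rate: statistic = 11.3, p = 0.000188
```

The last line compares per-rat mean DA firing rates across the three
treatment groups (the simulated day-2 reuptake-blocker cell fires at 70%
of baseline by construction; the Bonferroni post hoc singles out that
group against both others at p < 0.02).

The `analysis/` directory holds the numbered workflow the package was
built around — simulate a cohort to plain-text files, then burst/firing,
population-activity, RT50/IT50, PSTH-suppression and tonic-activation
analyses, each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_burst_firing.R
# ... through 06_tonic_activation.R
```

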