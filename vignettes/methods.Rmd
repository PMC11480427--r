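---
title: "Methods: spike-train metrics, microiontophoresis indices and per-rat statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train metrics, microiontophoresis indices and per-rat statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephystat)
```

`ephystat` implements the quantitative core of a classical in vivo
pharmaco-electrophysiology experiment: extracellular single-unit recordings
of ventral tegmental dopamine (DA), dorsal raphe serotonin (5-HT), locus
coeruleus norepinephrine (NE) and hippocampal CA3 pyramidal neurons under
chronic antidepressant treatment. This vignette describes each estimator,
its assumptions and tunable parameters, the synthetic point-process
generators that provide ground truth, and the numerical choices made where
the verbal definitions of the field leave room.

## Spike trains and firing rate

A `spike_train` stores event times (seconds, microsecond resolution,
strictly increasing) together with explicit epoch bounds and a cell-type
label. Epoch bounds are never inferred from the spikes: a silent neuron is
a valid, informative observation when counting spontaneously active cells.
The mean firing rate divides the spike count by the *full* epoch duration,
not the first-to-last spike span, for the same reason.

## ISI burst detection

Burst firing is detected with the standard two-threshold interspike-interval
(ISI) rule: a burst opens at the first ISI strictly below the onset
threshold (0.08 s for DA and NE, 0.01 s for 5-HT), each later spike joins
while its ISI stays at or below the termination threshold (0.16 s for
DA/NE, 0.01 s for 5-HT), and the first ISI strictly above the termination
threshold closes it, after which onset scanning resumes.

Two semantic points are deliberately fixed here because the verbal rule
does not decide them:

* ISIs in the band `[onset, termination]` **extend** a burst but never
  **start** one. For 5-HT the two thresholds coincide, the band is empty,
  and a burst is simply a maximal run of ISIs below 0.01 s.
* A burst still open at the last spike closes there; no censoring flag is
  kept, because the summaries are count-based.

This makes the detector equivalent to a simple characterization that we
use as an independent test oracle: split the ISI sequence at every ISI
above the termination threshold; within each maximal surviving run, a
burst starts at the first onset-qualifying ISI and absorbs the rest of the
run. The test suite checks exact agreement on randomized sequences
spanning both thresholds.

A neuron "has burst activity" if it shows at least one burst; the per-rat
summaries average `%` spikes in burst over a rat's neurons and count the
fraction of bursting neurons — data points for each rat are averaged
before any statistics, never pooled across neurons.

## Population activity

Population activity is the mean number of spontaneously active DA neurons
per stereotaxic electrode descent, over a grid of 6–9 tracks per rat.
Tracks are treated as exchangeable counts; the simulator draws them
Poisson(λ) per track, which makes λ the recoverable ground truth and gives
the usual `sqrt(λ/n)` standard error for the design (8 tracks × 6 rats).
The rate criterion for "spontaneously active" uses the closed interval of
each type's physiological range (2–10 Hz DA, 0.5–2.5 Hz 5-HT, 0.5–5 Hz NE,
10–15 Hz quisqualate-driven pyramidal); boundary rates count as active, the
least surprising reading of a range given without strictness.

## RT50 and IT50

Both indices are ratios to the pre-ejection baseline, measured on a binned
rate trace:

* **RT50** (s): time from ejection offset until the rate first recovers to
  50% of baseline — slower recovery indicates less transmitter reuptake.
* **IT50** (nC): ejection current × time from ejection onset until the
  rate first falls to 50% of baseline — a smaller charge indicates a more
  sensitive postsynaptic receptor.

Defaults are a 2-s bin and a 60-s baseline window. At pyramidal rates of
10–15 Hz a 2-s bin holds 20–30 events, which keeps the 50% comparison
stable; the baseline window averages ~30 bins. Crossings are located by
linear interpolation between the bracketing bin centers, which removes the
half-bin quantization without any model assumption. The first crossing is
taken, not a sustained one, staying faithful to the verbal definitions.

**Why smoothing is recommended for slow recoveries.** A first-crossing
rule applied to independent noisy bins is early-biased on a slow ramp: on
an exponential recovery with τ = 30 s, roughly ten bins precede the true
50% point, and each carries a 5–40% chance that Poisson fluctuation alone
clears the threshold. The cumulative effect pulls the raw estimator several
seconds early at a 12 Hz baseline. A 3-bin moving average reduces the
per-bin standard deviation by √3 and brings the median estimate within one
bin of the closed-form value τ·ln 2; the package therefore exposes
`smooth = TRUE` and uses it in the cohort analyses. The function default
remains `smooth = FALSE` so that the estimator matches the bare definition
unless the analyst opts in; the baseline is always computed from raw bins.
The downward IT50 crossing is much less affected (the intensity falls
quickly through the threshold), but the same setting is applied for
consistency.

If firing never recovers (or never falls) to the threshold, the functions
return `NA` with an explanatory attribute rather than extrapolating; a
zero baseline is an error, since both indices are undefined.

## PSTH and duration of suppression

PSTHs accumulate spike times re-referenced to each of 200 stimulation
pulses (0.5 ms, 300 µA, 1 or 5 Hz) into 2-ms bins over a −100…+200 ms
window; at 5 Hz the post-pulse window is truncated to the 200-ms
inter-pulse interval with a warning. The prestimulation mean is the mean
count of the 50 bins before the pulse (the 100-ms prestimulation window is
a package choice; the convention fixes only the 2-ms bin).

Duration of suppression (DOS) runs from the first post-pulse bin at or
below 50% of the prestimulation mean to the first subsequent bin at or
above 90% of it, both taken at bin left edges. Single-bin crossings
qualify; an optional two-bin persistence guard for the onset is available
for noisy traces but off by default.

**Known accuracy limit of the 90% recovery rule.** With 200 pulses at a
12 Hz baseline the prestimulation mean is 4.8 events per 2-ms bin, and the
recovery threshold of 0.9 × 4.8 = 4.32 is only about half a standard
deviation below the mean of an at-baseline bin: the first recovered bin
clears it with probability ≈ 0.5. The offset therefore lands on the first
recovered bin only about half the time and drifts geometrically otherwise.
The estimator is median-unbiased (median DOS equals the true 40 ms in the
validation runs) and its mean bias stays under one bin, but per-run
accuracy to ±1 bin is achieved in only ~75–80% of runs at these counts —
an intrinsic property of the threshold definition at this event density,
not of the implementation. Materially tighter per-run accuracy would
require more pulses or a higher prestimulation rate than the protocol
provides.

## Tonic activation

Tonic receptor activation is inferred from disinhibition: the percent
change in pyramidal firing after an intravenous antagonist
(WAY 100635 for 5-HT1A, idazoxan for α2, prazosin for α1), computed as
`100·(response − baseline)/baseline`. Defaults are 60-s baseline and
response windows with the response starting 30 s after injection (skipping
the injection artifact and circulation delay); all three are configurable,
as no timing convention is universal. Cumulative dosing references every
dose's response to the *original* pre-first-dose baseline, matching
"overall change" semantics, and refuses windows that straddle another
dose. Only one tonic-activation neuron is recorded per rat, so these
values enter group statistics directly.

## Per-rat aggregation and statistics

The unit of analysis is the rat. `aggregate_to_rats()` averages metric
columns within each `(rat, group, day)` cell (optionally keeping
within-rat factors such as stimulation frequency or cumulative dose for
repeated-measures designs) and returns a table of class `rat_table`;
`compare_groups()` accepts only that class, so testing on per-neuron data
is structurally impossible, not merely discouraged.

Standard tests are delegated to `stats::t.test`, `stats::wilcox.test` and
`stats::aov` (with an `Error(rat/factor)` stratum for repeated measures).
The layer owns design dispatch, cell-size checks (≥2 rats per cell,
errors name the offending cell), and the post-hoc families: Bonferroni
pairwise t for one-way designs and Holm–Šidák step-down
(`1 − (1 − p_(i))^(m−i+1)` with a running maximum) for the two-way
designs, written out because base R's `p.adjust` offers Holm–Bonferroni
but not the Šidák step-down. Pooling the day-2 and day-14 vehicle groups
is an explicit flag, intended to be used only after a pre-test shows no
difference between them — never automatic.

Degenerate inputs are defined rather than left to chance: identical group
distributions give F = 0; zero-variance pairs with equal means report a
post-hoc p of 1.

## Synthetic data: what it emulates and what it does not

All generators are point-process level — no membrane biophysics:

* **Tonic units**: gamma-renewal trains (shape = regularity, CV = 1/√shape),
  Poisson at shape 1, clock-like at large shape.
* **Bursting units**: a two-state process — single spikes and burst onsets
  compete along the timeline, bursts carry `2 + Geometric` spikes at a
  fixed intra-burst ISI. Every inter-event gap includes a floor above the
  termination threshold, so ground-truth labels are exactly recoverable by
  the detector; a hard-mode switch removes the floor (and the guarantee)
  for stress testing. Geometric burst sizes are a modeling choice, not an
  empirical claim.
* **Iontophoresis and stimulation recordings**: inhomogeneous Poisson
  trains drawn by exact thinning from piecewise intensity profiles whose
  RT50/IT50/DOS are known in closed form (e.g. exponential recovery
  crosses 50% at τ·ln 2).
* **Cohorts**: three groups × two days × six rats by default, with
  per-cell effect multipliers whose defaults follow the direction and
  rough size of the treatment effects the design targets (reduced DA
  firing under the reuptake blocker alone at 2 days; raised population
  activity; doubled recovery time constants when a transporter is
  blocked; doubled antagonist disinhibition under the sustained
  combination). Recording lengths per neuron are not standardized in this
  literature, so they are configurable, with 120-s monoamine epochs as the
  default.

Simulated trains are stationary within segments, carry no electrode drift,
no spike-sorting contamination, no waveform information and no correlated
network activity. Passing parameter-recovery tests on these data therefore
validates the estimators and the statistical plumbing — it does not certify
performance on recordings whose noise violates Poisson/renewal assumptions.

## Problem sizes and reproducibility

The validation suite uses 10⁴ random ISI sequences for the burst oracle,
100–200 seeds for burst-label, RT50/IT50 and DOS recovery, 500 simulated
group estimates for population activity, and 2000/1000 replicates for
type-I error and power calibration of the per-rat one-way ANOVA (checked
against the closed-form noncentral-F power). Every generator accepts a
seed and restores the caller's RNG state; a cohort simulated twice from
the same configuration is byte-identical, as is the full
simulate → analyze → compare pipeline.
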