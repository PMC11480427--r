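#' Simulate a tonic (renewal-process) spike train
#'
#' Gamma-renewal process: ISIs are Gamma(shape = `regularity`,
#' rate = `regularity * rate`), so the mean ISI is `1/rate` and the ISI
#' coefficient of variation is `1/sqrt(regularity)`. `regularity = 1` gives a
#' Poisson process (irregular firing); large values give the clock-like
#' regularity typical of serotonergic and noradrenergic neurons.
#'
#' @param rate Target mean firing rate, Hz (> 0).
#' @param duration Epoch length in seconds (> 0); epoch is `[0, duration]`.
#' @param regularity Gamma shape parameter (> 0, default 1).
#' @param neuron_type,neuron_id,rat_id Passed to [spike_train()].
#' @param seed Optional integer; when given, the draw is made reproducible
#'   without disturbing the caller's RNG stream.
#' @return A [spike_train()].
#' @export
simulate_tonic_train <- function(rate, duration, regularity = 1,
                                 neuron_type = "DA", neuron_id = "n1",
                                 rat_id = "r1", seed = NULL) {
  if (rate <= 0 || duration <= 0 || regularity <= 0) {
    stop("rate, duration and regularity must be positive", call. = FALSE)
  }
  draw <- function() {
    n_max <- ceiling(rate * duration + 4 * sqrt(rate * duration) + 25)
    repeat {
      isis <- stats::rgamma(n_max, shape = regularity, rate = regularity * rate)
      t <- cumsum(isis)
      if (t[length(t)] > duration) break
      n_max <- 2 * n_max
    }
    t[t <= duration]
  }
  times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  spike_train(times, 0, duration, neuron_type, neuron_id, rat_id)
}

#' Simulate a two-state bursting train with ground-truth labels
#'
#' Events are laid down sequentially: each inter-event gap is
#' `min_gap + Exp(event_rate)` where `min_gap` exceeds the burst-termination
#' threshold, and each event is a burst (probability `p_burst`) or a single
#' spike. A burst contains `2 + Geometric` spikes (mean `burst_size_mean`)
#' at a fixed `intra_burst_isi`. Because every inter-event gap is above the
#' termination threshold and every intra-burst ISI below the onset
#' threshold, the true burst labels are recoverable exactly by the
#' two-threshold detector; `enforce_separation = FALSE` ("hard mode") drops
#' the minimum-gap floor and forfeits that guarantee.
#'
#' @param duration Seconds.
#' @param event_rate Rate of events (singles + burst onsets), events/s.
#' @param p_burst Probability that an event is a burst.
#' @param intra_burst_isi Within-burst ISI in seconds; must be strictly
#'   below the onset threshold of `neuron_type` or the bursts would be
#'   undetectable by construction (error).
#' @param burst_size_mean Mean spikes per burst (>= 2).
#' @param min_gap Floor on inter-event gaps, seconds; default is 1.5x the
#'   termination threshold.
#' @param enforce_separation Keep the `min_gap` floor (default `TRUE`).
#' @inheritParams simulate_tonic_train
#' @return A [spike_train()] with attribute `burst_label` (logical vector,
#'   `TRUE` for spikes that belong to a true burst).
#' @export
simulate_bursting_train <- function(duration, event_rate = 1, p_burst = 0.2,
                                    intra_burst_isi = 0.05, burst_size_mean = 3,
                                    min_gap = NULL, enforce_separation = TRUE,
                                    neuron_type = "DA", neuron_id = "n1",
                                    rat_id = "r1", seed = NULL) {
  params <- neuron_type_params(neuron_type)
  if (!is.na(params$burst_onset_isi) && intra_burst_isi >= params$burst_onset_isi) {
    stop("intra_burst_isi at or above the onset threshold makes bursts undetectable by construction",
         call. = FALSE)
  }
  stopifnot(burst_size_mean >= 2, duration > 0, event_rate > 0,
            p_burst >= 0, p_burst <= 1)
  if (is.null(min_gap)) min_gap <- 1.5 * params$burst_termination_isi
  if (!enforce_separation) min_gap <- 0
  draw <- function() {
    times <- numeric(0); label <- logical(0)
    t <- min_gap + stats::rexp(1, event_rate)
    while (t <= duration) {
      if (stats::runif(1) < p_burst) {
        n <- 2L + stats::rgeom(1, 1 / (burst_size_mean - 1))
        bt <- t + intra_burst_isi * (seq_len(n) - 1L)
        bt <- bt[bt <= duration]
        # a burst truncated to a lone spike at the epoch edge is just a single
        times <- c(times, bt); label <- c(label, rep(length(bt) >= 2L, length(bt)))
        t <- max(bt)
      } else {
        times <- c(times, t); label <- c(label, FALSE)
      }
      t <- t + min_gap + stats::rexp(1, event_rate)
    }
    list(times = times, label = label)
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  st <- spike_train(res$times, 0, duration, neuron_type, neuron_id, rat_id)
  attr(st, "burst_label") <- res$label
  st
}

# Inhomogeneous Poisson process on [0, duration] by thinning; rate_fn must be
# bounded above by rate_max. Exact for bounded intensities.
rpoisson_inhom <- function(rate_fn, rate_max, duration) {
  n <- stats::rpois(1, rate_max * duration)
  cand <- sort(stats::runif(n, 0, duration))
  keep <- stats::runif(length(cand)) < rate_fn(cand) / rate_max
  # events are stored at microsecond resolution; coincident draws collapse
  # to one spike (an absolute refractory period of 1 us)
  unique(round(cand[keep], 6))
}

#' Intensity profile of an iontophoresis recording
#'
#' Builds the deterministic firing-intensity function of a simulated
#' ejection experiment: baseline before the ejection, inhibition during it
#' (linear ramp to zero over `decline_duration`, or exponential decay with
#' time constant `tau_inhibition`), and recovery after it (linear ramp at
#' `recovery_rate_hz_per_s`, or exponential approach with `tau_recovery`).
#' The true RT50 and IT50 of the profile are available in closed form:
#' exponential recovery crosses 50% at `tau_recovery * log(2)`; linear
#' recovery at `0.5 * baseline / recovery_rate_hz_per_s`; exponential
#' decline at `tau_inhibition * log(2)`; linear decline at
#' `decline_duration / 2`.
#'
#' @param baseline_rate Hz.
#' @param epoch An [ionto_epoch()].
#' @param inhibition `"exponential"` or `"linear"`.
#' @param recovery `"exponential"` or `"linear"`.
#' @param tau_inhibition,tau_recovery Time constants, seconds.
#' @param decline_duration Seconds to reach zero under linear inhibition.
#' @param recovery_rate_hz_per_s Hz/s slope of linear recovery.
#' @return A list of class `ionto_profile` with elements `rate_fn`,
#'   `rate_max`, `true_rt50`, `true_it50` (nC).
#' @export
ionto_profile <- function(baseline_rate, epoch,
                          inhibition = c("exponential", "linear"),
                          recovery = c("exponential", "linear"),
                          tau_inhibition = 10, tau_recovery = 30,
                          decline_duration = 10, recovery_rate_hz_per_s = 1) {
  inhibition <- match.arg(inhibition)
  recovery <- match.arg(recovery)
  stopifnot(baseline_rate > 0, inherits(epoch, "ionto_epoch"))
  on <- epoch$ejection_onset; off <- epoch$ejection_offset
  rate_fn <- function(t) {
    r <- rep(baseline_rate, length(t))
    inh <- t >= on & t < off
    r[inh] <- if (inhibition == "exponential") {
      baseline_rate * exp(-(t[inh] - on) / tau_inhibition)
    } else {
      pmax(0, baseline_rate * (1 - (t[inh] - on) / decline_duration))
    }
    rec <- t >= off
    r[rec] <- if (recovery == "exponential") {
      baseline_rate * (1 - exp(-(t[rec] - off) / tau_recovery))
    } else {
      pmin(baseline_rate, recovery_rate_hz_per_s * (t[rec] - off))
    }
    r
  }
  t50_inh <- if (inhibition == "exponential") tau_inhibition * log(2) else decline_duration / 2
  true_rt50 <- if (recovery == "exponential") tau_recovery * log(2) else
    0.5 * baseline_rate / recovery_rate_hz_per_s
  structure(list(rate_fn = rate_fn, rate_max = baseline_rate,
                 true_rt50 = true_rt50,
                 true_it50 = epoch$current * t50_inh),
            class = "ionto_profile")
}

#' Simulate an iontophoresis recording
#'
#' Inhomogeneous Poisson spike train (exact thinning) whose intensity
#' follows an [ionto_profile()], so the true RT50/IT50 are known in closed
#' form for estimator validation.
#'
#' @param profile An [ionto_profile()].
#' @param duration Total recording length, seconds.
#' @inheritParams simulate_tonic_train
#' @return A [spike_train()] with attributes `true_rt50` and `true_it50`.
#' @export
simulate_iontophoresis <- function(profile, duration, neuron_id = "p1",
                                   rat_id = "r1", seed = NULL) {
  stopifnot(inherits(profile, "ionto_profile"), duration > 0)
  draw <- function() rpoisson_inhom(profile$rate_fn, profile$rate_max, duration)
  times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  st <- spike_train(times, 0, duration, "PYR", neuron_id, rat_id)
  attr(st, "true_rt50") <- profile$true_rt50
  attr(st, "true_it50") <- profile$true_it50
  st
}

#' Simulate a stimulation (PSTH) experiment
#'
#' Baseline-rate Poisson firing with the intensity set to zero for
#' `suppression_s` seconds after each pulse, then stepped back — so the true
#' duration of suppression equals `suppression_s` exactly. Implemented by
#' thinning with an indicator intensity (exact).
#'
#' @param baseline_rate Hz.
#' @param suppression_s True suppression duration, seconds; must be shorter
#'   than the inter-pulse interval.
#' @param protocol A [stim_protocol()].
#' @param tail_s Recording time appended after the last pulse (default 5 s).
#' @inheritParams simulate_tonic_train
#' @return A list with elements `train` (a [spike_train()] with attribute
#'   `true_dos_ms`) and `protocol`.
#' @export
simulate_stimulation_experiment <- function(baseline_rate, suppression_s,
                                            protocol = stim_protocol(),
                                            tail_s = 5, neuron_id = "p1",
                                            rat_id = "r1", seed = NULL) {
  stopifnot(baseline_rate > 0, suppression_s >= 0,
            inherits(protocol, "stim_protocol"))
  ipi <- if (protocol$n_pulses > 1) min(diff(protocol$pulse_times)) else Inf
  if (suppression_s >= ipi) {
    stop("suppression duration must be shorter than the inter-pulse interval",
         call. = FALSE)
  }
  duration <- max(protocol$pulse_times) + tail_s
  pt <- protocol$pulse_times
  rate_fn <- function(t) {
    idx <- findInterval(t, pt)
    suppressed <- idx >= 1 & (t - pt[pmax(idx, 1)]) < suppression_s
    ifelse(suppressed, 0, baseline_rate)
  }
  draw <- function() rpoisson_inhom(rate_fn, baseline_rate, duration)
  times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  st <- spike_train(times, 0, duration, "PYR", neuron_id, rat_id)
  attr(st, "true_dos_ms") <- 1000 * suppression_s
  list(train = st, protocol = protocol)
}

#' Simulate a per-rat track grid of active-neuron counts
#'
#' Per-track counts of spontaneously active neurons are drawn
#' Poisson(`lambda`) — the standard model for cells encountered per
#' electrode descent — over `n_tracks` exchangeable tracks.
#'
#' @param lambda True mean neurons per track.
#' @param n_tracks Tracks in the grid (default 8).
#' @param rat_id Identifier.
#' @inheritParams simulate_tonic_train
#' @return A [track_grid()] with attribute `true_lambda`.
#' @export
simulate_track_grid <- function(lambda, n_tracks = 8, rat_id = "r1", seed = NULL) {
  stopifnot(lambda >= 0, n_tracks >= 1)
  draw <- function() stats::rpois(n_tracks, lambda)
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  g <- track_grid(rat_id, counts)
  attr(g, "true_lambda") <- lambda
  g
}
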