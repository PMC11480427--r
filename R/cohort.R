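#' Simulation configuration for a multi-rat treatment cohort
#'
#' Encodes the study design the simulator emulates: treatment groups by
#' days-of-administration, n rats per group, cell-type firing parameters,
#' the per-rat recording menu (DA/5-HT/NE units across a 6-9 track grid;
#' one pyramidal neuron per rat for iontophoresis, stimulation and
#' tonic-activation tests), and per-(group, day) effect multipliers.
#' Default effect sizes follow the direction and approximate magnitude of
#' the treatment effects the study design targets (e.g. a 30% drop in DA
#' firing under the reuptake blocker alone at day 2, restored by the
#' combination; a doubled RT50 when reuptake is blocked; doubled
#' antagonist disinhibition under sustained combination); see
#' [default_effects()] and the methods vignette.
#'
#' @param seed Integer seed; mandatory (every bundle must be reproducible).
#' @param n_rats_per_group Rats per (group, day) cell (default 6).
#' @param groups Character vector of treatment groups.
#' @param days Days of administration (default `c(2, 14)`).
#' @param effects Effect-multiplier table from [default_effects()].
#' @param da_rate,ht5_rate,ne_rate,pyr_rate Baseline mean rates, Hz.
#' @param da_p_burst Probability that a DA event is a burst (two-state
#'   generator).
#' @param n_ht5,n_ne 5-HT and NE units recorded per rat.
#' @param train_duration Monoamine recording length, seconds.
#' @param track_lambda True mean spontaneously active DA neurons per track.
#' @param tau_recovery_5ht,tau_recovery_ne Baseline post-ejection recovery
#'   time constants, seconds.
#' @param tau_inhibition Ejection inhibition time constant, seconds.
#' @param ionto_current Ejection current, nA (default 20).
#' @param suppression_ms_1hz,suppression_ms_5hz True DOS at the two
#'   stimulation frequencies, ms.
#' @param way_doses Cumulative WAY 100635 doses, ug/kg.
#' @param way_multipliers Saturating intensity multipliers after each
#'   cumulative dose (baseline tonic-activation effect).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_rats_per_group = 6,
                       groups = c("vehicle", "venlafaxine", "combination"),
                       days = c(2, 14),
                       effects = default_effects(),
                       da_rate = 4.5, ht5_rate = 1.2, ne_rate = 2.5,
                       pyr_rate = 12,
                       da_p_burst = 0.2, n_ht5 = 5, n_ne = 5,
                       train_duration = 120,
                       track_lambda = 1.2,
                       tau_recovery_5ht = 30, tau_recovery_ne = 30,
                       tau_inhibition = 10, ionto_current = 20,
                       suppression_ms_1hz = 50, suppression_ms_5hz = 35,
                       way_doses = c(25, 50, 75, 100),
                       way_multipliers = c(1.1, 1.18, 1.23, 1.25)) {
  if (missing(seed)) stop("sim_config() requires an explicit seed", call. = FALSE)
  stopifnot(n_rats_per_group >= 1, length(groups) >= 1, length(days) >= 1,
            all(c(da_rate, ht5_rate, ne_rate, pyr_rate, train_duration,
                  track_lambda, tau_recovery_5ht, tau_recovery_ne,
                  tau_inhibition, ionto_current) > 0),
            length(way_doses) == length(way_multipliers))
  structure(as.list(environment()), class = "sim_config")
}

#' Default per-(group, day) effect multipliers
#'
#' Multipliers applied to the baseline simulation parameters for each
#' treatment cell. `1` means no effect. Columns: `rate_mult` (monoamine
#' firing rate), `burst_mult` (burst probability), `lambda_mult`
#' (active DA neurons per track), `rt50_5ht_mult`/`rt50_ne_mult`
#' (recovery time constants, i.e. reuptake blockade), `disinhibition_mult`
#' (scaling of the antagonist-induced firing increase), `dos_mult`
#' (suppression duration).
#'
#' @return A tibble with one row per (group, day).
#' @export
default_effects <- function() {
  tibble::tribble(
    ~group,         ~day, ~rate_mult, ~burst_mult, ~lambda_mult,
    ~rt50_5ht_mult, ~rt50_ne_mult, ~disinhibition_mult, ~dos_mult,
    "vehicle",       2,  1.00, 1.00, 1.00, 1.0, 1.0, 1.0, 1.0,
    "vehicle",      14,  1.00, 1.00, 1.00, 1.0, 1.0, 1.0, 1.0,
    "venlafaxine",   2,  0.70, 0.67, 1.00, 2.0, 2.7, 1.0, 1.0,
    "venlafaxine",  14,  1.00, 1.00, 1.60, 2.0, 1.0, 1.0, 1.0,
    "combination",   2,  1.00, 1.37, 1.60, 2.0, 1.0, 1.0, 1.0,
    "combination",  14,  1.00, 1.47, 1.60, 2.0, 1.0, 2.0, 1.0
  )
}

cfg_effect <- function(config, group, day) {
  e <- config$effects[config$effects$group == group & config$effects$day == day, ]
  if (nrow(e) == 0) {
    e <- config$effects[1, ]
    e[1, -(1:2)] <- 1
  }
  as.list(e[1, ])
}

# step-function disinhibition train: baseline_rate before the first dose,
# baseline_rate * mult_i after dose i (exact thinning)
simulate_dose_response_train <- function(baseline_rate, dose_times, multipliers,
                                         duration, neuron_id = "p1",
                                         rat_id = "r1", seed = NULL) {
  stopifnot(length(dose_times) == length(multipliers),
            !is.unsorted(dose_times, strictly = TRUE), baseline_rate > 0)
  mults <- c(1, multipliers)
  rate_fn <- function(t) baseline_rate * mults[findInterval(t, dose_times) + 1L]
  rmax <- baseline_rate * max(mults)
  draw <- function() rpoisson_inhom(rate_fn, rmax, duration)
  times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  st <- spike_train(times, 0, duration, "PYR", neuron_id, rat_id)
  attr(st, "true_multipliers") <- multipliers
  st
}

#' Simulate a complete experiment cohort
#'
#' Generates, for every rat of every (group, day) cell: a 6-9 track grid of
#' spontaneously active DA neuron counts with one two-state bursting DA
#' train per counted neuron; regular 5-HT and NE renewal trains; and one
#' pyramidal neuron carrying a 5-HT and an NE iontophoretic ejection, 1 Hz
#' and 5 Hz stimulation experiments, and a cumulative WAY 100635 dosing
#' record (one tonic-activation neuron per rat). All ground-truth
#' parameters are returned alongside in `$truth`. Identical `config`
#' (including its seed) gives a byte-identical bundle.
#'
#' @param config A [sim_config()].
#' @return A list of class `cohort_bundle`; see Details in the vignette.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  rats <- expand.grid(rep = seq_len(config$n_rats_per_group),
                      day = config$days, group = config$groups,
                      stringsAsFactors = FALSE)
  rats$rat_id <- sprintf("%s_d%d_r%d", rats$group, rats$day, rats$rep)

  trains <- list(); neuron_meta <- list()
  grids <- list(); ionto <- list(); stim <- list(); tonic <- list()
  truth_rat <- list()

  for (i in seq_len(nrow(rats))) {
    rid <- rats$rat_id[i]; grp <- rats$group[i]; day <- rats$day[i]
    eff <- cfg_effect(config, grp, day)

    # -- DA population: grid of tracks, one bursting train per counted neuron
    n_tracks <- sample(6:9, 1)
    lam <- config$track_lambda * eff$lambda_mult
    grid <- simulate_track_grid(lam, n_tracks, rat_id = rid)
    grids[[rid]] <- grid
    n_da <- sum(grid$neurons_per_track)
    rate_da <- config$da_rate * eff$rate_mult
    p_burst <- min(1, config$da_p_burst * eff$burst_mult)
    for (k in seq_len(n_da)) {
      nid <- sprintf("%s_DA%02d", rid, k)
      # event_rate chosen so the overall rate is close to the target:
      # mean spikes/event = (1 - p) * 1 + p * burst_size_mean, and each
      # inter-event gap carries the min_gap floor plus the burst duration
      spe <- (1 - p_burst) + p_burst * 3
      gap_overhead <- 1.5 * 0.16 + p_burst * 2 * 0.05
      ev_rate <- 1 / max(spe / rate_da - gap_overhead, 0.05)
      tr <- simulate_bursting_train(config$train_duration, event_rate = ev_rate,
                                    p_burst = p_burst, neuron_type = "DA",
                                    neuron_id = nid, rat_id = rid)
      trains[[nid]] <- tr
      neuron_meta[[nid]] <- tibble::tibble(neuron_id = nid, rat_id = rid,
                                           group = grp, day = day,
                                           neuron_type = "DA")
    }

    # -- 5-HT and NE units: regular renewal trains, occasional bursts via
    #    a small burst probability for NE (5-HT bursts need sub-10 ms ISIs)
    for (k in seq_len(config$n_ht5)) {
      nid <- sprintf("%s_5HT%02d", rid, k)
      tr <- simulate_tonic_train(config$ht5_rate * eff$rate_mult,
                                 config$train_duration, regularity = 16,
                                 neuron_type = "5HT", neuron_id = nid, rat_id = rid)
      trains[[nid]] <- tr
      neuron_meta[[nid]] <- tibble::tibble(neuron_id = nid, rat_id = rid,
                                           group = grp, day = day,
                                           neuron_type = "5HT")
    }
    for (k in seq_len(config$n_ne)) {
      nid <- sprintf("%s_NE%02d", rid, k)
      ne_rate <- config$ne_rate * eff$rate_mult
      ev_ne <- 1 / max(1.2 / ne_rate - (1.5 * 0.16 + 0.1 * 2 * 0.05), 0.05)
      tr <- simulate_bursting_train(config$train_duration, event_rate = ev_ne,
                                    p_burst = 0.1, neuron_type = "NE",
                                    neuron_id = nid, rat_id = rid)
      trains[[nid]] <- tr
      neuron_meta[[nid]] <- tibble::tibble(neuron_id = nid, rat_id = rid,
                                           group = grp, day = day,
                                           neuron_type = "NE")
    }

    # -- pyramidal neuron: iontophoresis (5-HT, NE), stimulation, WAY dosing
    ionto[[rid]] <- list()
    for (agent in c("5HT", "NE")) {
      tau_rec <- if (agent == "5HT") config$tau_recovery_5ht * eff$rt50_5ht_mult
                 else config$tau_recovery_ne * eff$rt50_ne_mult
      ep <- ionto_epoch(100, 160, config$ionto_current, agent)
      prof <- ionto_profile(config$pyr_rate, ep,
                            inhibition = "exponential", recovery = "exponential",
                            tau_inhibition = config$tau_inhibition,
                            tau_recovery = tau_rec)
      tr <- simulate_iontophoresis(prof, duration = 160 + 6 * tau_rec,
                                   neuron_id = sprintf("%s_PYR_%s", rid, agent),
                                   rat_id = rid)
      ionto[[rid]][[agent]] <- list(train = tr, epoch = ep,
                                    true_rt50 = prof$true_rt50,
                                    true_it50 = prof$true_it50)
    }
    stim[[rid]] <- list()
    for (f in c(1, 5)) {
      supp <- (if (f == 1) config$suppression_ms_1hz else config$suppression_ms_5hz) *
        eff$dos_mult / 1000
      pro <- stim_protocol(n_pulses = 200, frequency = f)
      ex <- simulate_stimulation_experiment(config$pyr_rate, supp, pro,
                                            neuron_id = sprintf("%s_PYR_stim", rid),
                                            rat_id = rid)
      stim[[rid]][[paste0("f", f)]] <- ex
    }
    mults <- 1 + (config$way_multipliers - 1) * eff$disinhibition_mult
    dose_times <- 300 + 180 * (seq_along(config$way_doses) - 1)
    way_train <- simulate_dose_response_train(
      config$pyr_rate, dose_times, mults,
      duration = max(dose_times) + 180,
      neuron_id = sprintf("%s_PYR_way", rid), rat_id = rid)
    doses <- lapply(seq_along(config$way_doses), function(j) {
      dose_event(dose_times[j], "WAY100635", config$way_doses[j], j)
    })
    tonic[[rid]] <- list(train = way_train, doses = doses,
                         true_multipliers = mults)

    truth_rat[[rid]] <- list(group = grp, day = day,
                             track_lambda = lam, da_rate = rate_da,
                             p_burst = p_burst,
                             true_dos_ms = c(f1 = config$suppression_ms_1hz,
                                             f5 = config$suppression_ms_5hz) * eff$dos_mult,
                             disinhibition = mults)
  }

  structure(
    list(rats = tibble::as_tibble(rats[, c("rat_id", "group", "day")]),
         trains = trains,
         neuron_meta = dplyr::bind_rows(neuron_meta),
         grids = grids, ionto = ionto, stim = stim, tonic = tonic,
         truth = truth_rat, config = config),
    class = "cohort_bundle"
  )
}

#' Run the full analysis pipeline over a simulated (or assembled) cohort
#'
#' Computes every study metric from the raw event times in a bundle:
#' per-neuron firing rate and burst statistics (per cell type), per-rat
#' population activity, RT50/IT50 per agent, 1/5 Hz suppression durations
#' and cumulative WAY 100635 percent-change curves. Purely deterministic:
#' the same bundle always yields identical tables.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param rt_smooth Use the 3-bin smoothed crossing search for RT50/IT50
#'   (default `TRUE`, the recommended configuration; see the vignette).
#' @return A list of tibbles: `neuron_metrics`, `rat_metrics` (class
#'   `rat_table`), `population`, `ionto`, `dos`, `tonic`.
#' @export
analyze_cohort <- function(bundle, rt_smooth = TRUE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  meta <- bundle$neuron_meta

  nm <- lapply(seq_len(nrow(meta)), function(i) {
    tr <- bundle$trains[[meta$neuron_id[i]]]
    br <- detect_bursts(tr)
    dplyr::bind_cols(meta[i, ],
                     tibble::tibble(firing_rate = mean_firing_rate(tr),
                                    pct_spikes_in_burst = br$pct_spikes_in_burst,
                                    has_burst = br$has_burst))
  })
  neuron_metrics <- dplyr::bind_rows(nm)
  neuron_metrics$pct_neurons_with_burst <- 100 * as.numeric(neuron_metrics$has_burst)

  rat_metrics <- aggregate_to_rats(
    neuron_metrics[neuron_metrics$neuron_type == "DA",
                   c("rat_id", "group", "day", "firing_rate",
                     "pct_spikes_in_burst", "pct_neurons_with_burst")])

  population <- dplyr::bind_rows(lapply(names(bundle$grids), function(rid) {
    tibble::tibble(rat_id = rid,
                   population_activity = population_activity(bundle$grids[[rid]]))
  }))
  population <- dplyr::left_join(population, bundle$rats, by = "rat_id")

  ionto <- dplyr::bind_rows(lapply(names(bundle$ionto), function(rid) {
    dplyr::bind_rows(lapply(names(bundle$ionto[[rid]]), function(agent) {
      rec <- bundle$ionto[[rid]][[agent]]
      tibble::tibble(rat_id = rid, agent = agent,
                     rt50 = as.numeric(rt50(rec$train, rec$epoch, smooth = rt_smooth)),
                     it50 = as.numeric(it50(rec$train, rec$epoch, smooth = rt_smooth)),
                     true_rt50 = rec$true_rt50, true_it50 = rec$true_it50)
    }))
  }))
  ionto <- dplyr::left_join(ionto, bundle$rats, by = "rat_id")

  dos <- dplyr::bind_rows(lapply(names(bundle$stim), function(rid) {
    p1 <- build_psth(bundle$stim[[rid]]$f1$train, bundle$stim[[rid]]$f1$protocol)
    p5 <- suppressWarnings(
      build_psth(bundle$stim[[rid]]$f5$train, bundle$stim[[rid]]$f5$protocol))
    cf <- compare_frequencies(p1, p5)
    tibble::tibble(rat_id = rid, dos_1hz_ms = cf$dos_1hz_ms, dos_5hz_ms = cf$dos_5hz_ms)
  }))
  dos <- dplyr::left_join(dos, bundle$rats, by = "rat_id")

  tonic <- dplyr::bind_rows(lapply(names(bundle$tonic), function(rid) {
    rec <- bundle$tonic[[rid]]
    curve <- cumulative_dose_curve(rec$train, rec$doses)
    dplyr::bind_cols(tibble::tibble(rat_id = rid), curve,
                     tibble::tibble(overall_pct_change = mean(curve$pct_change)))
  }))
  tonic <- dplyr::left_join(tonic, bundle$rats, by = "rat_id")

  list(neuron_metrics = neuron_metrics, rat_metrics = rat_metrics,
       population = population, ionto = ionto, dos = dos, tonic = tonic)
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Produces `trains.csv` (one row per spike, monoamine units),
#' `pyramidal_trains.csv`, `grids.csv` (`rat_id, track_index,
#' n_active_neurons`), `epochs.csv`, `pulses.csv`, `doses.csv` and
#' `truth.json`, so a bundle can be consumed file-by-file and round-tripped
#' through [read_spiketrains()].
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$rats, file.path(dir, "rats.csv"),
                   row.names = FALSE, quote = FALSE)
  write_spiketrains(bundle$trains, file.path(dir, "trains.csv"))

  pyr <- list()
  for (rid in names(bundle$ionto)) {
    for (agent in names(bundle$ionto[[rid]])) {
      tr <- bundle$ionto[[rid]][[agent]]$train
      pyr[[tr$neuron_id]] <- tr
    }
    for (f in names(bundle$stim[[rid]])) {
      tr <- bundle$stim[[rid]][[f]]$train
      pyr[[paste0(tr$neuron_id, "_", f)]] <- tr
    }
    pyr[[bundle$tonic[[rid]]$train$neuron_id]] <- bundle$tonic[[rid]]$train
  }
  # stim trains at both frequencies share a neuron id; disambiguate
  pyr <- lapply(names(pyr), function(nm) {
    tr <- pyr[[nm]]; tr$neuron_id <- nm; tr
  })
  write_spiketrains(pyr, file.path(dir, "pyramidal_trains.csv"))

  grids <- dplyr::bind_rows(lapply(bundle$grids, function(g) {
    tibble::tibble(rat_id = g$rat_id, track_index = seq_len(g$track_count),
                   n_active_neurons = g$neurons_per_track)
  }))
  utils::write.csv(grids, file.path(dir, "grids.csv"), row.names = FALSE, quote = FALSE)

  epochs <- dplyr::bind_rows(lapply(names(bundle$ionto), function(rid) {
    dplyr::bind_rows(lapply(names(bundle$ionto[[rid]]), function(agent) {
      e <- bundle$ionto[[rid]][[agent]]$epoch
      tibble::tibble(neuron_id = bundle$ionto[[rid]][[agent]]$train$neuron_id,
                     onset = e$ejection_onset, offset = e$ejection_offset,
                     current_nA = e$current, agent = e$agent)
    }))
  }))
  utils::write.csv(epochs, file.path(dir, "epochs.csv"), row.names = FALSE, quote = FALSE)

  pulses <- dplyr::bind_rows(lapply(names(bundle$stim), function(rid) {
    dplyr::bind_rows(lapply(names(bundle$stim[[rid]]), function(f) {
      pro <- bundle$stim[[rid]][[f]]$protocol
      tibble::tibble(neuron_id = paste0(bundle$stim[[rid]][[f]]$train$neuron_id, "_", f),
                     frequency_hz = pro$frequency, pulse_time = pro$pulse_times)
    }))
  }))
  utils::write.csv(pulses, file.path(dir, "pulses.csv"), row.names = FALSE, quote = FALSE)

  doses <- dplyr::bind_rows(lapply(names(bundle$tonic), function(rid) {
    dplyr::bind_rows(lapply(bundle$tonic[[rid]]$doses, function(d) {
      tibble::tibble(neuron_id = bundle$tonic[[rid]]$train$neuron_id,
                     time = d$time, drug = d$drug, dose = d$dose,
                     units = "ug/kg", cumulative_index = d$cumulative_index)
    }))
  }))
  utils::write.csv(doses, file.path(dir, "doses.csv"), row.names = FALSE, quote = FALSE)

  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
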