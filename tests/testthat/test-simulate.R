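test_that("gamma-renewal trains hit their rate and regularity", {
  st <- simulate_tonic_train(1, 400, regularity = 100, seed = 1)
  isi <- interspike_intervals(st)
  expect_lt(abs(mean(isi) - 1), 0.05)
  expect_lt(abs(sd(isi) / mean(isi) - 0.1), 0.05)  # CV = 1/sqrt(shape)

  # long-run rate error below 2% at modest rates
  st2 <- simulate_tonic_train(0.5, 1000, regularity = 4, seed = 2)
  expect_lt(abs(mean_firing_rate(st2) - 0.5) / 0.5, 0.06)
  err <- vapply(1:20, function(s) {
    abs(mean_firing_rate(simulate_tonic_train(2, 1000, 4, seed = s)) - 2) / 2
  }, numeric(1))
  expect_lt(median(err), 0.02)
})

test_that("shape-1 renewal ISIs are exponential (KS at alpha = 0.01)", {
  for (s in c(10, 20, 30)) {
    st <- simulate_tonic_train(3, 500, regularity = 1, seed = s)
    ks <- suppressWarnings(ks.test(interspike_intervals(st), "pexp", 3))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("identical seeds give identical draws; invalid parameters error", {
  a <- simulate_tonic_train(2, 100, 4, seed = 9)
  b <- simulate_tonic_train(2, 100, 4, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_tonic_train(-1, 10), "positive")
  expect_error(simulate_tonic_train(1, 10, -2), "positive")
})

test_that("two-state trains carry exactly recoverable burst labels", {
  st <- simulate_bursting_train(300, event_rate = 1.5, p_burst = 0.3,
                                intra_burst_isi = 0.05, seed = 42)
  lab <- attr(st, "burst_label")
  det <- detect_bursts(st)
  got <- rep(FALSE, n_spikes(st))
  for (i in seq_len(nrow(det$bursts))) {
    got[det$bursts$start_index[i]:det$bursts$end_index[i]] <- TRUE
  }
  expect_identical(got, lab)

  # burst probability zero reduces to a tonic, burst-free train
  st0 <- simulate_bursting_train(200, event_rate = 2, p_burst = 0, seed = 4)
  expect_equal(detect_bursts(st0)$pct_spikes_in_burst, 0)

  # undetectable-by-construction configurations are rejected
  expect_error(simulate_bursting_train(100, intra_burst_isi = 0.1),
               "undetectable")
})

test_that("stimulation simulator enforces the inter-pulse bound and truth", {
  expect_error(simulate_stimulation_experiment(12, 0.25, stim_protocol(frequency = 5)),
               "inter-pulse")
  ex <- simulate_stimulation_experiment(12, 0, stim_protocol(n_pulses = 50), seed = 3)
  psth <- build_psth(ex$train, ex$protocol)
  expect_equal(attr(ex$train, "true_dos_ms"), 0)
  # with no true suppression a single-bin noise dip can still trigger a
  # transient onset; any detected suppression must be at most two bins
  expect_lte(duration_of_suppression(psth)$dos_ms, 4)
})

test_that("cohort bundles are deterministic and internally consistent", {
  cfg <- sim_config(seed = 77, n_rats_per_group = 2,
                    groups = c("vehicle", "combination"), days = 2,
                    n_ht5 = 2, n_ne = 2, train_duration = 60)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1, b2)

  # every simulated neuron is listed, labeled, and within its rat
  expect_setequal(names(b1$trains), b1$neuron_meta$neuron_id)
  expect_true(all(b1$neuron_meta$rat_id %in% b1$rats$rat_id))
  # one tonic-activation pyramidal neuron per rat
  expect_setequal(names(b1$tonic), b1$rats$rat_id)
  # grids respect the 6-9 track protocol
  expect_true(all(vapply(b1$grids, function(g) g$track_count, numeric(1)) %in% 6:9))
})

test_that("cohort bundles round-trip through the fixture formats", {
  cfg <- sim_config(seed = 5, n_rats_per_group = 1, groups = "vehicle",
                    days = 2, n_ht5 = 1, n_ne = 1, train_duration = 30)
  b <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_true(all(file.exists(file.path(dir, c("trains.csv", "pyramidal_trains.csv",
                                               "grids.csv", "epochs.csv",
                                               "pulses.csv", "doses.csv",
                                               "truth.json")))))
  back <- read_spiketrains(file.path(dir, "trains.csv"))
  expect_setequal(names(back), names(b$trains))
  nid <- names(b$trains)[1]
  expect_equal(back[[nid]]$times, b$trains[[nid]]$times)
  expect_equal(back[[nid]]$epoch_end, b$trains[[nid]]$epoch_end)
})

test_that("analyze_cohort is deterministic given a bundle", {
  cfg <- sim_config(seed = 11, n_rats_per_group = 2,
                    groups = c("vehicle", "combination"), days = 2,
                    n_ht5 = 1, n_ne = 1, train_duration = 60)
  b <- simulate_cohort(cfg)
  r1 <- analyze_cohort(b)
  r2 <- analyze_cohort(b)
  expect_identical(r1, r2)
  # per-rat table carries the aggregation contract
  expect_s3_class(r1$rat_metrics, "rat_table")
})
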