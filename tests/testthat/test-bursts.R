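da <- neuron_type_params("DA")

test_that("hand-traced burst examples are reproduced", {
  # one burst of spikes 1-3 (ISIs 0.05 opens, 0.05 joins, 0.40 closes)
  r <- detect_bursts(make_train(c(0, 0.05, 0.10, 0.50, 1.00), 2), da)
  expect_equal(nrow(r$bursts), 1L)
  expect_equal(r$bursts$start_index, 1L)
  expect_equal(r$bursts$end_index, 3L)
  expect_equal(r$pct_spikes_in_burst, 60)
  expect_true(r$has_burst)

  # all ISIs above onset: no bursts
  r2 <- detect_bursts(make_train(c(0, 0.5, 1.0, 1.5), 2), da)
  expect_equal(nrow(r2$bursts), 0L)
  expect_equal(r2$pct_spikes_in_burst, 0)
  expect_false(r2$has_burst)

  # ISIs 0.07, 0.12, 0.07: the 0.12 (in the [onset, termination] band)
  # extends the burst, the trailing 0.07 keeps it open -> all spikes burst
  r3 <- detect_bursts(make_train(c(0, 0.07, 0.19, 0.26), 1), da)
  expect_equal(r3$pct_spikes_in_burst, 100)
  expect_equal(r3$bursts$n_spikes, 4L)

  # 5-HT: onset = termination = 0.01; 0.02 ISIs never start a burst
  ht <- neuron_type_params("5HT")
  r4 <- detect_bursts(make_train(cumsum(rep(0.02, 10)), 1, "5HT"), ht)
  expect_false(r4$has_burst)
})

test_that("trains with fewer than two spikes yield empty burst results", {
  expect_false(detect_bursts(make_train(0.5, 1), da)$has_burst)
  expect_equal(detect_bursts(spike_train(numeric(0), 0, 1, "DA"), da)$pct_spikes_in_burst, 0)
})

test_that("detector matches the exhaustive run-decomposition oracle", {
  # property-based: random ISI sequences spanning both thresholds
  vals <- c(0.005, 0.05, 0.12, 0.2)
  withr::with_seed(101, {
    for (rep in 1:2000) {
      len <- sample(1:12, 1)
      isi <- sample(vals, len, replace = TRUE)
      st <- make_train(times_from_isi(isi), sum(isi) + 1)
      got <- detect_bursts(st, da)$bursts
      want <- oracle_bursts(isi, da$burst_onset_isi, da$burst_termination_isi)
      expect_identical(got$start_index, want$start_index)
      expect_identical(got$end_index, want$end_index)
    }
  })
})

test_that("bursts are disjoint, ordered, and contiguous in spike indices", {
  withr::with_seed(55, {
    for (rep in 1:50) {
      isi <- runif(80, 0.01, 0.3)
      st <- make_train(times_from_isi(isi), sum(isi) + 1)
      b <- detect_bursts(st, da)$bursts
      if (nrow(b) >= 1) {
        expect_true(all(b$n_spikes >= 2))
        expect_true(all(b$end_index - b$start_index + 1L == b$n_spikes))
      }
      if (nrow(b) >= 2) {
        expect_true(all(diff(b$start_index) > 0))
        expect_true(all(b$start_index[-1] > b$end_index[-nrow(b)]))
      }
    }
  })
})

test_that("raising the onset threshold never decreases the burst fraction", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      isi <- runif(60, 0.01, 0.3)
      st <- make_train(times_from_isi(isi), sum(isi) + 1)
      onsets <- c(0.02, 0.05, 0.08, 0.12, 0.16)
      pct <- vapply(onsets, function(on) {
        p <- neuron_type_params("DA", burst_onset_isi = on,
                                burst_termination_isi = 0.16)
        detect_bursts(st, p)$pct_spikes_in_burst
      }, numeric(1))
      expect_true(all(diff(pct) >= 0))
    }
  })
})

test_that("onset-qualifying ISI fraction of a Poisson train matches theory", {
  # P(ISI < onset) = 1 - exp(-rate * onset) for a homogeneous Poisson train
  rate <- 5; onset <- 0.08
  st <- simulate_tonic_train(rate, 2000, regularity = 1, seed = 17)
  isi <- interspike_intervals(st)
  p_hat <- mean(isi < onset)
  p_true <- 1 - exp(-rate * onset)
  se <- sqrt(p_true * (1 - p_true) / length(isi))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("per-rat summaries average neurons, never pool spikes", {
  r0 <- detect_bursts(make_train(c(0, 0.5, 1.0, 1.5), 2), da)          # 0%
  r60 <- detect_bursts(make_train(c(0, 0.05, 0.10, 0.50, 1.00), 2), da) # 60%
  s <- burst_summary_by_rat(list(r0, r60), c("rat1", "rat1"))
  expect_equal(s$pct_spikes_in_burst, 30)
  expect_equal(s$pct_neurons_with_burst, 50)

  s2 <- burst_summary_by_rat(list(r0, r0, r0, r60), rep("ratA", 4))
  expect_equal(s2$pct_neurons_with_burst, 25)

  # fixed-ISI renewal trains at 0.5 s never burst
  rs <- lapply(1:6, function(i) detect_bursts(make_train(cumsum(rep(0.5, 30)), 20), da))
  s3 <- burst_summary_by_rat(rs, rep(c("r1", "r2"), each = 3))
  expect_equal(s3$pct_spikes_in_burst, c(0, 0))
  expect_equal(s3$pct_neurons_with_burst, c(0, 0))
})
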