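test_that("stimulation protocol defaults follow the standard paradigm", {
  p <- stim_protocol()
  expect_equal(p$n_pulses, 200L)
  expect_equal(p$intensity, 300)
  expect_equal(p$pulse_width_ms, 0.5)
  expect_equal(diff(p$pulse_times)[1], 1)
  p5 <- stim_protocol(frequency = 5)
  expect_equal(diff(p5$pulse_times)[1], 0.2)
})

test_that("PSTH counts conserve spike-pulse pairs and flat input stays flat", {
  pro <- stim_protocol(n_pulses = 200, frequency = 1)
  st <- simulate_tonic_train(12, 215, 1, neuron_type = "PYR", seed = 31)
  psth <- build_psth(st, pro, bin_ms = 2, window_ms = c(-100, 200))
  # conservation: total counts = number of (spike, pulse) pairs in window
  pairs <- sum(vapply(pro$pulse_times, function(p) {
    sum(st$times - p >= -0.1 & st$times - p < 0.2)
  }, numeric(1)))
  expect_equal(sum(psth$counts), pairs)
  # flat train: every bin within 4 sqrt(prestim_mean) of the prestim mean
  expect_true(all(abs(psth$counts - psth$prestim_mean) <
                    4 * sqrt(psth$prestim_mean)))
  # empty train: all-zero PSTH
  empty <- spike_train(numeric(0), 0, 215, "PYR")
  expect_true(all(build_psth(empty, pro)$counts == 0))
})

test_that("a 5 Hz window exceeding the inter-pulse interval is truncated", {
  pro <- stim_protocol(n_pulses = 50, frequency = 5)
  st <- simulate_tonic_train(12, 25, 1, neuron_type = "PYR", seed = 5)
  expect_warning(psth <- build_psth(st, pro, window_ms = c(-100, 300)),
                 "truncated")
  expect_equal(psth$window_ms[2], 200)
})

test_that("DOS thresholds are traced on a hand-built PSTH", {
  # prestim mean 10; five sub-50% bins then recovery at the sixth
  mk_psth <- function(post) {
    structure(list(breaks_ms = seq(-100, by = 2, length.out = 51 + length(post)),
                   counts = c(rep(10L, 50), post), bin_ms = 2,
                   window_ms = c(-100, 2 * length(post)),
                   prestim_mean = 10, n_pulses = 200, neuron_id = "n"),
              class = "psth")
  }
  d <- duration_of_suppression(mk_psth(c(2L, 2L, 2L, 2L, 2L, 9L, 10L, 10L)))
  expect_equal(d$onset_ms, 0)
  expect_equal(d$offset_ms, 10)
  expect_equal(d$dos_ms, 10)
  expect_false(d$censored)

  # flat PSTH at the prestim mean: no suppression
  flat <- duration_of_suppression(mk_psth(rep(10L, 8)))
  expect_equal(flat$dos_ms, 0)

  # suppression without recovery inside the window: censored
  cens <- duration_of_suppression(mk_psth(rep(1L, 8)))
  expect_true(cens$censored)
  expect_true(is.na(cens$dos_ms))

  # DOS is invariant under uniform count scaling
  sc <- mk_psth(c(2L, 2L, 2L, 2L, 2L, 9L, 10L, 10L))
  sc$counts <- sc$counts * 7L; sc$prestim_mean <- 70
  expect_equal(duration_of_suppression(sc)$dos_ms, 10)
})

test_that("simulated step suppression is recovered with at most one-bin bias", {
  ests <- vapply(1:40, function(s) {
    ex <- simulate_stimulation_experiment(12, 0.040, stim_protocol(),
                                          seed = 900 + s)
    psth <- build_psth(ex$train, ex$protocol)
    duration_of_suppression(psth)$dos_ms
  }, numeric(1))
  expect_equal(median(ests), 40)
  expect_lte(abs(mean(ests) - 40), 2)  # bias no more than one bin
})

test_that("paired 1/5 Hz comparison recovers a constructed DOS difference", {
  # true durations 60 and 40 ms on the same neuron; median paired
  # difference over seeds recovers 20 ms within one-and-a-half bins
  diffs <- vapply(1:15, function(s) {
    ex1 <- simulate_stimulation_experiment(12, 0.060, stim_protocol(frequency = 1),
                                           seed = 70 + s)
    ex5 <- simulate_stimulation_experiment(12, 0.040, stim_protocol(frequency = 5),
                                           seed = 170 + s)
    p1 <- build_psth(ex1$train, ex1$protocol)
    p5 <- suppressWarnings(build_psth(ex5$train, ex5$protocol))
    out <- compare_frequencies(p1, p5)
    out$dos_1hz_ms - out$dos_5hz_ms
  }, numeric(1))
  expect_lte(abs(median(diffs) - 20), 3)

  # identical PSTHs give identical DOS; mismatched neurons are refused
  ex <- simulate_stimulation_experiment(12, 0.040, stim_protocol(), seed = 1)
  p1 <- build_psth(ex$train, ex$protocol)
  expect_equal(compare_frequencies(p1, p1)$dos_1hz_ms,
               compare_frequencies(p1, p1)$dos_5hz_ms)
  p_other <- p1; p_other$neuron_id <- "other"
  expect_error(compare_frequencies(p1, p_other), "different neurons")
})

test_that("a pyramidal rate too low for DOS extraction is an error", {
  pro <- stim_protocol(n_pulses = 20)
  silent <- spike_train(numeric(0), 0, 40, "PYR")
  psth <- build_psth(silent, pro)
  expect_error(duration_of_suppression(psth), "prestimulation mean")
})
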