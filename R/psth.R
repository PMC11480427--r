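#' Electrical stimulation protocol
#'
#' Pulse train delivered to the ascending 5-HT fiber bundle. The standard
#' protocol is 200 square pulses of 0.5 ms at 300 uA, delivered at 1 or 5 Hz;
#' the same neuron is tested at both frequencies to probe the terminal
#' 5-HT1B autoreceptor.
#'
#' @param pulse_times Seconds; if omitted, generated as `n_pulses` evenly
#'   spaced pulses at `frequency` starting at `first_pulse`.
#' @param n_pulses Number of pulses (default 200).
#' @param frequency Hz (default 1; the protocol uses 1 and 5).
#' @param intensity Pulse intensity in uA (default 300).
#' @param pulse_width_ms Pulse width in ms (default 0.5).
#' @param first_pulse Time of the first pulse in seconds (default 10).
#' @return A list of class `stim_protocol`.
#' @export
stim_protocol <- function(pulse_times = NULL, n_pulses = 200, frequency = 1,
                          intensity = 300, pulse_width_ms = 0.5,
                          first_pulse = 10) {
  if (is.null(pulse_times)) {
    stopifnot(n_pulses >= 1, frequency > 0)
    pulse_times <- first_pulse + (seq_len(n_pulses) - 1) / frequency
  } else {
    stopifnot(!is.unsorted(pulse_times, strictly = TRUE))
    n_pulses <- length(pulse_times)
  }
  structure(list(pulse_times = as.numeric(pulse_times),
                 n_pulses = as.integer(n_pulses),
                 frequency = as.numeric(frequency),
                 intensity = as.numeric(intensity),
                 pulse_width_ms = as.numeric(pulse_width_ms)),
            class = "stim_protocol")
}

#' Peristimulus time histogram
#'
#' Spike times are re-referenced to each stimulation pulse and accumulated
#' into fixed-width bins over a window around the pulse; counts are summed
#' over pulses. The prestimulation mean (`prestim_mean`, events per bin) is
#' computed from the bins lying entirely before time 0. If the requested
#' post-pulse window exceeds the inter-pulse interval (e.g. a 5 Hz train with
#' a 200 ms-plus window), the window is truncated to the interval with a
#' warning so that each spike is attributed to the pulse that precedes it.
#'
#' @param train A [spike_train()].
#' @param protocol A [stim_protocol()].
#' @param bin_ms Bin width in ms (default 2, the conventional PSTH bin).
#' @param window_ms Length-2 numeric `c(pre, post)` in ms around each pulse
#'   (default `c(-100, 200)`; `pre` is negative).
#' @return A list of class `psth`: `breaks_ms`, `counts`, `bin_ms`,
#'   `window_ms`, `prestim_mean`, `n_pulses`, `neuron_id`.
#' @export
build_psth <- function(train, protocol, bin_ms = 2, window_ms = c(-100, 200)) {
  stopifnot(inherits(train, "spike_train"), inherits(protocol, "stim_protocol"),
            bin_ms > 0, length(window_ms) == 2L, window_ms[1] < 0,
            window_ms[2] > 0)
  ipi_ms <- if (protocol$n_pulses > 1) 1000 * min(diff(protocol$pulse_times)) else Inf
  if (window_ms[2] > ipi_ms) {
    warning(sprintf("post-pulse window (%g ms) exceeds the inter-pulse interval (%g ms); truncated",
                    window_ms[2], ipi_ms))
    window_ms[2] <- ipi_ms
  }
  pre_bins <- floor(-window_ms[1] / bin_ms)
  post_bins <- floor(window_ms[2] / bin_ms)
  if (pre_bins < 10) stop("window must cover at least 10 prestimulation bins", call. = FALSE)
  breaks <- bin_ms * seq.int(-pre_bins, post_bins)
  counts <- integer(pre_bins + post_bins)
  for (p in protocol$pulse_times) {
    rel <- (train$times - p) * 1000
    rel <- rel[rel >= breaks[1] & rel < breaks[length(breaks)]]
    if (length(rel)) {
      counts <- counts + tabulate(floor((rel - breaks[1]) / bin_ms) + 1L,
                                  nbins = length(counts))
    }
  }
  structure(list(breaks_ms = breaks, counts = counts, bin_ms = bin_ms,
                 window_ms = window_ms,
                 prestim_mean = mean(counts[seq_len(pre_bins)]),
                 n_pulses = protocol$n_pulses,
                 neuron_id = train$neuron_id),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> neuron %s: %d pulses, %g-ms bins over [%g, %g] ms; prestim %.2f events/bin\n",
              x$neuron_id, x$n_pulses, x$bin_ms, x$window_ms[1], x$window_ms[2],
              x$prestim_mean))
  invisible(x)
}

#' Duration of suppression (DOS) from a PSTH
#'
#' DOS is the interval from the first post-stimulus bin whose count falls to
#' at or below 50% of the prestimulation mean, to the first subsequent bin
#' whose count returns to at or above 90% of that mean. Both times are taken
#' at bin left edges, so the estimate is quantized to the bin width. If no
#' bin qualifies as an onset the DOS is 0; an onset without recovery inside
#' the window is censored (`dos_ms = NA`). `persistence = 2` additionally
#' requires two consecutive sub-50% bins to accept an onset, guarding
#' against single-bin noise dips (off by default; the plain rule follows the
#' verbal definition).
#'
#' @param psth A [build_psth()] result with `prestim_mean > 0`.
#' @param persistence 1 (default) or 2 consecutive bins required at onset.
#' @return A list of class `dos_result`: `dos_ms`, `onset_ms`, `offset_ms`,
#'   `censored`.
#' @export
duration_of_suppression <- function(psth, persistence = 1) {
  stopifnot(inherits(psth, "psth"), persistence %in% c(1, 2))
  pm <- psth$prestim_mean
  if (pm <= 0) stop("prestimulation mean is zero; DOS undefined", call. = FALSE)
  left <- psth$breaks_ms[-length(psth$breaks_ms)]
  post <- which(left >= 0)
  cnt <- psth$counts
  low <- cnt[post] <= 0.5 * pm
  if (persistence == 2) low <- low & c(low[-1], FALSE)
  on_rel <- which(low)[1]
  if (is.na(on_rel)) {
    return(structure(list(dos_ms = 0, onset_ms = NA_real_, offset_ms = NA_real_,
                          censored = FALSE), class = "dos_result"))
  }
  onset_ms <- left[post[on_rel]]
  rec <- which(cnt[post] >= 0.9 * pm & seq_along(post) > on_rel)[1]
  if (is.na(rec)) {
    return(structure(list(dos_ms = NA_real_, onset_ms = onset_ms,
                          offset_ms = NA_real_, censored = TRUE),
                     class = "dos_result"))
  }
  offset_ms <- left[post[rec]]
  structure(list(dos_ms = offset_ms - onset_ms, onset_ms = onset_ms,
                 offset_ms = offset_ms, censored = FALSE),
            class = "dos_result")
}

#' @export
print.dos_result <- function(x, ...) {
  if (x$censored) cat("<dos_result> censored (no recovery inside window)\n")
  else cat(sprintf("<dos_result> DOS %.1f ms (onset %.1f, offset %.1f)\n",
                   x$dos_ms, x$onset_ms, x$offset_ms))
  invisible(x)
}

#' Paired 1 Hz / 5 Hz suppression durations
#'
#' The terminal 5-HT1B autoreceptor probe: the same neuron is stimulated at
#' 1 and 5 Hz and the two suppression durations are compared within-neuron.
#'
#' @param psth_1hz,psth_5hz PSTHs of the same neuron at the two frequencies.
#' @param ... Passed to [duration_of_suppression()].
#' @return A tibble with one row: `neuron_id`, `dos_1hz_ms`, `dos_5hz_ms`.
#' @export
compare_frequencies <- function(psth_1hz, psth_5hz, ...) {
  stopifnot(inherits(psth_1hz, "psth"), inherits(psth_5hz, "psth"))
  if (!identical(psth_1hz$neuron_id, psth_5hz$neuron_id)) {
    stop("PSTHs come from different neurons; the comparison is within-neuron",
         call. = FALSE)
  }
  tibble::tibble(neuron_id = psth_1hz$neuron_id,
                 dos_1hz_ms = duration_of_suppression(psth_1hz, ...)$dos_ms,
                 dos_5hz_ms = duration_of_suppression(psth_5hz, ...)$dos_ms)
}
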